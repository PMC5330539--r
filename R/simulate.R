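#' Simulate the E-I spiking network
#'
#' Integrates the coupled membrane/conductance dynamics with a fixed-step
#' second-order Runge-Kutta (midpoint) scheme.  Each neuron obeys
#' \deqn{\tau_k \frac{dV}{dt} = V_L - V + G_E(t)(E_E - V) + G_I(t)(E_I - V),}
#' with \eqn{G_E, G_I} the kernel-filtered, latency-delayed sums of
#' presynaptic spike trains (strengths in units of the leak conductance,
#' scaled by the membrane time constant \eqn{\tau_k}), plus pooled external
#' Poisson drive.  In the current-based variant the driving forces
#' \eqn{(E_k - V)} are replaced by \eqn{(E_k - \bar V)} with the fixed
#' potential \code{V_mean}.  A threshold crossing emits a spike, resets
#' \eqn{V} to \code{V_reset}, and clamps \eqn{V} there for the refractory
#' period while the conductance states keep integrating inputs.  Initial
#' membrane potentials are uniform on \eqn{[V_L, \theta)}; the first
#' \code{discard} seconds are dropped and the origin of the returned spike
#' times shifted accordingly.  Fully reproducible given the seed.
#'
#' @param params a \code{\link{NetworkParams}} object.
#' @param topology a \code{\link{Topology}} consistent with \code{params};
#'   built from \code{params} (with \code{params@seed}) when omitted.
#' @param record optional integer vector of neuron indices whose membrane
#'   potential and input conductances are recorded every step (keep the
#'   duration short when recording).
#' @param seed integer seed for the integration RNG (initial conditions and
#'   external drive); defaults to \code{params@seed}.
#' @param clamp_G_E,clamp_G_I constant conductances (units of leak
#'   conductance) added to every neuron's synaptic input; with
#'   \code{f_ex = 0} and \code{C = 0} this turns the integrator into a
#'   single-neuron constant-input oracle.
#' @return a \code{\link{SpikeData}} raster; when \code{record} is given,
#'   the raster carries a \code{\link{StateTrace}} in
#'   \code{attr(x, "trace")}.
#' @examples
#' p <- networkParams(N = 50L, duration = 1.5, discard = 0.5, f_ex = 2.5)
#' sd <- simulateNetwork(p, buildNetwork(p))
#' nNeurons(sd)
#' @export
simulateNetwork <- function(params, topology = NULL, record = NULL,
                            seed = params@seed,
                            clamp_G_E = 0, clamp_G_I = 0) {
  stopifnot(is(params, "NetworkParams"))
  validObject(params)
  if (is.null(topology)) topology <- buildNetwork(params)
  stopifnot(is(topology, "Topology"))
  if (topology@nE + topology@nI != params@N)
    stop("topology size does not match params@N")
  csr <- .topologyToCSR(topology)
  rec <- if (is.null(record)) integer() else as.integer(record)
  res <- .simulate_ei_cpp(topology@nE, topology@nI, csr$ptr, csr$idx,
                          .paramsToList(params, clamp_G_E, clamp_G_I),
                          rec, as.integer(seed))
  N <- params@N
  dur_ms <- (params@duration - params@discard) * 1000
  spikes <- split(res$time, factor(res$neuron, levels = seq_len(N)))
  spikes <- lapply(spikes, as.numeric)
  label <- rep(c("E", "I"), c(topology@nE, topology@nI))
  out <- new("SpikeData", spikes = spikes, label = label,
             duration = dur_ms, params = params)
  if (length(rec)) {
    attr(out, "trace") <- new("StateTrace",
      time = as.numeric(res$trace_time),
      V = res$trace_V, G_E = res$trace_GE, G_I = res$trace_GI,
      neurons = rec)
  }
  out
}
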