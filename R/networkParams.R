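#' Construct a network parameter set
#'
#' Returns a \code{\link{NetworkParams}} object whose defaults are the
#' reference parameter set of the conductance-based E-I network: 2500
#' neurons at a 4:1 E:I ratio, connection probability 0.2, 400 external
#' Poisson inputs per neuron at 2.5 Hz each, balanced synaptic strengths
#' (in units of the leak conductance), 20/10 ms membrane time constants,
#' -50 mV threshold, -60 mV reset, 2/1 ms refractory periods, 1 ms
#' synaptic latency and 0.5 ms rise time.  The excitatory and inhibitory
#' synaptic decay times \code{tau_de} and \code{tau_di} are the swept
#' parameters; their defaults (4, 10) ms sit in the moderately
#' synchronised (critical) region.
#'
#' @param tau_de,tau_di excitatory/inhibitory synaptic decay times (ms).
#' @param N total neuron count.
#' @param ratio_EI E:I population ratio.
#' @param C connection probability.
#' @param K_O external in-degree.
#' @param f_ex external per-connection Poisson rate (Hz).
#' @param g_EO,g_IO,g_EE,g_IE,g_EI,g_II synaptic strengths (units of
#'   \code{g_L}); first index letter is the postsynaptic population.
#' @param g_L leak conductance (nS, metadata).
#' @param E_E,E_I reversal potentials (mV).
#' @param tau_E,tau_I membrane time constants (ms).
#' @param V_L leak potential (mV).
#' @param theta spike threshold (mV).
#' @param V_reset reset potential (mV).
#' @param t_rp_E,t_rp_I refractory periods (ms).
#' @param tau_l,tau_r synaptic latency and rise time (ms).
#' @param model_variant \code{"conductance"} (default) or \code{"current"},
#'   the latter replacing the voltage-dependent driving force by a fixed
#'   driving potential \code{V_mean}.
#' @param V_mean fixed driving potential for the current-based variant (mV).
#' @param dt integration step (ms).
#' @param duration simulated time (s).
#' @param discard initial transient to drop (s).
#' @param seed integer seed for the simulation RNG.
#'
#' @return a validated \code{NetworkParams} object.
#' @examples
#' p <- networkParams(tau_de = 4, tau_di = 10, duration = 2)
#' nExc(p)   # 2000
#' nInh(p)   # 500
#' @export
networkParams <- function(tau_de = 4, tau_di = 10,
                          N = 2500L, ratio_EI = 4, C = 0.2,
                          K_O = 400, f_ex = 2.5,
                          g_EO = 0.05, g_IO = 0.08, g_EE = 0.04,
                          g_IE = 0.08, g_EI = 0.6, g_II = 0.96,
                          g_L = 10,
                          E_E = 0, E_I = -70,
                          tau_E = 20, tau_I = 10,
                          V_L = -70, theta = -50, V_reset = -60,
                          t_rp_E = 2, t_rp_I = 1,
                          tau_l = 1, tau_r = 0.5,
                          model_variant = c("conductance", "current"),
                          V_mean = -60,
                          dt = 0.05, duration = 50, discard = 1,
                          seed = 1L) {
  model_variant <- match.arg(model_variant)
  # slot-wise assignment: a slot is named `C`, which would partially match
  # the `Class` argument of new()
  p <- new("NetworkParams")
  p@N <- as.integer(N); p@ratio_EI <- ratio_EI; p@C <- C
  p@K_O <- K_O; p@f_ex <- f_ex
  p@g_EO <- g_EO; p@g_IO <- g_IO; p@g_EE <- g_EE; p@g_IE <- g_IE
  p@g_EI <- g_EI; p@g_II <- g_II; p@g_L <- g_L
  p@E_E <- E_E; p@E_I <- E_I; p@tau_E <- tau_E; p@tau_I <- tau_I
  p@V_L <- V_L; p@theta <- theta; p@V_reset <- V_reset
  p@t_rp_E <- t_rp_E; p@t_rp_I <- t_rp_I
  p@tau_l <- tau_l; p@tau_r <- tau_r
  p@tau_de <- tau_de; p@tau_di <- tau_di
  p@model_variant <- model_variant; p@V_mean <- V_mean
  p@dt <- dt; p@duration <- duration; p@discard <- discard
  p@seed <- as.integer(seed)
  validObject(p)
  p
}

#' @rdname networkParams
#' @param params a \code{NetworkParams} object.
#' @return \code{nExc}/\code{nInh}: the excitatory/inhibitory population
#'   sizes implied by \code{N} and \code{ratio_EI}.
#' @export
nExc <- function(params) {
  as.integer(round(params@N * params@ratio_EI / (params@ratio_EI + 1)))
}

#' @rdname networkParams
#' @export
nInh <- function(params) params@N - nExc(params)

setMethod("show", "NetworkParams", function(object) {
  cat("NetworkParams (", object@model_variant, "-based)\n", sep = "")
  cat("  N =", object@N, " (E:I =", nExc(object), ":", nInh(object),
      "), C =", object@C, "\n")
  cat("  tau_de =", object@tau_de, "ms, tau_di =", object@tau_di, "ms\n")
  cat("  external: K_O =", object@K_O, "at f_ex =", object@f_ex, "Hz\n")
  cat("  duration =", object@duration, "s (discard", object@discard,
      "s), dt =", object@dt, "ms, seed =", object@seed, "\n")
})

# flatten a NetworkParams into the named list the C++ integrator expects
.paramsToList <- function(params, clamp_G_E = 0, clamp_G_I = 0) {
  list(
    g_EO = params@g_EO, g_IO = params@g_IO, g_EE = params@g_EE,
    g_IE = params@g_IE, g_EI = params@g_EI, g_II = params@g_II,
    E_E = params@E_E, E_I = params@E_I,
    tau_E = params@tau_E, tau_I = params@tau_I,
    V_L = params@V_L, theta = params@theta, V_reset = params@V_reset,
    t_rp_E = params@t_rp_E, t_rp_I = params@t_rp_I,
    tau_l = params@tau_l, tau_r = params@tau_r,
    tau_de = params@tau_de, tau_di = params@tau_di,
    dt = params@dt,
    duration_ms = params@duration * 1000,
    discard_ms = params@discard * 1000,
    K_O = params@K_O, f_ex = params@f_ex,
    current_based = identical(params@model_variant, "current"),
    V_mean = params@V_mean,
    clamp_G_E = clamp_G_E, clamp_G_I = clamp_G_I
  )
}
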