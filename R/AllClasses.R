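#' Network parameter set for the E-I spiking model
#'
#' Holds every constant of the conductance-based (or current-based)
#' excitatory-inhibitory leaky integrate-and-fire network: population sizes,
#' connectivity, synaptic strengths (in units of the leak conductance),
#' reversal potentials, membrane and synaptic time constants, spiking
#' thresholds and integration settings.  Construct with
#' \code{\link{networkParams}}, whose defaults are the reference parameter
#' set of the model.
#'
#' @slot N total neuron count.
#' @slot ratio_EI excitatory:inhibitory population ratio (e.g. 4 for 4:1).
#' @slot C connection probability in \eqn{[0,1]}.
#' @slot K_O external in-degree (number of external Poisson sources).
#' @slot f_ex external per-connection Poisson rate (Hz).
#' @slot g_EO,g_IO,g_EE,g_IE,g_EI,g_II synaptic strengths, dimensionless in
#'   units of the leak conductance; first superscript letter is the
#'   postsynaptic population, second the presynaptic source (O = external).
#' @slot g_L leak conductance (nS; metadata only, all dynamics are in units
#'   of \code{g_L}).
#' @slot E_E,E_I excitatory/inhibitory reversal potentials (mV).
#' @slot tau_E,tau_I membrane time constants (ms).
#' @slot V_L leak (resting) potential (mV).
#' @slot theta spike threshold (mV).
#' @slot V_reset reset potential (mV).
#' @slot t_rp_E,t_rp_I refractory periods (ms).
#' @slot tau_l,tau_r synaptic latency and rise time (ms).
#' @slot tau_de,tau_di excitatory/inhibitory synaptic decay times (ms).
#' @slot model_variant \code{"conductance"} or \code{"current"}.
#' @slot V_mean fixed driving potential for the current-based variant (mV).
#' @slot dt integration step (ms).
#' @slot duration simulated time (s).
#' @slot discard initial transient dropped from the output (s).
#' @slot seed integer seed for the simulation RNG.
#'
#' @seealso \code{\link{networkParams}}, \code{\link{simulateNetwork}}
#' @exportClass NetworkParams
setClass("NetworkParams",
  slots = c(
    N = "integer", ratio_EI = "numeric", C = "numeric",
    K_O = "numeric", f_ex = "numeric",
    g_EO = "numeric", g_IO = "numeric", g_EE = "numeric", g_IE = "numeric",
    g_EI = "numeric", g_II = "numeric", g_L = "numeric",
    E_E = "numeric", E_I = "numeric",
    tau_E = "numeric", tau_I = "numeric",
    V_L = "numeric", theta = "numeric", V_reset = "numeric",
    t_rp_E = "numeric", t_rp_I = "numeric",
    tau_l = "numeric", tau_r = "numeric",
    tau_de = "numeric", tau_di = "numeric",
    model_variant = "character", V_mean = "numeric",
    dt = "numeric", duration = "numeric", discard = "numeric",
    seed = "integer"
  ),
  prototype = list(
    N = 2500L, ratio_EI = 4, C = 0.2, K_O = 400, f_ex = 2.5,
    g_EO = 0.05, g_IO = 0.08, g_EE = 0.04, g_IE = 0.08,
    g_EI = 0.6, g_II = 0.96, g_L = 10,
    E_E = 0, E_I = -70, tau_E = 20, tau_I = 10,
    V_L = -70, theta = -50, V_reset = -60,
    t_rp_E = 2, t_rp_I = 1, tau_l = 1, tau_r = 0.5,
    tau_de = 4, tau_di = 10,
    model_variant = "conductance", V_mean = -60,
    dt = 0.05, duration = 50, discard = 1, seed = 1L
  )
)

setValidity("NetworkParams", function(object) {
  msg <- character()
  nE <- object@N * object@ratio_EI / (object@ratio_EI + 1)
  if (abs(nE - round(nE)) > 1e-9)
    msg <- c(msg, "N * ratio_EI / (ratio_EI + 1) must be an integer")
  if (object@C < 0 || object@C > 1)
    msg <- c(msg, "C must lie in [0, 1]")
  if (object@tau_r >= object@tau_de || object@tau_r >= object@tau_di)
    msg <- c(msg, "tau_r must be smaller than both tau_de and tau_di")
  if (object@V_reset >= object@theta)
    msg <- c(msg, "V_reset must be below theta")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@duration <= object@discard)
    msg <- c(msg, "duration must exceed discard")
  if (!object@model_variant %in% c("conductance", "current"))
    msg <- c(msg, "model_variant must be 'conductance' or 'current'")
  if (length(msg)) msg else TRUE
})

#' Spike raster with population labels
#'
#' The universal currency between pipeline stages: per-neuron ordered spike
#' times (ms, relative to the post-discard origin) together with each
#' neuron's population label (\code{"E"} or \code{"I"}), the raster
#' duration, and the parameter set (or surrogate description) that produced
#' it.
#'
#' @slot spikes list of strictly increasing numeric vectors, one per neuron.
#' @slot label character vector of \code{"E"}/\code{"I"} labels per neuron.
#' @slot duration raster duration (ms); all spike times lie in
#'   \eqn{[0, duration)}.
#' @slot params the \code{NetworkParams} that produced the raster, or a
#'   list tag describing a surrogate / file origin.
#'
#' @seealso \code{\link{simulateNetwork}}, \code{\link{generateSurrogate}},
#'   \code{\link{readRaster}}
#' @exportClass SpikeData
setClass("SpikeData",
  slots = c(spikes = "list", label = "character", duration = "numeric",
            params = "ANY")
)

setValidity("SpikeData", function(object) {
  msg <- character()
  if (length(object@spikes) != length(object@label))
    msg <- c(msg, "one label per neuron required")
  if (!all(object@label %in% c("E", "I")))
    msg <- c(msg, "labels must be 'E' or 'I'")
  bad <- vapply(object@spikes, function(s) {
    length(s) && (is.unsorted(s, strictly = TRUE) || s[1] < 0 ||
                  s[length(s)] >= object@duration)
  }, logical(1))
  if (any(bad))
    msg <- c(msg, "spike times must be strictly increasing within [0, duration)")
  if (length(msg)) msg else TRUE
})

#' Membrane-state traces of recorded neurons
#'
#' Time courses of the membrane potential and the excitatory/inhibitory
#' input conductances (dimensionless, units of leak conductance) for a
#' recorded subset of neurons, plus the corresponding synaptic currents
#' \eqn{G_E (E_E - V)} and \eqn{G_I (E_I - V)} in mV after division by the
#' leak conductance.
#'
#' @slot time time grid (ms).
#' @slot V,G_E,G_I matrices (time x recorded neuron).
#' @slot neurons indices of the recorded neurons.
#' @exportClass StateTrace
setClass("StateTrace",
  slots = c(time = "numeric", V = "matrix", G_E = "matrix", G_I = "matrix",
            neurons = "integer")
)

#' Set of neuronal avalanches extracted from a raster
#'
#' An avalanche is a maximal run of consecutive non-empty time bins of
#' (excitatory) population spiking, flanked by empty bins.  Sizes are the
#' number of distinct neurons participating (default) or the total spike
#' count; both are stored.
#'
#' @slot sizes avalanche sizes under the selected definition.
#' @slot sizesSpikes total-spike-count sizes (always recorded).
#' @slot durations avalanche durations in bins.
#' @slot startBin first (0-based) occupied bin of each avalanche.
#' @slot waiting waiting times between consecutive avalanches (ms).
#' @slot binWidth bin width \eqn{\delta t} (ms).
#' @slot sizeDef \code{"neurons"} or \code{"spikes"}.
#' @slot nBins total number of bins partitioning the time axis.
#' @seealso \code{\link{extractAvalanches}}, \code{\link{fitPowerLaw}}
#' @exportClass AvalancheSet
setClass("AvalancheSet",
  slots = c(sizes = "integer", sizesSpikes = "integer", durations = "integer",
            startBin = "integer", waiting = "numeric", binWidth = "numeric",
            sizeDef = "character", nBins = "integer")
)

setValidity("AvalancheSet", function(object) {
  msg <- character()
  if (length(object@sizes) && any(object@sizes < 1))
    msg <- c(msg, "avalanche sizes must be >= 1")
  if (length(object@durations) && any(object@durations < 1))
    msg <- c(msg, "avalanche durations must be >= 1 bin")
  if (length(msg)) msg else TRUE
})

#' Discrete power-law fit of an avalanche-size distribution
#'
#' Maximum-likelihood fit of a truncated discrete power law
#' \eqn{P(s) \propto s^{-\alpha}} on \eqn{[s_{min}, s_{max}]}, together
#' with the distance statistic \eqn{D}: the mean absolute size-weighted gap
#' between the empirical and fitted mass functions, normalised by the
#' fitted mean size.
#'
#' @slot exponent fitted exponent \eqn{\alpha}.
#' @slot sMin,sMax support bounds of the fit.
#' @slot pFit fitted probability mass on \code{sMin:sMax} (sums to 1).
#' @slot distance the distance statistic \eqn{D \ge 0}.
#' @slot method \code{"mle"} or \code{"logbin-ls"}.
#' @seealso \code{\link{fitPowerLaw}}
#' @exportClass PowerLawFit
setClass("PowerLawFit",
  slots = c(exponent = "numeric", sMin = "integer", sMax = "integer",
            pFit = "numeric", distance = "numeric", method = "character")
)

#' Windowed population spike patterns from one sampled neuron subset
#'
#' Spike trains of \code{n} sampled excitatory neurons binned into
#' consecutive windows of \eqn{\Delta\tau} ms.  In the binary scenario a
#' neuron contributes a spiking indicator per window; in the analog
#' scenario its spike count (capped at 10).  Pattern identities are stored
#' as a count table; the mean spike totals feeding the energy measures are
#' kept uncapped.
#'
#' @slot scenario \code{"binary"} or \code{"analog"}.
#' @slot window window length \eqn{\Delta\tau} (ms).
#' @slot n number of sampled neurons.
#' @slot neurons sampled neuron indices.
#' @slot counts named integer vector: pattern key to occurrence count;
#'   counts sum to \code{Tw}.
#' @slot Tw number of windows.
#' @slot m mean (uncapped) spikes per window over the subset.
#' @slot mn mean number of spiking neurons per window.
#' @seealso \code{\link{makePatterns}}, \code{\link{patternEntropy}}
#' @exportClass PatternEnsemble
setClass("PatternEnsemble",
  slots = c(scenario = "character", window = "numeric", n = "integer",
            neurons = "integer", counts = "integer", Tw = "integer",
            m = "numeric", mn = "numeric")
)

setValidity("PatternEnsemble", function(object) {
  msg <- character()
  if (sum(object@counts) != object@Tw)
    msg <- c(msg, "pattern counts must sum to the number of windows")
  if (!object@scenario %in% c("binary", "analog"))
    msg <- c(msg, "scenario must be 'binary' or 'analog'")
  if (length(msg)) msg else TRUE
})

#' Information-capacity and energy-efficiency report
#'
#' Summary of a pattern-ensemble analysis averaged over sampled neuron
#' subsets: plug-in entropy \eqn{H} (bits), mean spikes per window
#' \eqn{m}, mean spiking-neuron count \eqn{m_n}, activity level
#' \eqn{\rho = m/n}, burst level \eqn{B = m/m_n}, energy
#' \eqn{E = m + n r}, efficiency \eqn{\eta_{sim} = H/E}, the matched
#' maximum-entropy optimum \eqn{\eta_{opt}}, the burst and synchrony
#' reductions \eqn{R_B, R_S}, and the observed/predicted empty-pattern
#' probabilities.
#'
#' @slot scenario,n,Tw,nSamples provenance of the estimate.
#' @slot H entropy (bits), averaged over subsets.
#' @slot m,mn,rho,B activity summaries (see description).
#' @slot r resting energy per neuron per window (dimensionless).
#' @slot E energy per window.
#' @slot etaSim efficiency \eqn{H/E} (bits per energy unit).
#' @slot etaOpt optimal efficiency at the matched activity level.
#' @slot RB,RS burst and synchronisation reductions of efficiency.
#' @slot p0Observed,p0Predicted empty-pattern probability, observed and
#'   under independent sparse firing.
#' @seealso \code{\link{patternEfficiency}},
#'   \code{\link{reductionDecomposition}}
#' @exportClass EfficiencyReport
setClass("EfficiencyReport",
  slots = c(scenario = "character", n = "integer", Tw = "integer",
            nSamples = "integer", H = "numeric", m = "numeric",
            mn = "numeric", rho = "numeric", B = "numeric", r = "numeric",
            E = "numeric", etaSim = "numeric", etaOpt = "numeric",
            RB = "numeric", RS = "numeric",
            p0Observed = "numeric", p0Predicted = "numeric")
)
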