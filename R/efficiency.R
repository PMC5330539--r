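#' Information capacity and energy efficiency of pattern ensembles
#'
#' Aggregates a list of \code{\link{PatternEnsemble}} objects (the random
#' neuron subsets) into an \code{\link{EfficiencyReport}}: the plug-in
#' entropy \eqn{H} is averaged over subsets, as are the mean spikes per
#' window \eqn{m} and mean spiking-neuron count \eqn{m_n}; the energy per
#' window is \eqn{E = m + n r} (every emitted spike costs one unit even
#' in the binary scenario, plus the resting cost \eqn{r} per neuron), the
#' efficiency is \eqn{\eta_{sim} = H/E}, and the matched optimum
#' \eqn{\eta_{opt}(\rho)} with \eqn{\rho = m/n} is attached, along with
#' the burst/synchrony decomposition of the efficiency gap and the
#' empty-pattern probabilities.
#'
#' @param ensembles a \code{\link{PatternEnsemble}} or list of them, all
#'   from the same scenario and subset size.
#' @param r resting energy per neuron per window (dimensionless; the
#'   empirical range is roughly 0.005 to 0.1).
#' @return an \code{\link{EfficiencyReport}}.
#' @seealso \code{\link{makePatterns}},
#'   \code{\link{reductionDecomposition}}, \code{\link{etaOpt}}
#' @export
patternEfficiency <- function(ensembles, r = 0) {
  if (is(ensembles, "PatternEnsemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1, r >= 0)
  scn <- ensembles[[1]]@scenario
  n <- ensembles[[1]]@n
  Tw <- ensembles[[1]]@Tw
  H <- patternEntropy(ensembles)
  m <- mean(vapply(ensembles, function(e) e@m, numeric(1)))
  mn <- mean(vapply(ensembles, function(e) e@mn, numeric(1)))
  if (m == 0 && r == 0)
    stop("zero spikes with r = 0: efficiency undefined")
  rho <- m / n
  B <- if (mn > 0) m / mn else NA_real_
  E <- m + n * r
  etaSim <- H / E
  etaOptMatched <- tryCatch(etaOpt(rho, r, scn), error = function(e) NA_real_)
  p0 <- emptyPatternProbability(ensembles)
  rpt <- new("EfficiencyReport", scenario = scn, n = n, Tw = Tw,
             nSamples = length(ensembles), H = H, m = m, mn = mn,
             rho = rho, B = B, r = r, E = E, etaSim = etaSim,
             etaOpt = etaOptMatched, RB = NA_real_, RS = NA_real_,
             p0Observed = p0$p0_observed, p0Predicted = p0$p0_predicted)
  dec <- reductionDecomposition(rpt)
  rpt@RB <- dec$R_B
  rpt@RS <- dec$R_S
  rpt
}

#' Burst/synchrony decomposition of the efficiency gap
#'
#' Splits the gap between the simulated efficiency and its
#' maximum-entropy upper bound into the part due to bursting (redundant
#' spikes of the same neuron within one window) and the remainder,
#' ascribed to synchronisation among neurons:
#' \deqn{R_B = \frac{H}{m_n} - \frac{H}{m} = (B - 1)\,\eta_{sim},
#' \qquad
#' R_S = \eta_{opt}(m_n/n) - B\,\eta_{sim},}
#' evaluated at \eqn{r = 0} (so \eqn{\eta_{sim} = H/m}), for which the
#' two sum exactly to \eqn{\eta_{opt}(m_n/n) - H/m}.  For a report with
#' \eqn{r > 0} the same forms are used with \eqn{\eta_{sim} = H/(m+nr)}
#' and \eqn{\eta_{opt}(m_n/n; r)} as a diagnostic, in which case the sum
#' equals \eqn{\eta_{opt}(m_n/n; r) - H/(m+nr)} exactly.
#'
#' @param report an \code{\link{EfficiencyReport}}.
#' @return list with \code{R_B}, \code{R_S} and their sum \code{total}.
#' @export
reductionDecomposition <- function(report) {
  stopifnot(is(report, "EfficiencyReport"))
  if (is.na(report@B) || report@mn == 0)
    return(list(R_B = NA_real_, R_S = NA_real_, total = NA_real_))
  etaSim <- report@H / (report@m + report@n * report@r)
  RB <- (report@B - 1) * etaSim
  etaOptMn <- tryCatch(etaOpt(report@mn / report@n, report@r,
                              report@scenario),
                       error = function(e) NA_real_)
  RS <- etaOptMn - report@B * etaSim
  list(R_B = RB, R_S = RS, total = RB + RS)
}

setMethod("show", "EfficiencyReport", function(object) {
  cat("EfficiencyReport (", object@scenario, ", r = ", object@r, ")\n",
      sep = "")
  cat("  n =", object@n, ", windows =", object@Tw, ", subsets =",
      object@nSamples, "\n")
  cat("  H =", round(object@H, 4), "bits;  m =", round(object@m, 4),
      ";  m_n =", round(object@mn, 4), ";  B =", round(object@B, 4), "\n")
  cat("  rho =", round(object@rho, 4), ";  E =", round(object@E, 4),
      ";  eta_sim =", round(object@etaSim, 4), ";  eta_opt =",
      round(object@etaOpt, 4), "\n")
  cat("  R_B =", signif(object@RB, 4), ";  R_S =", signif(object@RS, 4),
      ";  p0 obs/pred =", signif(object@p0Observed, 4), "/",
      signif(object@p0Predicted, 4), "\n")
})

#' Flatten an EfficiencyReport to a one-row data.frame
#'
#' @param report an \code{\link{EfficiencyReport}}.
#' @return one-row data.frame with all report quantities.
#' @export
efficiencyAsData <- function(report) {
  data.frame(scenario = report@scenario, n = report@n, Tw = report@Tw,
             n_samples = report@nSamples, r = report@r, H = report@H,
             m = report@m, m_n = report@mn, rho = report@rho,
             B = report@B, E = report@E, eta_sim = report@etaSim,
             eta_opt = report@etaOpt, R_B = report@RB, R_S = report@RS,
             p0_observed = report@p0Observed,
             p0_predicted = report@p0Predicted)
}
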