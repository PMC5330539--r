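#' Optimal energy efficiency of population spike patterns
#'
#' Closed-form maximum-entropy upper bound on the energy efficiency of a
#' windowed population spike pattern at activity level \eqn{\rho = m/n}
#' (mean spikes per neuron per window) and relative resting energy
#' \eqn{r} (leak cost per neuron per window, in units of the cost of one
#' spike):
#' \deqn{\eta_{opt}(\rho) = \frac{f(\rho)}{\rho + r} \quad (binary),
#' \qquad
#' \eta_{opt}(\rho) = \frac{f(\rho/(1+\rho))\,(1+\rho)}{\rho + r}
#' \quad (analog),}
#' where \eqn{f(x) = -x \log_2 x - (1-x)\log_2(1-x)} is the binary entropy
#' function.  The bound is attained when neurons are active independently
#' with identical probability (binary) or with independent geometric
#' spike counts (analog); it is independent of the population size
#' \eqn{n}.
#'
#' @param rho activity level; in \eqn{(0, 1)} for binary, \eqn{> 0} for
#'   analog.  Vectorised.
#' @param r relative resting energy per neuron per window (empirical
#'   range roughly 0.005 to 0.1).
#' @param scenario \code{"binary"} or \code{"analog"}.
#' @return optimal efficiency in bits per energy unit.
#' @examples
#' etaOpt(0.5, r = 0, scenario = "binary")   # 2 bits per spike
#' etaOpt(1,   r = 0, scenario = "analog")   # 2
#' @export
etaOpt <- function(rho, r = 0, scenario = c("binary", "analog")) {
  scenario <- match.arg(scenario)
  if (scenario == "binary") {
    if (any(rho <= 0 | rho >= 1))
      stop("binary scenario requires 0 < rho < 1")
    binaryEntropy(rho) / (rho + r)
  } else {
    if (any(rho <= 0)) stop("analog scenario requires rho > 0")
    binaryEntropy(rho / (1 + rho)) * (1 + rho) / (rho + r)
  }
}

#' @rdname etaOpt
#' @param x probability in \eqn{[0, 1]}; vectorised.
#' @return \code{binaryEntropy}: \eqn{f(x)} in bits, with
#'   \eqn{0 \log 0 = 0}.
#' @export
binaryEntropy <- function(x) {
  stopifnot(all(x >= 0 & x <= 1))
  out <- numeric(length(x))
  ok <- x > 0 & x < 1
  out[ok] <- -x[ok] * log2(x[ok]) - (1 - x[ok]) * log2(1 - x[ok])
  out
}

#' Optimal activity level as a function of resting energy
#'
#' The activity level \eqn{\rho_m} maximising \code{\link{etaOpt}} at a
#' given \eqn{r}, obtained from the stationarity condition of the
#' optimal-efficiency curve:
#' \deqn{\rho_m^{\,r} = (1-\rho_m)^{1+r} \quad (binary), \qquad
#'       \rho_m^{\,r} = (1+\rho_m)^{r-1} \quad (analog),}
#' solved by bracketed root-finding (both conditions are re-derived from
#' the first-order optimality of the closed-form curves; a grid-argmax
#' cross-check guards the algebra in the test-suite).  As
#' \eqn{r \to \infty}, \eqn{\rho_m \to 0.5} (binary) or
#' \eqn{\rho_m \to 1} (analog); as \eqn{r \to 0}, \eqn{\rho_m \to 0} and
#' the function returns 0 with attribute \code{limit = TRUE}.
#'
#' @param r resting energy, \eqn{\ge 0}.
#' @param scenario \code{"binary"} or \code{"analog"}.
#' @param dtau optional pattern window (ms); when supplied, the result
#'   carries the matching optimal firing rate
#'   \eqn{v_m = \rho_m/\Delta\tau} (Hz) as attribute \code{v_m}.
#' @param tol root-finder tolerance.
#' @return \eqn{\rho_m}; with attribute \code{v_m} if \code{dtau} is
#'   given.
#' @examples
#' rhoM(0.1, "binary")           # ~ 0.156
#' attr(rhoM(0.1, "binary", dtau = 20), "v_m")  # ~ 7.8 Hz
#' @export
rhoM <- function(r, scenario = c("binary", "analog"), dtau = NULL,
                 tol = 1e-12) {
  scenario <- match.arg(scenario)
  stopifnot(length(r) == 1, r >= 0)
  if (r == 0) {
    out <- 0
    attr(out, "limit") <- TRUE
    if (!is.null(dtau)) attr(out, "v_m") <- 0
    return(out)
  }
  g <- if (scenario == "binary") {
    function(p) r * log(p) - (1 + r) * log1p(-p)
  } else {
    function(p) r * log(p) - (r - 1) * log1p(p)
  }
  upper <- if (scenario == "binary") 1 - 1e-12 else 1e3
  root <- uniroot(g, c(1e-12, upper), tol = tol)$root
  out <- root
  if (!is.null(dtau)) attr(out, "v_m") <- root / (dtau / 1000)
  out
}

#' @rdname etaOpt
#' @param s_max largest spike count a neuron can contribute per window.
#' @return \code{etaOptAnalogExact}: the analog bound computed from the
#'   exactly truncated (counts \eqn{0..s_{max}}) maximum-entropy count
#'   distribution, rather than the geometric closed form; the two agree
#'   closely at low activity levels.
#' @export
etaOptAnalogExact <- function(rho, r = 0, s_max = 10) {
  stopifnot(length(rho) == 1, rho > 0, rho < s_max)
  s <- 0:s_max
  # solve for the count-distribution parameter matching the mean rho
  meanAt <- function(mu) {
    w <- exp(-mu * s)
    sum(s * w) / sum(w) - rho
  }
  mu <- uniroot(meanAt, c(-50, 50), tol = 1e-14)$root
  w <- exp(-mu * s)
  p <- w / sum(w)
  h <- -sum(p[p > 0] * log2(p[p > 0]))   # per-neuron entropy, bits
  h / (rho + r)
}

#' Maximum-entropy optimal pattern distribution
#'
#' The pattern distribution attaining the entropy bound at activity level
#' \eqn{\rho}: in the binary scenario each neuron is independently active
#' with probability \eqn{\rho}, so a pattern with \eqn{m_i} active
#' neurons has probability \eqn{(1-\rho)^{n-m_i}\rho^{m_i}} and the total
#' spike count is Binomial\eqn{(n, \rho)}; in the analog scenario spike
#' counts are independently geometric with parameter
#' \eqn{\rho' = \rho/(1+\rho)}, a pattern with \eqn{m_i} total spikes has
#' probability \eqn{(1-\rho')^n \rho'^{m_i}}, and the total count follows
#' the negative-binomial form
#' \eqn{P_k = \binom{n-1+k}{n-1}(1-\rho')^n\rho'^k}.
#'
#' @param rho activity level.
#' @param n number of neurons.
#' @param scenario \code{"binary"} or \code{"analog"}.
#' @param k_max largest total count tabulated for the analog \eqn{P_k}.
#' @return list with \code{patternProb} (function of the per-pattern
#'   spike total \eqn{m_i}) and \code{Pk} (named numeric vector over
#'   total counts \eqn{k}).
#' @export
optimalPatternDistribution <- function(rho, n,
                                       scenario = c("binary", "analog"),
                                       k_max = 10 * n) {
  scenario <- match.arg(scenario)
  if (scenario == "binary") {
    stopifnot(rho > 0, rho < 1)
    k <- 0:n
    Pk <- choose(n, k) * (1 - rho)^(n - k) * rho^k
    list(patternProb = function(mi) (1 - rho)^(n - mi) * rho^mi,
         Pk = setNames(Pk, k))
  } else {
    stopifnot(rho > 0)
    rp <- rho / (1 + rho)
    k <- 0:k_max
    Pk <- choose(n - 1 + k, n - 1) * (1 - rp)^n * rp^k
    list(patternProb = function(mi) (1 - rp)^n * rp^mi,
         Pk = setNames(Pk, k))
  }
}

#' Optimal-efficiency theory curve
#'
#' Tabulates \eqn{\eta_{opt}(\rho)} over a grid of activity levels, and
#' reports the optimum \eqn{\rho_m} and matching firing rate
#' \eqn{v_m = \rho_m/\Delta\tau}.
#'
#' @param scenario \code{"binary"} or \code{"analog"}.
#' @param r resting energy.
#' @param rho grid of activity levels.
#' @param dtau pattern window (ms) used to convert \eqn{\rho} to Hz.
#' @return data.frame with columns \code{rho} and \code{eta_opt};
#'   attributes \code{rho_m} and \code{v_m} carry the optimum.
#' @export
theoryCurve <- function(scenario = c("binary", "analog"), r = 0.1,
                        rho = NULL, dtau = 20) {
  scenario <- match.arg(scenario)
  if (is.null(rho))
    rho <- if (scenario == "binary")
      seq(0.001, 0.999, length.out = 999) else
      seq(0.001, 3, length.out = 1000)
  out <- data.frame(rho = rho, eta_opt = etaOpt(rho, r, scenario))
  rm_ <- rhoM(r, scenario, dtau = dtau)
  attr(out, "rho_m") <- as.numeric(rm_)
  attr(out, "v_m") <- attr(rm_, "v_m")
  out
}
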