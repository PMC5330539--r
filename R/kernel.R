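#' Bi-exponential synaptic conductance kernel
#'
#' The unitary conductance time course elicited by one presynaptic spike:
#' a delayed difference of exponentials
#' \deqn{s(t) = \Theta(t-\tau_l)\,
#'   \frac{e^{-(t-\tau_l)/\tau_d} - e^{-(t-\tau_l)/\tau_r}}{\tau_d-\tau_r},}
#' with latency \eqn{\tau_l}, rise time \eqn{\tau_r} and decay time
#' \eqn{\tau_d} (all ms).  The kernel is non-negative, has unit time
#' integral for any valid parameters, and peaks at
#' \eqn{\tau_l + \frac{\tau_r\tau_d}{\tau_d-\tau_r}\log(\tau_d/\tau_r)}
#' (see \code{\link{kernelPeakTime}}).
#'
#' @param t time (ms), vectorised; any real values.
#' @param tau_l latency (ms).
#' @param tau_r rise time (ms); must be strictly less than \code{tau_d}.
#' @param tau_d decay time (ms).
#' @return kernel values (1/ms), zero for \code{t <= tau_l}.
#' @examples
#' tt <- seq(0, 40, by = 0.01)
#' sum(synapticKernel(tt, 1, 0.5, 4)) * 0.01  # ~ 1
#' @export
synapticKernel <- function(t, tau_l = 1, tau_r = 0.5, tau_d = 4) {
  if (tau_d == tau_r)
    stop("degenerate kernel: tau_d must differ from tau_r")
  x <- t - tau_l
  out <- numeric(length(t))
  pos <- x > 0
  out[pos] <- (exp(-x[pos] / tau_d) - exp(-x[pos] / tau_r)) / (tau_d - tau_r)
  out
}

#' @rdname synapticKernel
#' @return \code{kernelPeakTime}: the time (ms) at which the kernel is
#'   maximal.
#' @export
kernelPeakTime <- function(tau_l = 1, tau_r = 0.5, tau_d = 4) {
  if (tau_d == tau_r)
    stop("degenerate kernel: tau_d must differ from tau_r")
  tau_l + tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
}
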