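#' Power spectrum of population activity with peak detection
#'
#' Welch-averaged power spectrum of the mean-detrended population
#' activity, smoothed with a Gaussian kernel over frequency, and the
#' frequency/power of the smoothed maximum above a floor frequency.
#'
#' @slot freq frequency grid (Hz).
#' @slot power raw Welch power.
#' @slot smoothed Gaussian-smoothed power.
#' @slot peakFreq,peakPower location and height of the smoothed maximum
#'   over \code{freq >= f_min}.
#' @seealso \code{\link{spectrumPeak}}
#' @exportClass SpectrumResult
setClass("SpectrumResult",
  slots = c(freq = "numeric", power = "numeric", smoothed = "numeric",
            peakFreq = "numeric", peakPower = "numeric")
)

setMethod("show", "SpectrumResult", function(object) {
  cat("SpectrumResult: peak", round(object@peakFreq, 2), "Hz (power",
      signif(object@peakPower, 4), "),", length(object@freq),
      "frequency bins\n")
})

#' Spectral peak of the population rhythm
#'
#' Estimates the power spectrum of the mean-detrended binned population
#' activity with Welch's method (Hann-windowed segments, 50\% overlap),
#' smooths it with a Gaussian kernel of standard deviation
#' \code{smoothing_sigma} Hz, and reports the frequency of maximal
#' smoothed power at or above \code{f_min}.  The floor frequency excludes
#' the low-frequency mass of asynchronous activity so that a genuine
#' oscillation peak (gamma band for the reference network) is picked out.
#'
#' @param activity a \code{\link{PopulationActivity}} (1-ms bins give a
#'   500 Hz Nyquist frequency).
#' @param smoothing_sigma Gaussian smoothing width (Hz).
#' @param f_min lowest frequency searched for the peak (Hz).
#' @param segment segment length for Welch averaging (s).
#' @param overlap fractional overlap of consecutive segments.
#' @return a \code{\link{SpectrumResult}}.
#' @export
spectrumPeak <- function(activity, smoothing_sigma = 2, f_min = 10,
                         segment = 2, overlap = 0.5) {
  stopifnot(is(activity, "PopulationActivity"))
  A <- activity@counts
  fs <- 1000 / activity@bin                    # sampling rate, Hz
  if (f_min > fs / 2) stop("f_min exceeds the Nyquist frequency")
  nseg <- min(length(A), round(segment * fs))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(A) - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  wnorm <- fs * sum(w^2)
  nf <- floor(nseg / 2) + 1
  pxx <- numeric(nf)
  for (s0 in starts) {
    seg <- A[s0:(s0 + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    pxx <- pxx + (Mod(X)^2) / wnorm
  }
  pxx <- pxx / length(starts)
  # one-sided: double the interior bins
  if (nf > 2) pxx[2:(nf - 1)] <- 2 * pxx[2:(nf - 1)]
  freq <- (seq_len(nf) - 1) * fs / nseg

  df <- fs / nseg
  half <- max(1L, ceiling(4 * smoothing_sigma / df))
  kx <- (-half):half
  kern <- exp(-0.5 * (kx * df / smoothing_sigma)^2)
  kern <- kern / sum(kern)
  padded <- c(rep(pxx[1], half), pxx, rep(pxx[nf], half))
  smoothed <- vapply(seq_len(nf), function(i)
    sum(padded[i:(i + 2 * half)] * kern), numeric(1))

  search <- which(freq >= f_min)
  pk <- search[which.max(smoothed[search])]
  new("SpectrumResult", freq = freq, power = pxx, smoothed = smoothed,
      peakFreq = freq[pk], peakPower = smoothed[pk])
}
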