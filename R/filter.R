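# Digital Butterworth low-pass design via the bilinear transform, and a
# zero-phase (forward-backward) application.  Hand-built because no filter
# design package is available in the target environment; validated in the
# test suite against the closed-form analytic magnitude response.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth low-pass filter
#'
#' Standard analog-prototype design: Butterworth poles on the left-half
#' s-plane circle at the prewarped cutoff, mapped to the z-plane by the
#' bilinear transform, with all zeros at z = -1 and unit DC gain.
#'
#' @param order filter order (number of poles).
#' @param cutoff_hz -3 dB corner frequency in Hz.
#' @param fs sampling frequency in Hz; `cutoff_hz` must be below `fs / 2`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(order = 6L, cutoff_hz = 55, fs = 250) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff must lie strictly inside (0, fs/2)")
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)          # prewarped analog cutoff
  k <- seq_len(order)
  p_analog <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p_digital <- (2 * fs + p_analog) / (2 * fs - p_analog)
  a <- Re(poly_from_roots(p_digital))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)                          # unit gain at DC (z = 1)
  list(b = b, a = a)
}

# single-pass IIR filtering, zero initial state; C-backed via stats::filter
iir_filter <- function(x, b, a) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb - 1 + seq_along(x)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter forward and then backward so the net phase is zero and
#' ST timing relative to the fiducial point is preserved; the effective
#' magnitude response is the squared single-pass response.  Edge transients
#' are suppressed by odd reflection padding.
#'
#' @param x numeric signal.
#' @param b,a filter coefficients from [butter_lowpass()].
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(x, b, a) {
  n <- length(x)
  pad <- min(n - 1, 3 * (length(a) + length(b)) + 100)
  head_pad <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xe <- c(head_pad, x, tail_pad)
  y <- iir_filter(xe, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[pad + seq_len(n)]
}
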