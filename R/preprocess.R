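#' Ambulatory ECG record container
#'
#' Holds multi-lead signal samples in microvolts together with a per-beat
#' table.  All leads share one sampling frequency and length; beats are
#' sorted by fiducial sample.
#'
#' @param signals numeric matrix, one column per lead (uV).
#' @param fs sampling frequency in Hz.
#' @param beats data.frame with columns `fiducial` (sample index of the
#'   stable fiducial point F) and `label` (`"normal"` or `"abnormal"`).
#' @return object of class `ecg_record` with fields `signals`, `fs`,
#'   `beats`, plus (after [annotate_isoelectric()]) per-beat, per-lead
#'   isoelectric levels `iso` and isoelectric window centers `iso_center`.
#' @export
ecg_record <- function(signals, fs, beats = NULL) {
  signals <- as.matrix(signals)
  if (fs <= 0) stop("fs must be positive")
  if (is.null(beats))
    beats <- data.frame(fiducial = integer(), label = character())
  if (!all(c("fiducial", "label") %in% names(beats)))
    stop("beats needs columns 'fiducial' and 'label'")
  beats <- beats[order(beats$fiducial), , drop = FALSE]
  rownames(beats) <- NULL
  if (nrow(beats) && (min(beats$fiducial) < 1 ||
                      max(beats$fiducial) > nrow(signals)))
    stop("fiducial points outside record")
  structure(list(signals = signals, fs = fs, beats = beats,
                 iso = NULL, iso_center = NULL),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record: %d leads, %.1f s at %g Hz, %d beats\n",
              ncol(x$signals), nrow(x$signals) / x$fs, x$fs, nrow(x$beats)))
  invisible(x)
}

#' Low-pass filter an ECG record
#'
#' Removes high-frequency noise with a 6-pole Butterworth low-pass
#' (default -3 dB at 55 Hz) applied forward-backward to every lead, so the
#' net result is zero-phase with the squared single-pass magnitude.
#'
#' @param record an `ecg_record`.
#' @param cutoff_hz corner frequency (default 55 Hz).
#' @param order number of poles (default 6).
#' @return the filtered record.
#' @export
lowpass_filter <- function(record, cutoff_hz = 55, order = 6L) {
  if (record$fs <= 2 * cutoff_hz)
    stop("sampling frequency too low for the requested cutoff")
  ba <- butter_lowpass(order, cutoff_hz, record$fs)
  record$signals <- apply(record$signals, 2, filtfilt_zero_phase,
                          b = ba$b, a = ba$a)
  record
}

# flattest-window search shared by estimate_isoelectric / annotate_isoelectric;
# returns c(z, center_sample) or c(NA, NA) when there is no room before F
flattest_window <- function(sig, fidu, fs, search_ms = c(120, 20),
                            window_ms = 20) {
  lo <- fidu - round(search_ms[1] * fs / 1000)
  hi <- fidu - round(search_ms[2] * fs / 1000)
  w <- max(2L, round(window_ms * fs / 1000))
  if (lo < 1 || hi - lo + 1 < w) return(c(NA_real_, NA_real_))
  starts <- lo:(hi - w + 1L)
  seg <- sig[lo:hi]
  ad <- abs(diff(seg))
  cs <- c(0, cumsum(ad))
  flat <- cs[starts - lo + w] - cs[starts - lo + 1]   # sum |diff| per window
  best <- starts[max(which(flat <= min(flat) + 1e-12))]  # tie: closest to F
  csum <- c(0, cumsum(seg))
  z <- (csum[best - lo + w + 1] - csum[best - lo + 1]) / w
  c(z, best + (w - 1) / 2)
}

#' Estimate the isoelectric level of one beat
#'
#' Slides a 20 ms window over the PQ search region \[F - 120 ms, F - 20 ms\]
#' and scores each position by the sum of absolute first differences; the
#' isoelectric level z is the mean amplitude of the flattest window, ties
#' broken in favor of the window closest to F.
#'
#' @param record an `ecg_record`.
#' @param beat_index row of the beat table.
#' @param search_ms search region as ms before F, `c(from, to)`.
#' @param window_ms flatness window length in ms.
#' @return numeric vector of z per lead (uV), with attribute `center`
#'   (window center, in samples) per lead; NA when there is not enough
#'   signal before the fiducial point.
#' @export
estimate_isoelectric <- function(record, beat_index,
                                 search_ms = c(120, 20), window_ms = 20) {
  fidu <- record$beats$fiducial[beat_index]
  res <- vapply(seq_len(ncol(record$signals)), function(l)
    flattest_window(record$signals[, l], fidu, record$fs, search_ms,
                    window_ms), numeric(2))
  z <- res[1, ]
  attr(z, "center") <- res[2, ]
  z
}

#' Fill per-beat, per-lead isoelectric levels
#'
#' Runs [estimate_isoelectric()] over every beat and stores the results in
#' the record (`iso`, `iso_center`, both beats x leads).  Beats without
#' enough pre-fiducial signal get NA and are treated as unusable downstream.
#'
#' @inheritParams estimate_isoelectric
#' @return the annotated record.
#' @export
annotate_isoelectric <- function(record, search_ms = c(120, 20),
                                 window_ms = 20) {
  nb <- nrow(record$beats)
  nl <- ncol(record$signals)
  iso <- matrix(NA_real_, nb, nl)
  ctr <- matrix(NA_real_, nb, nl)
  for (j in seq_len(nb)) {
    z <- estimate_isoelectric(record, j, search_ms, window_ms)
    iso[j, ] <- z
    ctr[j, ] <- attr(z, "center")
  }
  record$iso <- iso
  record$iso_center <- ctr
  record
}

#' Remove baseline wander by cubic-spline subtraction
#'
#' Fits a natural cubic spline per lead through the knots (isoelectric
#' window center time, isoelectric level) and subtracts it, so the corrected
#' signal's isoelectric level is zero at every knot.  The fit-and-subtract
#' step is applied twice: after the first subtraction the isoelectric
#' levels are re-estimated (the flattest PQ window can move once the large
#' wander is gone) and the remaining mid-knot interpolation residual is
#' removed by a second spline.  With fewer than three usable knots the fit
#' falls back to linear interpolation with a warning.
#'
#' @param record an `ecg_record` annotated by [annotate_isoelectric()].
#' @param passes number of fit-subtract iterations (default 2).
#' @return the baseline-corrected record, re-annotated so `iso` reflects the
#'   corrected signal.
#' @export
remove_baseline <- function(record, passes = 2L) {
  if (is.null(record$iso)) record <- annotate_isoelectric(record)
  for (pass in seq_len(passes)) {
    record <- remove_baseline_once(record)
  }
  record
}

remove_baseline_once <- function(record) {
  n <- nrow(record$signals)
  for (l in seq_len(ncol(record$signals))) {
    ok <- !is.na(record$iso[, l])
    xs <- record$iso_center[ok, l]
    ys <- record$iso[ok, l]
    keep <- !duplicated(xs)
    xs <- xs[keep]; ys <- ys[keep]
    if (length(xs) < 3) {
      warning("fewer than 3 isoelectric knots in lead ", l,
              "; falling back to linear baseline")
      if (length(xs) < 2) next
      base <- stats::approx(xs, ys, xout = seq_len(n), rule = 2)$y
    } else {
      base <- stats::spline(xs, ys, xout = seq_len(n), method = "natural")$y
    }
    record$signals[, l] <- record$signals[, l] - base
  }
  annotate_isoelectric(record)
}

#' Select normal beats with normal neighbors
#'
#' Keeps beats labeled normal whose immediate predecessor and successor are
#' also normal; the first and last beats are kept when their single neighbor
#' is normal.  Abnormal beats and their direct neighbors are excluded
#' because ectopy distorts both the preceding and following ST segments.
#'
#' @param beats data.frame with a `label` column, or a character vector of
#'   labels.
#' @return integer indices of the kept beats.
#' @export
select_normal_beats <- function(beats) {
  labels <- if (is.data.frame(beats)) beats$label else beats
  n <- length(labels)
  if (n == 0) return(integer())
  normal <- labels == "normal"
  prev_ok <- c(TRUE, normal[-n])
  next_ok <- c(normal[-1], TRUE)
  which(normal & prev_ok & next_ok)
}

#' Full preprocessing chain
#'
#' Low-pass filtering, isoelectric annotation, cubic-spline baseline
#' removal, re-annotation, and normal-beat selection.  The kept beat
#' indices are stored in `record$kept_beats`; the beat table itself is left
#' intact so indices remain aligned with ground truth.
#'
#' @param record an `ecg_record`.
#' @param cutoff_hz low-pass corner (default 55 Hz).
#' @return the preprocessed record.
#' @export
preprocess_record <- function(record, cutoff_hz = 55) {
  record <- lowpass_filter(record, cutoff_hz)
  record <- annotate_isoelectric(record)
  record <- remove_baseline(record)
  record$kept_beats <- select_normal_beats(record$beats)
  record
}
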