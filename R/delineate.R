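#' Instantaneous heart rate from beat times
#'
#' h(j) = 60000 / RR(j) with RR(j) = t(j) - t(j-1); the first beat has no
#' preceding RR interval, so h(1) is backfilled from h(2).
#'
#' @param beat_times_ms beat times in ms, strictly increasing.
#' @return heart rate in bpm, one value per beat.
#' @export
instantaneous_heart_rate <- function(beat_times_ms) {
  if (length(beat_times_ms) < 2) stop("need at least 2 beats")
  if (any(diff(beat_times_ms) <= 0)) stop("beat times must be increasing")
  rr <- diff(beat_times_ms)
  h <- 60000 / rr
  c(h[1], h)
}

#' Rate-adjusted ST measurement offset
#'
#' The ST amplitude is measured at F + 160 ms at heart rates up to 100 bpm
#' and at F + 120 ms from 120 bpm upward, with the measurement point
#' adjusted linearly in between.
#'
#' @param h heart rate in bpm (vectorized).
#' @return measurement offset after F, in ms.
#' @export
st_measurement_offset <- function(h) {
  if (any(h <= 0)) stop("heart rate must be positive")
  pmin(160, pmax(120, 160 - 2 * (h - 100)))
}

# linear-interpolated amplitude at a fractional offset (ms) after fiducial
amplitude_at <- function(sig, fidu, offset_ms, fs) {
  pos <- fidu + offset_ms * fs / 1000
  i0 <- floor(pos)
  if (i0 < 1 || i0 + 1 > length(sig)) return(NA_real_)
  frac <- pos - i0
  (1 - frac) * sig[i0] + frac * sig[i0 + 1]
}

#' ST-segment level of one beat
#'
#' Amplitude at the rate-adjusted measurement point minus the beat's
#' isoelectric level z.
#'
#' @param record an `ecg_record` annotated with isoelectric levels.
#' @param beat_index beat-table row.
#' @param lead lead index.
#' @param h heart rate (bpm) of this beat.
#' @return ST level in uV (NA when the measurement point or z is unusable).
#' @export
st_level <- function(record, beat_index, lead, h) {
  z <- record$iso[beat_index, lead]
  off <- if (is.na(h)) 160 else st_measurement_offset(h)
  a <- amplitude_at(record$signals[, lead], record$beats$fiducial[beat_index],
                    off, record$fs)
  a - z
}

#' ST-segment slope of one beat
#'
#' Amplitude difference between the rate-adjusted measurement point and the
#' point F + 60 ms; independent of the isoelectric level.
#'
#' @inheritParams st_level
#' @return ST slope in uV.
#' @export
st_slope <- function(record, beat_index, lead, h) {
  sig <- record$signals[, lead]
  fidu <- record$beats$fiducial[beat_index]
  off <- if (is.na(h)) 160 else st_measurement_offset(h)
  amplitude_at(sig, fidu, off, record$fs) -
    amplitude_at(sig, fidu, 60, record$fs)
}

#' Extract the isoelectric-corrected ST pattern vector of one beat
#'
#' The signal over \[F + 40 ms, F + 160 ms\] is resampled by linear
#' interpolation onto `n_samples` equally spaced points (both window
#' endpoints included) and the beat's isoelectric level is subtracted from
#' every sample.
#'
#' @inheritParams st_level
#' @param window an [st_window_spec()].
#' @return numeric pattern vector (uV), or NULL when the window leaves the
#'   record or z is unavailable.
#' @export
extract_pattern_vector <- function(record, beat_index, lead,
                                   window = st_window_spec()) {
  fidu <- record$beats$fiducial[beat_index]
  fs <- record$fs
  pos <- fidu + seq(window$start_offset_ms, window$end_offset_ms,
                    length.out = window$n_samples) * fs / 1000
  if (floor(pos[1]) < 1 || ceiling(pos[length(pos)]) > nrow(record$signals))
    return(NULL)
  z <- record$iso[beat_index, lead]
  if (is.na(z)) return(NULL)
  sig <- record$signals[, lead]
  i0 <- floor(pos)
  frac <- pos - i0
  (1 - frac) * sig[i0] + frac * sig[pmin(i0 + 1, length(sig))] - z
}

#' Project a pattern vector onto the leading basis functions
#'
#' Raw morphologic coefficients: the first `n` entries of t(Phi) x.
#'
#' @param x pattern vector (uV).
#' @param basis a `basis_matrix` (or plain matrix) whose rows match `x`.
#' @param n number of leading coefficients (default 9).
#' @return numeric vector of length `n`.
#' @export
project_pattern <- function(x, basis, n = 9L) {
  e <- entries_of(basis)
  if (length(x) != nrow(e)) stop("pattern and basis dimensions disagree")
  as.numeric(crossprod(e[, seq_len(n), drop = FALSE], x))
}

#' Normalize raw coefficients by training-corpus standard deviations
#'
#' Elementwise division by rho (KLT) or theta (LPT), so each normalized
#' coefficient has unit standard deviation on the training corpus and
#' higher-order (smaller-variance) features are emphasized.
#'
#' @param raw raw coefficients.
#' @param model a [normalization_model()].
#' @param transform `"KLT"` or `"LPT"`.
#' @return normalized coefficients.
#' @export
normalize_coefficients <- function(raw, model, transform = c("KLT", "LPT")) {
  transform <- match.arg(transform)
  s <- if (transform == "KLT") model$rho else model$theta
  if (any(s <= 0)) stop("non-positive standard deviation in model")
  raw / s[seq_along(raw)]
}

#' Residual reconstruction error
#'
#' Root-mean-square of the difference between the pattern vector and its
#' reconstruction from the first `n` coefficients; with n = M (a complete
#' orthonormal basis) the residual vanishes.
#'
#' @inheritParams project_pattern
#' @return RMS residual in uV.
#' @export
residual_error <- function(x, basis, n = 9L) {
  e <- entries_of(basis)[, seq_len(n), drop = FALSE]
  r <- x - as.numeric(e %*% crossprod(e, x))
  sqrt(mean(r^2))
}

#' Mahalanobis-style compound distance series
#'
#' Euclidean distance, in normalized-coefficient space restricted to the
#' first `n_d` coefficients, between each beat's feature vector and the
#' first beat's; because the coefficients are variance-normalized this is a
#' Mahalanobis distance with diagonal covariance.  d(1) = 0 by construction.
#'
#' @param normalized matrix of normalized coefficients, one beat per row.
#' @param n_d number of leading coefficients used (default 5).
#' @return numeric distance series.
#' @export
mahalanobis_series <- function(normalized, n_d = 5L) {
  normalized <- as.matrix(normalized)
  if (nrow(normalized) == 0) stop("empty series")
  if (n_d > ncol(normalized)) stop("n_d exceeds coefficient count")
  d <- sweep(normalized[, seq_len(n_d), drop = FALSE], 2,
             normalized[1, seq_len(n_d)])
  sqrt(rowSums(d^2))
}

#' Delineate a preprocessed record into feature-vector time series
#'
#' Runs the per-beat diagnostic and morphologic measurements over the
#' selected normal beats of every lead and assembles the aligned series:
#' heart rate, ST level, ST slope, raw and normalized KLT and LPT
#' coefficients, residual errors, and Mahalanobis distances to the first
#' kept beat.
#'
#' @param record a preprocessed `ecg_record` (see [preprocess_record()]).
#' @param lpt LPT `basis_matrix`.
#' @param klt a `klt_model` (or KLT `basis_matrix`).
#' @param norm a `normalization_model`; when NULL, standard deviations are
#'   computed from this record's own patterns with a provenance warning.
#' @param n_coeffs coefficients per transform (default 9).
#' @param n_d Mahalanobis dimensionality (default 5).
#' @param window ST window specification.
#' @return a `feature_series` data.frame, one row per (lead, beat).
#' @export
delineate_record <- function(record, lpt, klt, norm = NULL, n_coeffs = 9L,
                             n_d = 5L, window = st_window_spec()) {
  if (is.null(record$iso)) record <- annotate_isoelectric(record)
  kept <- record$kept_beats
  if (is.null(kept)) kept <- select_normal_beats(record$beats)
  if (length(kept) == 0) stop("no usable beats in record")
  klt_b <- if (inherits(klt, "klt_model")) klt$basis else klt
  fs <- record$fs
  # heart rate from RR intervals between consecutive detected beats (all
  # beats, so a dropped ectopic does not inflate the apparent RR), then
  # restricted to the kept beats
  times_all_ms <- record$beats$fiducial / fs * 1000
  h_all <- if (nrow(record$beats) >= 2) instantaneous_heart_rate(times_all_ms)
           else rep(NA_real_, nrow(record$beats))
  h <- h_all[kept]
  times_ms <- times_all_ms[kept]

  rows <- list()
  for (lead in seq_len(ncol(record$signals))) {
    pats <- lapply(seq_along(kept), function(i)
      extract_pattern_vector(record, kept[i], lead, window))
    usable <- !vapply(pats, is.null, logical(1))
    if (!any(usable)) next
    idx <- which(usable)
    pmat <- do.call(rbind, pats[idx])
    raw_k <- pmat %*% entries_of(klt_b)[, seq_len(n_coeffs)]
    raw_l <- pmat %*% entries_of(lpt)[, seq_len(n_coeffs)]
    if (is.null(norm)) {
      warning("no normalization model supplied; standard deviations are ",
              "estimated from this record itself")
      norm <- normalization_model(
        rho = coefficient_stds(pmat, klt_b, n_coeffs),
        theta = coefficient_stds(pmat, lpt, n_coeffs),
        provenance = "self-trained on the delineated record")
    }
    norm_k <- sweep(raw_k, 2, norm$rho[seq_len(n_coeffs)], `/`)
    norm_l <- sweep(raw_l, 2, norm$theta[seq_len(n_coeffs)], `/`)
    res_k <- vapply(seq_len(nrow(pmat)), function(i)
      residual_error(pmat[i, ], klt_b, n_coeffs), numeric(1))
    res_l <- vapply(seq_len(nrow(pmat)), function(i)
      residual_error(pmat[i, ], lpt, n_coeffs), numeric(1))
    hh <- h[idx]
    sl <- ss <- numeric(length(idx))
    for (i in seq_along(idx)) {
      b <- kept[idx[i]]
      sl[i] <- st_level(record, b, lead, hh[i])
      ss[i] <- st_slope(record, b, lead, hh[i])
    }
    df <- data.frame(lead = lead, beat = kept[idx],
                     time_s = times_ms[idx] / 1000, h = hh,
                     s_l = sl, s_s = ss)
    colnames(raw_k) <- paste0("klt_", seq_len(n_coeffs))
    colnames(raw_l) <- paste0("lpt_", seq_len(n_coeffs))
    colnames(norm_k) <- paste0("nklt_", seq_len(n_coeffs))
    colnames(norm_l) <- paste0("nlpt_", seq_len(n_coeffs))
    df <- cbind(df, raw_k, norm_k, raw_l, norm_l,
                res_klt = res_k, res_lpt = res_l,
                d_k = mahalanobis_series(norm_k, n_d),
                d_l = mahalanobis_series(norm_l, n_d))
    rows[[lead]] <- df
  }
  if (!length(rows)) stop("no usable beats in record")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("feature_series", "data.frame"),
            n_coeffs = n_coeffs, n_d = n_d, window = window,
            provenance = if (!is.null(norm)) norm$provenance else NA)
}
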