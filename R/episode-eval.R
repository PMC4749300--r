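#' Mean episode feature vector
#'
#' Represents an annotated episode by the unweighted mean of the per-beat
#' normalized coefficient vectors inside a 20 s window centered on the
#' episode extremum (clipped to the episode bounds), restricted to the
#' requested coefficient subset.  Only a stable extremum is needed, not
#' accurate onset/offset detection.
#'
#' @param series a `feature_series` from [delineate_record()].
#' @param episode an [episode_spec()] (its first lead is used).
#' @param transform `"KLT"` or `"LPT"`.
#' @param subset coefficient indices, e.g. `1:8`.
#' @param half_window_s half-width of the averaging window (default 10 s).
#' @return numeric vector of length `length(subset)`, or NULL when no beat
#'   falls inside the window (warned).
#' @export
episode_feature <- function(series, episode, transform = c("KLT", "LPT"),
                            subset = 1:8, half_window_s = 10) {
  transform <- match.arg(transform)
  lead <- episode$leads[1]
  lo <- max(episode$extremum_s - half_window_s, episode$onset_s)
  hi <- min(episode$extremum_s + half_window_s, episode$offset_s)
  sel <- series$lead == lead & series$time_s >= lo & series$time_s <= hi
  if (!any(sel)) {
    warning("no beats inside the episode window; episode skipped")
    return(NULL)
  }
  prefix <- if (transform == "KLT") "nklt_" else "nlpt_"
  cols <- paste0(prefix, subset)
  colMeans(as.matrix(series[sel, cols, drop = FALSE]))
}

#' Sensitivity, specificity, classification accuracy
#'
#' Se = TP / (TP + FN), Sp = TN / (TN + FP),
#' CA = (TP + TN) / (TP + FN + TN + FP), reported in percent.  Positives
#' are ischaemic episodes.
#'
#' @param TP,FN,TN,FP confusion counts (non-negative).
#' @return named numeric vector `c(Se, Sp, CA)` in percent.
#' @export
classification_metrics <- function(TP, FN, TN, FP) {
  TP <- unname(TP); FN <- unname(FN); TN <- unname(TN); FP <- unname(FP)
  counts <- c(TP, FN, TN, FP)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (TP + FN == 0 || TN + FP == 0)
    stop("undefined metric: one class is empty")
  c(Se = 100 * TP / (TP + FN),
    Sp = 100 * TN / (TN + FP),
    CA = 100 * (TP + TN) / (TP + FN + TN + FP))
}

#' Repeated stratified cross-validation of episode classification
#'
#' Stratified 10-fold cross-validation repeated 10 times (both
#' configurable).  Instances are first put into a canonical order (by label,
#' then lexicographically by feature values) so fold assignment does not
#' depend on input order; each repetition reshuffles within class from the
#' seed.  Confusion counts are pooled over the folds of a repetition, and
#' Se/Sp/CA are averaged over repetitions.
#'
#' @param features numeric matrix, one instance per row.
#' @param labels `"ischaemic"` (positive) / `"non_ischaemic"` per row.
#' @param classifier one of [classifier_ids()].
#' @param folds,repetitions cross-validation geometry.
#' @param seed RNG seed (restored after use).
#' @return object of class `eval_result`: list with `classifier`, `Se`,
#'   `Sp`, `CA` (mean percentages) and `confusion` (per-repetition counts).
#' @export
crossvalidate <- function(features, labels, classifier = "3nn", folds = 10,
                          repetitions = 10, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (min(table(labels)) < folds)
    stop("each class needs at least as many instances as folds; ",
         "reduce 'folds' or supply more episodes")
  ord <- do.call(order, c(list(labels),
                          lapply(seq_len(ncol(features)),
                                 function(j) features[, j])))
  features <- features[ord, , drop = FALSE]
  labels <- labels[ord]
  pos <- "ischaemic"
  with_seed(seed, {
    conf <- matrix(0L, repetitions, 4,
                   dimnames = list(NULL, c("TP", "FN", "TN", "FP")))
    for (r in seq_len(repetitions)) {
      fold_id <- integer(length(labels))
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
      }
      pred <- character(length(labels))
      for (f in seq_len(folds)) {
        te <- fold_id == f
        pred[te] <- fit_and_predict(classifier,
                                    features[!te, , drop = FALSE],
                                    labels[!te],
                                    features[te, , drop = FALSE])
      }
      conf[r, ] <- c(sum(pred == pos & labels == pos),
                     sum(pred != pos & labels == pos),
                     sum(pred != pos & labels != pos),
                     sum(pred == pos & labels != pos))
    }
    m <- t(apply(conf, 1, function(z)
      classification_metrics(z[1], z[2], z[3], z[4])))
    structure(list(classifier = classifier,
                   Se = mean(m[, "Se"]), Sp = mean(m[, "Sp"]),
                   CA = mean(m[, "CA"]), confusion = conf),
              class = "eval_result")
  })
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s: Se %.1f%%  Sp %.1f%%  CA %.1f%%\n",
              x$classifier, x$Se, x$Sp, x$CA))
  invisible(x)
}

#' Synthetic episode-classification benchmark
#'
#' Generates a seeded benchmark of single-episode synthetic records
#' (ischaemic with true ST deviation versus heart-rate-related with T-wave
#' encroachment only), trains KLT and normalization models on a synthetic
#' corpus, runs the full preprocessing and delineation pipeline on every
#' record, and returns the per-episode mean normalized coefficient vectors
#' for both transforms.
#'
#' @param n_ischaemic,n_hr_related episode counts.
#' @param seed RNG seed; per-record seeds are derived from it.
#' @param duration_s length of each single-episode record.
#' @param noise_rms measurement noise (uV) in the records.
#' @param n_coeffs coefficients retained per transform.
#' @return list with `klt`, `lpt` (episode x coefficient matrices),
#'   `labels`, and the trained `models`.
#' @export
synth_episode_benchmark <- function(n_ischaemic = 200, n_hr_related = 100,
                                    seed = 1L, duration_s = 50,
                                    noise_rms = 15, n_coeffs = 9L) {
  models <- train_klt(make_training_corpus(seed = seed),
                      n_coeffs = n_coeffs)
  n <- n_ischaemic + n_hr_related
  klt_f <- lpt_f <- matrix(NA_real_, n, n_coeffs)
  labels <- character(n)
  for (i in seq_len(n)) {
    isch <- i <= n_ischaemic
    labels[i] <- if (isch) "ischaemic" else "non_ischaemic"
    ep <- with_seed(seed + 7L * i, {
      if (isch) {
        episode_spec("ischaemic", onset_s = 5, extremum_s = duration_s / 2,
                     offset_s = duration_s - 5,
                     magnitude_uv = sample(c(-1, 1), 1, prob = c(.75, .25)) *
                       stats::runif(1, 60, 250),
                     slope_uv = stats::rnorm(1, 0, 40),
                     scoop_uv = sample(c(-1, 1), 1) * stats::runif(1, 0, 80),
                     hr_delta_bpm = stats::runif(1, 0, 15))
      } else {
        episode_spec("heart_rate_related", onset_s = 5,
                     extremum_s = duration_s / 2, offset_s = duration_s - 5,
                     hr_delta_bpm = stats::runif(1, 15, 40))
      }
    })
    cfg <- synth_config(duration_s = duration_s, leads = 1L,
                        base_hr = 60 + (i %% 7) * 4, episodes = list(ep),
                        noise_rms = noise_rms,
                        baseline_wander = c(120, 0.3),
                        abnormal_beat_rate = 0.02, seed = seed + 1000L + i)
    rec <- make_record(cfg)
    pre <- preprocess_record(rec$record)
    fs <- delineate_record(pre, models$lpt, models$klt, models$norm,
                           n_coeffs = n_coeffs)
    fk <- episode_feature(fs, ep, "KLT", seq_len(n_coeffs))
    fl <- episode_feature(fs, ep, "LPT", seq_len(n_coeffs))
    if (!is.null(fk)) klt_f[i, ] <- fk
    if (!is.null(fl)) lpt_f[i, ] <- fl
  }
  ok <- stats::complete.cases(klt_f) & stats::complete.cases(lpt_f)
  list(klt = klt_f[ok, , drop = FALSE], lpt = lpt_f[ok, , drop = FALSE],
       labels = labels[ok], models = models)
}
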