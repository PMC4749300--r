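#' Reject outlying ST pattern vectors
#'
#' Simplified robust rejection rule used before class means are formed: the
#' per-sample median pattern is taken as the reference, each pattern's
#' root-mean-square deviation from it is computed, and patterns whose RMS
#' deviation exceeds `robust_z_threshold` times the median RMS deviation are
#' dropped.  Deterministic; a single pattern is always kept (its deviation
#' is zero).
#'
#' @param patterns numeric matrix, one pattern vector per row (uV).
#' @param robust_z_threshold multiple of the median RMS deviation beyond
#'   which a pattern is rejected (default 4).
#' @return the kept rows, as a matrix.
#' @export
reject_outliers <- function(patterns, robust_z_threshold = 4) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) == 0) stop("no patterns supplied")
  ref <- apply(patterns, 2, stats::median)
  rms <- sqrt(rowMeans(sweep(patterns, 2, ref)^2))
  med <- stats::median(rms)
  keep <- rms <= robust_z_threshold * med   # med = 0 keeps only exact matches
  if (!any(keep)) stop("degenerate input: all patterns rejected")
  patterns[keep, , drop = FALSE]
}

#' Group annotated interval patterns into classes and take their means
#'
#' Each annotated interval (ischaemic deviation, non-ischaemic deviation, or
#' no deviation) contributes one class whose representative is the arithmetic
#' mean of its member pattern vectors.  Leads are pooled: pattern vectors
#' from every lead enter the same corpus, since single-lead basis functions
#' independent of the physiological lead are wanted.
#'
#' @param corpus list of intervals; each element is a list with `patterns`
#'   (matrix, one pattern per row) and `label` (character).
#' @return list of classes, each with `label`, `mean` and `n_members`;
#'   empty intervals are skipped with a warning.
#' @export
build_classes <- function(corpus) {
  out <- list()
  for (iv in corpus) {
    p <- as.matrix(iv$patterns)
    if (nrow(p) == 0) {
      warning("skipping empty interval (label: ", iv$label, ")")
      next
    }
    out[[length(out) + 1L]] <- list(label = iv$label,
                                    mean = colMeans(p),
                                    n_members = nrow(p))
  }
  out
}

#' Robust covariance matrix from interval-class means
#'
#' The class means replace their members (one observation per annotated
#' interval, regardless of interval length), are centralized by the
#' unweighted grand mean over all classes, and the population-form outer
#' product average (divisor K) is returned.  This kernel-approximation
#' style estimate is insensitive to noisy individual beats because only
#' interval means enter it.
#'
#' @param classes list of classes from [build_classes()].
#' @param divisor `"K"` (population form, default) or `"K-1"`; the
#'   eigenvectors are unaffected by the choice.
#' @return list of class `robust_covariance` with `matrix`, `grand_mean`,
#'   `n_classes`.
#' @export
robust_covariance <- function(classes, divisor = c("K", "K-1")) {
  divisor <- match.arg(divisor)
  K <- length(classes)
  if (K < 2) stop("need at least 2 classes")
  means <- do.call(rbind, lapply(classes, `[[`, "mean"))
  gm <- colMeans(means)
  centered <- sweep(means, 2, gm)
  denom <- if (divisor == "K") K else K - 1
  cv <- crossprod(centered) / denom
  structure(list(matrix = cv, grand_mean = gm, n_classes = K),
            class = "robust_covariance")
}

#' Derive the KLT basis from a robust covariance matrix
#'
#' Eigendecomposition of the covariance; eigenvectors are ordered by
#' descending eigenvalue (ties broken by original index) and become the KLT
#' basis functions.  Because the leading KLT shapes empirically resemble the
#' low-order Legendre shapes, each eigenvector's sign is fixed so that its
#' inner product with the LPT basis function of the same index is >= 0,
#' giving a deterministic orientation.
#'
#' @param cov a `robust_covariance`, or a symmetric numeric matrix (uV^2).
#' @param window window spec attached to the basis.
#' @return list of class `klt_model` with `basis` (a `basis_matrix` of kind
#'   `"KLT"`), `eigenvalues` (descending) and `grand_mean`.
#' @export
derive_klt <- function(cov, window = NULL) {
  cv <- if (inherits(cov, "robust_covariance")) cov$matrix else as.matrix(cov)
  if (max(abs(cv - t(cv))) > 1e-8 * max(1, max(abs(cv))))
    stop("covariance matrix is not symmetric")
  M <- nrow(cv)
  if (is.null(window)) window <- st_window_spec(n_samples = M)
  eg <- eigen((cv + t(cv)) / 2, symmetric = TRUE)   # already descending
  vec <- eg$vectors
  ref <- lpt_basis(M)$entries
  for (k in seq_len(M)) {
    if (sum(vec[, k] * ref[, k]) < 0) vec[, k] <- -vec[, k]
  }
  structure(list(basis = new_basis_matrix(vec, "KLT", window, rep(1, M)),
                 eigenvalues = pmax(eg$values, 0),
                 grand_mean = if (inherits(cov, "robust_covariance"))
                   cov$grand_mean else rep(0, M)),
            class = "klt_model")
}

#' @export
print.klt_model <- function(x, ...) {
  cat(sprintf("KLT model: %d basis functions, leading eigenvalues %s\n",
              ncol(x$basis$entries),
              paste(signif(utils::head(x$eigenvalues, 3), 4),
                    collapse = ", ")))
  invisible(x)
}

#' Per-coefficient standard deviations over a pattern corpus
#'
#' Projects every pattern vector onto the first `n_coeffs` basis functions
#' and returns the sample standard deviation (divisor n - 1) of each
#' coefficient over the corpus.  These populate the normalization model
#' (rho for KLT, theta for LPT).  A zero-variance coefficient is floored at
#' `1e-12` with a warning so that normalization stays defined.
#'
#' @param corpus numeric matrix, one pattern vector per row (uV).
#' @param basis a `basis_matrix`.
#' @param n_coeffs number of leading coefficients (default 9).
#' @return numeric vector of length `n_coeffs`.
#' @export
coefficient_stds <- function(corpus, basis, n_coeffs = 9L) {
  corpus <- as.matrix(corpus)
  if (nrow(corpus) < 2) stop("corpus must hold at least 2 patterns")
  coeffs <- corpus %*% entries_of(basis)[, seq_len(n_coeffs), drop = FALSE]
  s <- apply(coeffs, 2, stats::sd)
  if (any(s <= 0)) {
    warning("zero-variance coefficient(s) floored at 1e-12: ",
            paste(which(s <= 0), collapse = ", "))
    s[s <= 0] <- 1e-12
  }
  s
}

#' Normalization model for coefficient time series
#'
#' Bundles the per-coefficient standard deviations of the KLT (`rho`) and
#' LPT (`theta`) expansions, estimated on a training corpus, together with a
#' provenance string.  Normalized coefficients are raw projections divided
#' by these values, so each normalized feature has unit standard deviation
#' on the training corpus.
#'
#' @param rho KLT coefficient standard deviations (positive).
#' @param theta LPT coefficient standard deviations (positive).
#' @param provenance free-text description of the training corpus.
#' @return object of class `normalization_model`.
#' @export
normalization_model <- function(rho, theta, provenance = "unspecified") {
  if (any(rho <= 0) || any(theta <= 0))
    stop("all standard deviations must be positive")
  if (length(rho) != length(theta))
    stop("rho and theta must have equal length")
  structure(list(rho = as.numeric(rho), theta = as.numeric(theta),
                 provenance = provenance),
            class = "normalization_model")
}

#' Train a KLT model and normalization model from an interval corpus
#'
#' Full training path: per-interval outlier rejection, class formation,
#' robust covariance, eigendecomposition, and coefficient standard
#' deviations for both transforms over the pooled (post-rejection) beats.
#'
#' @param corpus list of intervals as for [build_classes()].
#' @param n_coeffs number of coefficients retained in the normalization
#'   model (default 9).
#' @param robust_z_threshold passed to [reject_outliers()].
#' @param provenance description stored in the normalization model.
#' @return list with `klt` (a `klt_model`), `lpt` (a `basis_matrix`) and
#'   `norm` (a `normalization_model`).
#' @export
train_klt <- function(corpus, n_coeffs = 9L, robust_z_threshold = 4,
                      provenance = "synthetic training corpus") {
  cleaned <- lapply(corpus, function(iv) {
    kept <- tryCatch(reject_outliers(iv$patterns, robust_z_threshold),
                     error = function(e) iv$patterns)
    list(patterns = kept, label = iv$label)
  })
  classes <- build_classes(cleaned)
  cv <- robust_covariance(classes)
  klt <- derive_klt(cv)
  M <- nrow(cv$matrix)
  lpt <- lpt_basis(M)
  pooled <- do.call(rbind, lapply(cleaned, `[[`, "patterns"))
  norm <- normalization_model(
    rho = coefficient_stds(pooled, klt$basis, n_coeffs),
    theta = coefficient_stds(pooled, lpt, n_coeffs),
    provenance = provenance)
  list(klt = klt, lpt = lpt, norm = norm)
}
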