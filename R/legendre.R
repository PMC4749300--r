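#' ST-segment analysis window specification
#'
#' The ST-segment pattern vector is read from a fixed window anchored at the
#' per-beat stable fiducial point F.  The default window runs from F + 40 ms
#' to F + 160 ms and is resampled to 32 equally spaced points (endpoints
#' included), which is also the dimension of the orthonormal bases.
#'
#' @param start_offset_ms window start, in ms after the fiducial point.
#' @param end_offset_ms window end, in ms after the fiducial point.
#' @param n_samples number of equally spaced samples spanning the window.
#' @return An object of class `st_window_spec`.
#' @export
st_window_spec <- function(start_offset_ms = 40, end_offset_ms = 160,
                           n_samples = 32L) {
  if (end_offset_ms <= start_offset_ms)
    stop("window end must lie after window start")
  if (n_samples < 2) stop("n_samples must be >= 2")
  structure(list(start_offset_ms = start_offset_ms,
                 end_offset_ms   = end_offset_ms,
                 n_samples       = as.integer(n_samples)),
            class = "st_window_spec")
}

#' @export
print.st_window_spec <- function(x, ...) {
  cat(sprintf("ST window: F+%g ms to F+%g ms, %d samples\n",
              x$start_offset_ms, x$end_offset_ms, x$n_samples))
  invisible(x)
}

#' Evaluate a Legendre polynomial
#'
#' Computes P_n(x) by the three-term recurrence
#' (j+1) P_{j+1}(x) = (2j+1) x P_j(x) - j P_{j-1}(x), seeded with
#' P_0(x) = 1 and P_1(x) = x.
#'
#' @param n polynomial degree (non-negative integer).
#' @param x evaluation points; the polynomials are orthogonal on \[-1, 1\]
#'   (values outside that interval are evaluated but flagged with a warning).
#' @return numeric vector of P_n(x), same length as `x`.
#' @examples
#' legendre_polynomial(2, c(-1, 0, 1))  # 1, -0.5, 1
#' @export
legendre_polynomial <- function(n, x) {
  if (length(n) != 1 || is.na(n) || n < 0 || n != round(n))
    stop("n must be a single non-negative integer")
  if (any(abs(x) > 1)) warning("evaluating Legendre polynomial outside [-1, 1]")
  n <- as.integer(n)
  p_prev <- rep(1, length(x))             # P_0
  if (n == 0L) return(p_prev)
  p_cur <- x                              # P_1
  if (n == 1L) return(p_cur)
  for (j in 1:(n - 1L)) {
    p_next <- ((2 * j + 1) * x * p_cur - j * p_prev) / (j + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  p_cur
}

#' Monomial design matrix on equally spaced abscissae
#'
#' Column j holds the monomial x^(j-1) evaluated at the M equally spaced
#' abscissae x_i = 2 (i - 1) / (M - 1) - 1, i = 1..M, spanning \[-1, 1\]
#' endpoint-inclusive.  This is the raw (ill-conditioned) input that the
#' Gram-Schmidt step orthonormalizes into the LPT basis.
#'
#' @param M number of samples (rows) and monomials (columns); M >= 2.
#' @return M x M numeric matrix with attribute `abscissae`.
#' @export
build_monomial_matrix <- function(M = 32L) {
  if (length(M) != 1 || is.na(M) || M < 2 || M != round(M))
    stop("M must be a single integer >= 2")
  M <- as.integer(M)
  x <- 2 * (seq_len(M) - 1) / (M - 1) - 1
  mat <- outer(x, 0:(M - 1L), `^`)
  attr(mat, "abscissae") <- x
  class(mat) <- c("monomial_matrix", class(mat))
  mat
}

new_basis_matrix <- function(entries, kind, window, weights) {
  structure(list(entries = entries, kind = kind, window = window,
                 weights = weights),
            class = "basis_matrix")
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat(sprintf("%s basis: %d x %d, window F+%g..F+%g ms\n", x$kind,
              nrow(x$entries), ncol(x$entries),
              x$window$start_offset_ms, x$window$end_offset_ms))
  invisible(x)
}

#' Weighted modified Gram-Schmidt orthonormalization
#'
#' Orthonormalizes the monomial columns sequentially (modified Gram-Schmidt:
#' each column is orthogonalized against the already-orthonormalized columns,
#' which is numerically far better behaved on the ill-conditioned monomial
#' matrix than the classical variant).  Column j is normalized to unit norm
#' under the weighted inner product sum_k w_k psi_kj^2, so column k is the
#' discretized orthonormal Legendre polynomial of degree k - 1.  Each
#' column's sign is fixed so its value at x = +1 (last row) is >= 0,
#' matching P_n(1) = 1.
#'
#' @param m monomial matrix from [build_monomial_matrix()] (any numeric
#'   matrix with linearly independent columns is accepted).
#' @param weights positive weights, one per row (discretized weighting
#'   function; default all 1).
#' @param window window specification attached to the resulting basis.
#' @return A `basis_matrix` of kind `"LPT"`.
#' @export
gram_schmidt_orthonormalize <- function(m, weights = rep(1, nrow(m)),
                                        window = st_window_spec(
                                          n_samples = nrow(m))) {
  m <- unclass(m)
  attr(m, "abscissae") <- NULL
  M <- nrow(m)
  if (length(weights) != M || any(weights <= 0))
    stop("weights must be positive, one per row")
  q <- matrix(0, M, ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    # two modified-GS sweeps ("twice is enough"): one sweep leaves the
    # highest-degree columns of the ill-conditioned monomial matrix with
    # O(1e-3) orthogonality loss; the second restores machine precision
    if (j > 1) for (sweep in 1:2) for (k in seq_len(j - 1)) {
      v <- v - sum(weights * q[, k] * v) * q[, k]
    }
    nrm <- sqrt(sum(weights * v^2))
    if (nrm < 1e-300)
      stop("numerical degeneracy: column ", j, " is linearly dependent")
    v <- v / nrm
    if (v[M] < 0) v <- -v
    q[, j] <- v
  }
  new_basis_matrix(q, "LPT", window, weights)
}

#' Build the discrete orthonormal Legendre-polynomial (LPT) basis
#'
#' Convenience wrapper: monomials on M equally spaced abscissae of \[-1, 1\],
#' then weighted modified Gram-Schmidt.  Columns 1..3 are the discretized
#' constant, linear and quadratic shapes that map directly onto ST-segment
#' level, slope and scooping.
#'
#' @inheritParams build_monomial_matrix
#' @inheritParams gram_schmidt_orthonormalize
#' @return A `basis_matrix` of kind `"LPT"`.
#' @examples
#' b <- lpt_basis(32)
#' orthonormality_error(b, 10)
#' @export
lpt_basis <- function(M = 32L, weights = rep(1, M),
                      window = st_window_spec(n_samples = M)) {
  gram_schmidt_orthonormalize(build_monomial_matrix(M), weights, window)
}

#' Orthonormality error of a basis
#'
#' Forms the weighted Gram matrix of the first `first_k` columns and reports
#' the largest deviation of its diagonal from 1 and the largest off-diagonal
#' magnitude.  Numerical orthogonality loss grows with the basis-function
#' number, so `first_k` bounds the portion checked.
#'
#' @param b a `basis_matrix`, or a plain numeric matrix (unit weights).
#' @param first_k number of leading columns to check.
#' @return list with `max_diag_error` and `max_offdiag_error`.
#' @export
orthonormality_error <- function(b, first_k = ncol(entries_of(b))) {
  e <- entries_of(b)
  w <- if (inherits(b, "basis_matrix")) b$weights else rep(1, nrow(e))
  if (first_k > ncol(e)) stop("first_k exceeds number of basis functions")
  e <- e[, seq_len(first_k), drop = FALSE]
  g <- crossprod(e * sqrt(w))
  list(max_diag_error   = max(abs(diag(g) - 1)),
       max_offdiag_error = if (first_k > 1) max(abs(g[upper.tri(g)])) else 0)
}

entries_of <- function(b) {
  if (inherits(b, "basis_matrix")) b$entries else as.matrix(b)
}
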