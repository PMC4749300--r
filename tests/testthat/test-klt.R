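test_that("reject_outliers keeps clean patterns and drops gross deviants", {
  pat <- matrix(5, 100, 8)
  expect_equal(nrow(reject_outliers(pat)), 100)
  set.seed(1)
  pat <- matrix(rnorm(99 * 8), 99, 8)
  pat <- rbind(pat, rep(1000, 8))        # one gross deviant
  kept <- reject_outliers(pat, robust_z_threshold = 4)
  expect_equal(nrow(kept), 99)
  expect_true(all(abs(kept) < 100))
  single <- matrix(rnorm(8), 1, 8)
  expect_equal(reject_outliers(single), single)
})

test_that("build_classes forms one mean per interval and pools leads", {
  cst <- matrix(7, 4, 8)
  cl <- build_classes(list(list(patterns = cst, label = "no_deviation"),
                           list(patterns = cst, label = "no_deviation")))
  expect_length(cl, 2)
  expect_equal(cl[[1]]$mean, rep(7, 8))
  cl2 <- build_classes(list(list(patterns = rbind(rep(0, 8), rep(2, 8)),
                                 label = "ischaemic_deviation")))
  expect_equal(cl2[[1]]$mean, rep(1, 8))
  corpus <- make_training_corpus(10, 5, 20, beats_per_interval = 3,
                                 seed = 3)
  expect_length(build_classes(corpus), 35)
  expect_warning(
    cl3 <- build_classes(list(list(patterns = cst[0, ], label = "x"),
                              list(patterns = cst, label = "y"))),
    "empty interval")
  expect_length(cl3, 1)
})

test_that("robust_covariance matches hand expansion and brute force", {
  v <- c(1, -2, 3, 0.5)
  cl <- list(list(label = "a", mean = v, n_members = 1),
             list(label = "b", mean = -v, n_members = 50))
  rc <- robust_covariance(cl)
  expect_equal(rc$matrix, outer(v, v))   # classes unweighted by size
  expect_equal(rc$grand_mean, rep(0, 4))
  same <- list(list(label = "a", mean = v, n_members = 2),
               list(label = "b", mean = v, n_members = 2))
  expect_equal(robust_covariance(same)$matrix, matrix(0, 4, 4))
  # 20-class toy set against the independent textbook estimator (stats::cov)
  set.seed(11)
  means <- matrix(rnorm(20 * 8), 20, 8)
  cl20 <- lapply(seq_len(20), function(i)
    list(label = "x", mean = means[i, ], n_members = 1))
  expect_lt(max(abs(robust_covariance(cl20)$matrix -
                    stats::cov(means) * 19 / 20)), 1e-10)
  expect_error(robust_covariance(cl20[1]), "at least 2")
})

test_that("covariance is invariant under uniform translation of classes", {
  set.seed(12)
  means <- matrix(rnorm(10 * 6), 10, 6)
  cl <- lapply(seq_len(10), function(i)
    list(label = "x", mean = means[i, ], n_members = 1))
  shift <- rnorm(6) * 100
  cl_sh <- lapply(cl, function(c) {c$mean <- c$mean + shift; c})
  expect_equal(robust_covariance(cl)$matrix,
               robust_covariance(cl_sh)$matrix, tolerance = 1e-9)
})

test_that("class-mean covariance is not the pooled-sample covariance", {
  # guard against the obvious mis-implementation: two intervals with very
  # different within-interval spread but identical means
  i1 <- matrix(rnorm(50 * 4, sd = 10), 50, 4)
  i2 <- matrix(rnorm(4 * 4, sd = 0.01), 4, 4)
  i1 <- sweep(i1, 2, colMeans(i1))       # exact zero means
  i2 <- sweep(i2, 2, colMeans(i2)) + 1
  cl <- build_classes(list(list(patterns = i1, label = "a"),
                           list(patterns = i2, label = "b")))
  rc <- robust_covariance(cl)$matrix
  pooled <- stats::cov(rbind(i1, i2))
  expect_gt(max(abs(rc - pooled)), 1)
})

test_that("derive_klt orders, orients and reconstructs", {
  d <- derive_klt(diag(c(4, 1, 0, 0)))
  expect_equal(d$eigenvalues, c(4, 1, 0, 0))
  expect_equal(abs(d$basis$entries[, 1]), c(1, 0, 0, 0))
  v <- c(3, -1, 2, 0.5, -2, 1, 0, 4)
  r1 <- derive_klt(outer(v, v))
  expect_equal(r1$eigenvalues[1], sum(v^2))
  expect_lt(max(abs(abs(r1$basis$entries[, 1]) - abs(v) / sqrt(sum(v^2)))),
            1e-9)
  set.seed(4)
  a <- matrix(rnorm(64), 8, 8)
  spd <- crossprod(a) + diag(8)
  k <- derive_klt(spd)
  expect_true(all(diff(k$eigenvalues) <= 1e-12))
  recon <- k$basis$entries %*% diag(k$eigenvalues) %*% t(k$basis$entries)
  expect_lt(max(abs(recon - spd)), 1e-9)
  expect_lt(abs(sum(k$eigenvalues) - sum(diag(spd))),
            1e-9 * sum(diag(spd)))
  err <- orthonormality_error(k$basis)
  expect_lt(max(err$max_diag_error, err$max_offdiag_error), 1e-9)
  expect_error(derive_klt(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("KLT eigenvector signs are anchored to the LPT shapes", {
  corpus <- make_training_corpus(seed = 21)
  k <- train_klt(corpus)$klt
  ref <- lpt_basis(32)$entries
  for (j in 1:3)
    expect_gte(sum(k$basis$entries[, j] * ref[, j]), 0)
})

test_that("leading KLT subspace recovers the injected LPT subspace", {
  # class means built as grand mean + random combinations of the first
  # three LPT shapes: principal angles of the leading 3-subspace vs LPT
  # columns 1-3 must be tiny
  set.seed(31)
  L <- lpt_basis(32)$entries[, 1:3]
  means <- t(sapply(1:25, function(i) 50 + L %*% rnorm(3, sd = 100)))
  cl <- lapply(seq_len(25), function(i)
    list(label = "x", mean = means[i, ], n_members = 1))
  k <- derive_klt(robust_covariance(cl))
  sv <- svd(crossprod(L, k$basis$entries[, 1:3]))$d
  angles <- acos(pmin(1, sv))
  expect_lt(max(angles), 1e-3)
})

test_that("coefficient_stds matches the two-pass oracle and documents the
           n-1 divisor", {
  expect_warning(s <- coefficient_stds(matrix(3, 5, 32), lpt32),
                 "floored")
  expect_equal(s, rep(1e-12, 9))
  a <- 25
  v <- lpt32$entries[, 1] * a
  s2 <- coefficient_stds(rbind(v, -v), lpt32)
  expect_equal(s2[1], a * sqrt(2))       # sd({+a, -a}) with divisor n-1
  expect_lt(max(s2[-1]), 1e-9)           # other coefficients are ~0
  set.seed(41)
  corpus <- matrix(rnorm(10000 * 32, sd = 30), 10000, 32)
  s3 <- coefficient_stds(corpus, lpt32)
  coeffs <- corpus %*% lpt32$entries[, 1:9]
  oracle <- sqrt(colSums(sweep(coeffs, 2, colMeans(coeffs))^2) / 9999)
  expect_equal(s3, oracle, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("train_klt returns a coherent model triple", {
  corpus <- make_training_corpus(10, 5, 15, beats_per_interval = 10,
                                 seed = 8)
  m <- train_klt(corpus)
  expect_s3_class(m$klt, "klt_model")
  expect_equal(m$klt$basis$kind, "KLT")
  expect_length(m$norm$rho, 9)
  expect_true(all(m$norm$rho > 0) && all(m$norm$theta > 0))
  expect_true(all(diff(m$klt$eigenvalues) <= 1e-9))
})
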