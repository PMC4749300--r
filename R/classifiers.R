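# Classifier roster behind a uniform train/predict interface.  kNN, the
# Gini classification tree, the least-squares SVM with degree-2 polynomial
# kernel and the kernel-density naive Bayes are implemented here (no
# class/rpart/e1071 in the target environment); QDA is MASS::qda.

knn_predict <- function(train_x, train_y, test_x, k) {
  train_y <- as.character(train_y)
  apply(test_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    # vote tie: class with the smallest mean neighbor distance wins
    md <- vapply(top, function(cl) mean(d[nn][train_y[nn] == cl]), numeric(1))
    top[which.min(md)]
  })
}

gini_impurity <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

grow_tree <- function(x, y, depth = 0, max_depth = 6, min_node = 5) {
  y <- as.character(y)
  maj <- names(sort(table(y), decreasing = TRUE))[1]
  if (depth >= max_depth || length(y) < 2 * min_node ||
      length(unique(y)) == 1)
    return(list(leaf = TRUE, class = maj))
  n <- length(y)
  best <- list(gain = 0)
  base <- gini_impurity(y)
  for (f in seq_len(ncol(x))) {
    v <- x[, f]
    cuts <- unique(stats::quantile(v, probs = seq(0.05, 0.95, by = 0.05),
                                   names = FALSE))
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left)
      if (nl < min_node || n - nl < min_node) next
      g <- base - nl / n * gini_impurity(y[left]) -
        (n - nl) / n * gini_impurity(y[!left])
      if (g > best$gain + 1e-12) best <- list(gain = g, f = f, cut = cut)
    }
  }
  if (best$gain <= 0) return(list(leaf = TRUE, class = maj))
  left <- x[, best$f] <= best$cut
  list(leaf = FALSE, f = best$f, cut = best$cut, class = maj,
       left = grow_tree(x[left, , drop = FALSE], y[left], depth + 1,
                        max_depth, min_node),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], depth + 1,
                         max_depth, min_node))
}

tree_predict <- function(node, x) {
  apply(x, 1, function(q) {
    nd <- node
    while (!nd$leaf) nd <- if (q[nd$f] <= nd$cut) nd$left else nd$right
    nd$class
  })
}

lssvm_train <- function(x, y, gamma = 1, degree = 2) {
  classes <- sort(unique(as.character(y)))
  if (length(classes) != 2) stop("LS-SVM here is binary")
  yy <- ifelse(as.character(y) == classes[2], 1, -1)
  n <- nrow(x)
  K <- (1 + tcrossprod(x))^degree
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / gamma))
  sol <- solve(A, c(0, yy))
  list(alpha = sol[-1], b = sol[1], x = x, classes = classes,
       degree = degree)
}

lssvm_predict <- function(model, test_x) {
  Kt <- (1 + test_x %*% t(model$x))^model$degree
  f <- as.numeric(Kt %*% model$alpha + model$b)
  ifelse(f >= 0, model$classes[2], model$classes[1])
}

nbc_kde_train <- function(x, y) {
  y <- as.character(y)
  classes <- sort(unique(y))
  lapply(stats::setNames(classes, classes), function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(prior = nrow(xc) / nrow(x),
         values = xc,
         bw = apply(xc, 2, function(v) max(stats::bw.nrd0(v), 1e-6)))
  })
}

nbc_kde_predict <- function(model, test_x) {
  scores <- vapply(names(model), function(cl) {
    m <- model[[cl]]
    apply(test_x, 1, function(q) {
      ll <- 0
      for (f in seq_along(q)) {
        dens <- mean(stats::dnorm(q[f], m$values[, f], m$bw[f]))
        ll <- ll + log(max(dens, 1e-300))
      }
      ll + log(m$prior)
    })
  }, numeric(nrow(test_x)))
  if (nrow(test_x) == 1) scores <- matrix(scores, nrow = 1,
                                          dimnames = list(NULL, names(model)))
  names(model)[max.col(scores, ties.method = "first")]
}

#' Available episode classifiers
#'
#' Identifiers accepted by [crossvalidate()]: `"3nn"`, `"4nn"`, `"5nn"`
#' (k-nearest neighbors, Euclidean, vote ties broken by smallest mean
#' neighbor distance), `"ct"` (Gini classification tree), `"qda"`
#' (quadratic discriminant analysis via MASS), `"svm"` (least-squares SVM
#' with degree-2 polynomial kernel), `"nbc"` (naive Bayes with per-feature
#' Gaussian kernel density estimates).
#'
#' @return character vector of classifier ids.
#' @export
classifier_ids <- function() c("3nn", "4nn", "5nn", "ct", "qda", "svm", "nbc")

fit_and_predict <- function(id, train_x, train_y, test_x) {
  switch(id,
    "3nn" = knn_predict(train_x, train_y, test_x, 3),
    "4nn" = knn_predict(train_x, train_y, test_x, 4),
    "5nn" = knn_predict(train_x, train_y, test_x, 5),
    "ct"  = tree_predict(grow_tree(train_x, train_y), test_x),
    "qda" = as.character(stats::predict(
      MASS::qda(train_x, grouping = factor(train_y)), test_x)$class),
    "svm" = lssvm_predict(lssvm_train(train_x, train_y), test_x),
    "nbc" = nbc_kde_predict(nbc_kde_train(train_x, train_y), test_x),
    stop("unknown classifier id: ", id))
}
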