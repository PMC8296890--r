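## Gradient-boosted decision trees for binary features, logistic loss.
## Second-order (Newton) boosting as in the usual GBDT formulation: per node
## G = sum of gradients, H = sum of hessians, leaf value -G/(H + lambda),
## split gain = GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l). Features are 0/1 so a
## node splits a feature at most once and candidate scans vectorize to two
## crossprods per node. Deterministic: no row/column subsampling.

.gbtBuildTree <- function(X, g, h, depth, lambda, lr, min_hessian) {
  build <- function(mask, depth_left) {
    G <- sum(g[mask]); H <- sum(h[mask])
    val <- -G / (H + lambda) * lr
    if (depth_left == 0L || sum(mask) < 2L)
      return(list(leaf = TRUE, value = val))
    Xm <- X[mask, , drop = FALSE]
    G1 <- as.numeric(crossprod(Xm, g[mask]))
    H1 <- as.numeric(crossprod(Xm, h[mask]))
    G0 <- G - G1; H0 <- H - H1
    feasible <- H1 >= min_hessian & H0 >= min_hessian
    gain <- ifelse(feasible,
                   G1^2 / (H1 + lambda) + G0^2 / (H0 + lambda) -
                     G^2 / (H + lambda),
                   -Inf)
    j <- which.max(gain)  # first max = deterministic tie-break in column order
    if (!is.finite(gain[j]) || gain[j] <= 1e-12)
      return(list(leaf = TRUE, value = val))
    on <- X[, j] == 1
    list(leaf = FALSE, feature = j, value = val,
         left = build(mask & !on, depth_left - 1L),   # feature == 0
         right = build(mask & on, depth_left - 1L))   # feature == 1
  }
  build(rep(TRUE, nrow(X)), as.integer(depth))
}

.gbtPredictTree <- function(node, X, mask = rep(TRUE, nrow(X)),
                            out = numeric(nrow(X))) {
  if (node$leaf) { out[mask] <- node$value; return(out) }
  on <- X[, node$feature] == 1
  out <- .gbtPredictTree(node$left, X, mask & !on, out)
  .gbtPredictTree(node$right, X, mask & on, out)
}

#' Fit a gradient-boosted tree classifier
#'
#' Boosted depth-limited decision trees on binary features with logistic loss
#' and optional balanced class weighting (`w = n/(2 n_class)`), the
#' configuration the risk model grid searches over. The fit is fully
#' deterministic given the data.
#'
#' @param x Numeric 0/1 matrix, samples x features (column names required).
#' @param y 0/1 labels (1 = AD-positive).
#' @param depth Maximum tree depth.
#' @param learning_rate Shrinkage applied to every leaf value.
#' @param n_iter Number of boosting iterations (trees).
#' @param class_weight Balanced class weighting switch (default `TRUE`; with
#'   a 50:357 imbalance the minority class would otherwise be ignored).
#' @param lambda L2 regularization on leaf values.
#' @return A `gbtModel` object; see [gbtMargin()], [predict.gbtModel()].
#' @export
gbtFit <- function(x, y, depth = 4, learning_rate = 0.1, n_iter = 100,
                   class_weight = TRUE, lambda = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y), !is.null(colnames(x)))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), length(unique(y)) == 2)
  n <- length(y)
  w <- if (class_weight) {
    ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  } else rep(1, n)
  base <- log(sum(w * y) / sum(w * (1 - y)))
  margin <- rep(base, n)
  trees <- vector("list", n_iter)
  min_hessian <- 1e-6
  for (t in seq_len(n_iter)) {
    p <- 1 / (1 + exp(-margin))
    g <- w * (p - y)
    h <- w * p * (1 - p)
    tree <- .gbtBuildTree(x, g, h, depth, lambda, learning_rate, min_hessian)
    trees[[t]] <- tree
    margin <- margin + .gbtPredictTree(tree, x)
  }
  structure(list(trees = trees, base_score = base,
                 feature_names = colnames(x),
                 params = list(depth = depth, learning_rate = learning_rate,
                               n_iter = n_iter, class_weight = class_weight,
                               lambda = lambda)),
            class = "gbtModel")
}

#' Margin (log-odds) output of a boosted model
#'
#' @param model A `gbtModel`.
#' @param x Feature matrix with the training columns.
#' @return Numeric vector of raw margins; `base_score + sum of tree outputs`.
#' @export
gbtMargin <- function(model, x) {
  stopifnot(inherits(model, "gbtModel"))
  x <- x[, model$feature_names, drop = FALSE]
  out <- rep(model$base_score, nrow(x))
  for (tree in model$trees) out <- out + .gbtPredictTree(tree, x)
  out
}

#' Predict from a boosted model
#'
#' @param object A `gbtModel`.
#' @param x Feature matrix.
#' @param type `"prob"` (default), `"margin"` or `"class"` (threshold 0.5).
#' @param ... Ignored.
#' @export
predict.gbtModel <- function(object, x, type = c("prob", "margin", "class"),
                             ...) {
  type <- match.arg(type)
  m <- gbtMargin(object, x)
  switch(type,
         margin = m,
         prob = 1 / (1 + exp(-m)),
         class = as.integer(m > 0))
}

#' @export
print.gbtModel <- function(x, ...) {
  cat("gbtModel:", length(x$trees), "trees, depth", x$params$depth,
      ", learning rate", x$params$learning_rate, "\n")
  invisible(x)
}

## Exact tree-path decomposition: walking from the root, each split's change
## in the node Newton value is credited to the split feature; telescoping
## makes base + rowSums(phi) equal the margin exactly.
.gbtTreeAttrib <- function(node, X, phi, mask) {
  if (node$leaf) return(phi)
  on <- X[, node$feature] == 1
  for (side in list(list(child = node$left, m = mask & !on),
                    list(child = node$right, m = mask & on))) {
    delta <- side$child$value - node$value
    if (any(side$m)) phi[side$m, node$feature] <- phi[side$m, node$feature] + delta
    phi <- .gbtTreeAttrib(side$child, X, phi, side$m)
  }
  phi
}

#' Additive per-feature attributions (tree-path decomposition)
#'
#' For every sample, credits each split along its root-to-leaf path with the
#' change in the node value, per tree, and sums over trees. Attributions are
#' exact on the margin scale: `base_value + rowSums(phi)` equals
#' [gbtMargin()] to machine precision (local accuracy).
#'
#' @param model A `gbtModel`.
#' @param x Feature matrix, samples x features.
#' @return List with `phi` (samples x features matrix), `base_value`, and
#'   `ranking` (features ordered by decreasing mean absolute attribution).
#' @export
featureAttributions <- function(model, x) {
  stopifnot(inherits(model, "gbtModel"))
  if (!all(model$feature_names %in% colnames(x)))
    stop("feature mismatch with the trained model")
  x <- x[, model$feature_names, drop = FALSE]
  phi <- matrix(0, nrow(x), ncol(x),
                dimnames = list(rownames(x), colnames(x)))
  base <- model$base_score
  for (tree in model$trees) {
    phi <- .gbtTreeAttrib(tree, x, phi, rep(TRUE, nrow(x)))
    base <- base + tree$value  # root Newton value joins the base
  }
  mean_abs <- colMeans(abs(phi))
  list(phi = phi, base_value = base,
       ranking = names(sort(mean_abs, decreasing = TRUE)),
       mean_abs = mean_abs)
}
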