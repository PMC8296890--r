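#' Build the binary feature matrix for the risk model
#'
#' One 0/1 column per structural alert plus the single `high_dose` column
#' (daily dose >= cutoff). Drugs with missing dose are excluded (reported via
#' attribute `n_dose_missing`), matching the exclude-and-report policy.
#'
#' @param screen An [AlertScreen].
#' @param rule A [DoseRule].
#' @return A [FeatureMatrix].
#' @export
buildFeatureMatrix <- function(screen, rule = doseRule()) {
  stopifnot(is(screen, "AlertScreen"))
  m <- matchMatrix(screen)
  if (ncol(m) == 0) stop("empty alert set")
  cd <- colData(screen)
  dose <- highDoseFlag(cd$daily_dose_mg, rule, missing = "na")
  keep <- !is.na(dose)
  x <- cbind(high_dose = 1 * dose[keep], 1 * m[keep, , drop = FALSE])
  rownames(x) <- cd$drug_id[keep]
  fm <- new("FeatureMatrix", x = x,
            labels = as.integer(cd$label[keep] == "AD_POSITIVE"))
  attr(fm, "n_dose_missing") <- sum(!keep)
  fm
}

#' Assemble a feature matrix directly from components
#'
#' Used by the synthetic-data path and by tests that bypass the chemistry
#' layer: `alert_matrix` is the drugs x alerts indicator matrix.
#'
#' @param alert_matrix Logical/0-1 matrix, drugs x alerts, with column names.
#' @param high_dose Logical/0-1 per-drug high-dose flag.
#' @param labels Character (`AD_POSITIVE`/`AD_NEGATIVE`) or 0/1 labels.
#' @return A [FeatureMatrix].
#' @export
featureMatrix <- function(alert_matrix, high_dose, labels) {
  if (is.character(labels)) labels <- labels == "AD_POSITIVE"
  x <- cbind(high_dose = 1 * as.numeric(high_dose),
             1 * as.matrix(alert_matrix))
  new("FeatureMatrix", x = x, labels = as.integer(labels))
}

#' @describeIn FeatureMatrix-class drugs x features dimensions
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@x))

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@x), "drugs x", ncol(object@x),
      "features;", sum(object@labels), "AD-positive\n")
})

.subsetFM <- function(fm, idx)
  new("FeatureMatrix", x = fm@x[idx, , drop = FALSE],
      labels = fm@labels[idx])

#' Model configuration
#'
#' Defaults: the depth x learning-rate x iterations grid searched by
#' [gridSearchCV()], 5 folds, 80/20 split, 1000 permutations and 1000 CV
#' repetitions, seed 42 — every random draw in the model pipeline flows from
#' this one seed.
#'
#' @param grid data.frame of hyperparameter combinations.
#' @param k_folds Cross-validation folds (>= 2).
#' @param split_fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param n_permutations,n_cv_repetitions Arm sizes of the permutation test.
#' @return A validated config list.
#' @export
modelConfig <- function(grid = defaultGrid(), k_folds = 5,
                        split_fraction = 0.8, seed = 42,
                        n_permutations = 1000, n_cv_repetitions = 1000) {
  stopifnot(k_folds >= 2, split_fraction > 0, split_fraction < 1,
            nrow(grid) >= 1)
  list(grid = grid, k_folds = k_folds, split_fraction = split_fraction,
       seed = as.integer(seed), n_permutations = n_permutations,
       n_cv_repetitions = n_cv_repetitions)
}

#' Default hyperparameter grid
#'
#' depth {2,4,6} x learning rate {0.03,0.1,0.3} x iterations {100,300},
#' balanced class weighting on throughout — a small grid suited to a small
#' binary categorical feature space.
#'
#' @return data.frame with columns `depth`, `learning_rate`, `n_iter`,
#'   `class_weight`.
#' @export
defaultGrid <- function() {
  g <- expand.grid(depth = c(2, 4, 6), learning_rate = c(0.03, 0.1, 0.3),
                   n_iter = c(100, 300), KEEP.OUT.ATTRS = FALSE)
  g$class_weight <- TRUE
  g
}

#' Stratified train/test split
#'
#' Per class, `floor(fraction * n_class)` drugs go to training (for the
#' 50/357 drug set at 0.8 this gives the 325/82 split); the partition is
#' exact and reproducible for a fixed seed.
#'
#' @param fm A [FeatureMatrix].
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return `list(train =, test =)` of [FeatureMatrix] objects.
#' @export
stratifiedSplit <- function(fm, fraction = 0.8, seed = 42) {
  stopifnot(is(fm, "FeatureMatrix"), fraction > 0, fraction < 1)
  y <- fm@labels
  if (min(table(y)) < 2) stop("each class needs at least 2 members")
  rng <- .seededRNG(seed)
  train_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    n_train <- max(1L, floor(fraction * length(idx)))
    if (n_train >= length(idx)) n_train <- length(idx) - 1L
    train_idx <- c(train_idx, .rngSample(rng, idx, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = .subsetFM(fm, train_idx),
       test = .subsetFM(fm, setdiff(seq_along(y), train_idx)))
}

## Local RNG helpers: an environment holding a .Random.seed so package RNG
## never touches (or depends on) the caller's global stream.
.seededRNG <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

.withRNG <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

.rngSample <- function(rng, x, size) .withRNG(rng, sample(x, size))

## Stratified k-fold assignment: per class, shuffled then dealt round-robin.
.stratifiedFolds <- function(y, k, rng) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) stop("class with fewer members than folds")
    idx <- .withRNG(rng, sample(idx))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.balancedAccuracy <- function(y, pred) {
  sens <- mean(pred[y == 1] == 1)
  spec <- mean(pred[y == 0] == 0)
  (sens + spec) / 2
}

.cvScore <- function(fm, params, k, rng) {
  fold <- .stratifiedFolds(fm@labels, k, rng)
  scores <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- gbtFit(fm@x[tr, , drop = FALSE], fm@labels[tr],
                    depth = params$depth,
                    learning_rate = params$learning_rate,
                    n_iter = params$n_iter,
                    class_weight = params$class_weight)
    pred <- predict(model, fm@x[!tr, , drop = FALSE], type = "class")
    scores[f] <- .balancedAccuracy(fm@labels[!tr], pred)
  }
  mean(scores)
}

#' Grid-search hyperparameters by cross-validated balanced accuracy
#'
#' For every grid point, mean balanced accuracy over `k_folds` stratified
#' folds; the argmax is returned with a deterministic tie-break (first in
#' grid order). All grid points are evaluated on the same fold assignment so
#' the comparison is paired.
#'
#' @param fm Training [FeatureMatrix] (both classes present).
#' @param config A [modelConfig()].
#' @return `list(best = params, table = data.frame of CV scores)`.
#' @export
gridSearchCV <- function(fm, config = modelConfig()) {
  stopifnot(is(fm, "FeatureMatrix"))
  if (length(unique(fm@labels)) < 2) stop("training set needs both classes")
  rng <- .seededRNG(config$seed)
  grid <- config$grid
  scores <- numeric(nrow(grid))
  fold_rng_state <- rng$state
  for (i in seq_len(nrow(grid))) {
    rng$state <- fold_rng_state  # same folds for every grid point
    scores[i] <- .cvScore(fm, as.list(grid[i, ]), config$k_folds, rng)
  }
  tab <- cbind(grid, cv_balanced_accuracy = scores)
  best <- as.list(grid[which.max(scores), ])
  list(best = best, table = tab)
}

#' Classifier test metrics
#'
#' Fits the boosted model on the training set with the chosen hyperparameters
#' and evaluates on the held-out test set: sensitivity, specificity, PPV,
#' NPV, balanced accuracy (= (sensitivity + specificity)/2, exactly), MCC,
#' and AUC by the rank statistic with average-rank tie handling. AUC is `NA`
#' when the test set has a single class.
#'
#' @param train,test Disjoint [FeatureMatrix] objects.
#' @param params Hyperparameter list (`depth`, `learning_rate`, `n_iter`,
#'   `class_weight`), e.g. `gridSearchCV(...)$best`.
#' @return `list(model =, metrics = named numeric, confusion =
#'   ContingencyTable)`.
#' @export
trainAndEvaluate <- function(train, test, params) {
  model <- gbtFit(train@x, train@labels, depth = params$depth,
                  learning_rate = params$learning_rate,
                  n_iter = params$n_iter, class_weight = params$class_weight)
  margin <- gbtMargin(model, test@x)
  pred <- as.integer(margin > 0)
  y <- test@labels
  ct <- contingencyTable(tp = sum(y == 1 & pred == 1),
                         fn = sum(y == 1 & pred == 0),
                         fp = sum(y == 0 & pred == 1),
                         tn = sum(y == 0 & pred == 0))
  list(model = model, confusion = ct,
       metrics = modelMetrics(ct, scores = margin, labels = y))
}

#' Metrics from a confusion table (plus optional AUC from scores)
#'
#' @param ct A [ContingencyTable].
#' @param scores Optional continuous scores for AUC.
#' @param labels 0/1 labels aligned with `scores`.
#' @return Named numeric: sensitivity, specificity, ppv, npv,
#'   balanced_accuracy, mcc, auc.
#' @export
modelMetrics <- function(ct, scores = NULL, labels = NULL) {
  met <- confusionMetrics(ct)
  bal <- (met[["sensitivity"]] + met[["specificity"]]) / 2
  tp <- ct@tp; fn <- ct@fn; fp <- ct@fp; tn <- ct@tn
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  auc <- NA_real_
  if (!is.null(scores) && !is.null(labels) && length(unique(labels)) == 2) {
    r <- rank(scores)  # average ranks on ties
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  c(sensitivity = met[["sensitivity"]], specificity = met[["specificity"]],
    ppv = met[["ppv"]], npv = met[["npv"]], balanced_accuracy = bal,
    mcc = mcc, auc = auc)
}

#' Permutation-null validation of the classifier
#'
#' Builds the empirical null by refitting the tuned configuration on
#' `n_permutations` label-reshuffled copies of the training data (each scored
#' by stratified k-fold CV balanced accuracy) and compares against
#' `n_cv_repetitions` repeated k-fold CVs on the intact labels with fresh
#' fold sampling, using a two-sided Welch t-test. Label-reshuffled balanced
#' accuracy is centred on 0.5 regardless of class imbalance.
#'
#' @param fm Training [FeatureMatrix].
#' @param params Tuned hyperparameters (re-used in both arms, not re-tuned
#'   per permutation).
#' @param n_permutations,n_cv_repetitions Arm sizes (each >= 2).
#' @param k_folds Folds per CV.
#' @param seed Integer seed for reshuffles and fold draws.
#' @return List with `permuted_scores`, `cv_scores`, `mean_permuted`,
#'   `mean_cv`, `t_statistic`, `p_value`.
#' @export
permutationTest <- function(fm, params, n_permutations = 1000,
                            n_cv_repetitions = 1000, k_folds = 5,
                            seed = 42) {
  stopifnot(n_permutations >= 2, n_cv_repetitions >= 2)
  rng <- .seededRNG(seed)
  perm <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    shuffled <- new("FeatureMatrix", x = fm@x,
                    labels = .withRNG(rng, sample(fm@labels)))
    perm[i] <- .cvScore(shuffled, params, k_folds, rng)
  }
  cv <- numeric(n_cv_repetitions)
  for (i in seq_len(n_cv_repetitions))
    cv[i] <- .cvScore(fm, params, k_folds, rng)
  tt <- stats::t.test(cv, perm, alternative = "two.sided", var.equal = FALSE)
  list(permuted_scores = perm, cv_scores = cv,
       mean_permuted = mean(perm), mean_cv = mean(cv),
       t_statistic = unname(tt$statistic), p_value = tt$p.value)
}
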