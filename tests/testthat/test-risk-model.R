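test_that("feature matrix has one column per alert plus the dose flag", {
  screen <- smallScreen()
  fm <- buildFeatureMatrix(screen, doseRule(100))
  expect_s4_class(fm, "FeatureMatrix")
  expect_identical(ncol(fm@x), nrow(screen) + 1L)
  expect_identical(colnames(fm@x)[1], "high_dose")
  expect_true(all(fm@x %in% c(0, 1)))
  # a 150 mg drug with one alert hit has exactly those two bits set
  m <- matchMatrix(screen)
  cd <- SummarizedExperiment::colData(screen)
  i <- which(cd$daily_dose_mg >= 100 & rowSums(m) == 1)[1]
  expect_equal(sum(fm@x[i, ]), 2)
  expect_equal(fm@x[i, "high_dose"], 1)
  # an all-zero drug stays all-zero
  j <- which(cd$daily_dose_mg < 100 & rowSums(m) == 0)[1]
  expect_equal(sum(fm@x[j, ]), 0)
  # the dose feature is mandatory and unique
  expect_error(featureMatrix(cbind(high_dose = c(0, 1), m[1:2, ]),
                             c(0, 1), c("AD_POSITIVE", "AD_NEGATIVE")),
               "unique")
})

test_that("stratified split reproduces the 325/82 partition and is seeded", {
  sim <- smallSim()  # 50 positives, 357 negatives
  fm <- featureMatrix(sim$indicators, sim$high_dose, sim$drugs$label)
  sp <- stratifiedSplit(fm, 0.8, seed = 42)
  expect_equal(nrow(sp$train@x), 325)
  expect_equal(nrow(sp$test@x), 82)
  expect_equal(sum(sp$train@labels), 40)
  expect_equal(sum(sp$test@labels), 10)
  # exact partition: no overlap, full cover
  expect_setequal(c(rownames(sp$train@x), rownames(sp$test@x)),
                  rownames(fm@x))
  # reproducible for a fixed seed, different for another
  sp2 <- stratifiedSplit(fm, 0.8, seed = 42)
  expect_identical(rownames(sp$train@x), rownames(sp2$train@x))
  sp3 <- stratifiedSplit(fm, 0.8, seed = 43)
  expect_false(identical(rownames(sp$train@x), rownames(sp3$train@x)))
  expect_error(stratifiedSplit(fm, 1.0), "fraction")
  tiny <- featureMatrix(matrix(0, 3, 1, dimnames = list(NULL, "a")),
                        c(0, 1, 1), c(0, 1, 1))
  expect_error(stratifiedSplit(tiny, 0.8), "at least 2")
})

test_that("grid search scores every point and breaks ties first-in-grid", {
  fm <- or6Features(seed = 2)
  one <- modelConfig(grid = data.frame(depth = 3, learning_rate = 0.1,
                                       n_iter = 30, class_weight = TRUE),
                     seed = 1)
  gs <- gridSearchCV(fm, one)
  expect_equal(nrow(gs$table), 1)
  expect_equal(gs$best$depth, 3)

  # duplicated grid point: identical scores, first one wins
  two <- modelConfig(grid = data.frame(depth = c(3, 3),
                                       learning_rate = 0.1, n_iter = 30,
                                       class_weight = TRUE), seed = 1)
  gs2 <- gridSearchCV(fm, two)
  expect_equal(gs2$table$cv_balanced_accuracy[1],
               gs2$table$cv_balanced_accuracy[2])
  expect_identical(gs2$best, as.list(two$grid[1, ]))

  # strongly separable synthetic data scores near-perfectly in CV
  d <- local({
    set.seed(77)
    y <- rep(0:1, each = 100)
    x <- cbind(high_dose = y, noise = rbinom(200, 1, 0.5))
    rownames(x) <- paste0("d", 1:200)
    featureMatrix(x[, "noise", drop = FALSE], x[, "high_dose"], y)
  })
  gs3 <- gridSearchCV(d, one)
  expect_gt(gs3$table$cv_balanced_accuracy[1], 0.9)
  # label-shuffled data scores at chance level
  set.seed(12)
  shuf <- new("FeatureMatrix", x = d@x, labels = sample(d@labels))
  gs4 <- gridSearchCV(shuf, one)
  expect_lt(abs(gs4$table$cv_balanced_accuracy[1] - 0.5), 0.12)
})

test_that("the confusion matrix implied by the test metrics evaluates correctly", {
  # 10 positives / 72 negatives: (tp, fn, fp, tn) = (4, 6, 2, 70)
  ct <- contingencyTable(tp = 4, fn = 6, fp = 2, tn = 70)
  met <- modelMetrics(ct)
  expect_equal(round(100 * met[["sensitivity"]]), 40)
  expect_equal(round(100 * met[["specificity"]]), 97)
  expect_equal(round(100 * met[["npv"]]), 92)
  expect_equal(round(100 * met[["balanced_accuracy"]]), 69)
  expect_equal(round(100 * met[["mcc"]]), 47)
  # balanced-accuracy identity holds exactly
  expect_equal(met[["balanced_accuracy"]],
               (met[["sensitivity"]] + met[["specificity"]]) / 2)
})

test_that("AUC uses average-rank tie handling (wilcoxon cross-check)", {
  set.seed(9)
  labels <- rbinom(60, 1, 0.4)
  scores <- round(rnorm(60), 1)  # force ties
  met <- modelMetrics(contingencyTable(1, 1, 1, 1), scores, labels)
  w <- stats::wilcox.test(scores[labels == 1], scores[labels == 0],
                          exact = FALSE)
  auc_ref <- w$statistic / (sum(labels == 1) * sum(labels == 0))
  expect_equal(met[["auc"]], unname(auc_ref), tolerance = 1e-12)
  # degenerate test class: AUC missing
  expect_true(is.na(modelMetrics(contingencyTable(1, 1, 1, 1),
                                 scores, rep(1, 60))[["auc"]]))
})

test_that("train/evaluate on planted signal beats the permutation null", {
  fm <- or6Features(seed = 4)
  sp <- stratifiedSplit(fm, 0.8, seed = 4)
  params <- list(depth = 3, learning_rate = 0.1, n_iter = 50,
                 class_weight = TRUE)
  fit <- trainAndEvaluate(sp$train, sp$test, params)
  expect_gt(fit$metrics[["balanced_accuracy"]], 0.5)
  expect_equal(fit$metrics[["balanced_accuracy"]],
               (fit$metrics[["sensitivity"]] + fit$metrics[["specificity"]]) / 2)

  pt <- permutationTest(sp$train, params, n_permutations = 15,
                        n_cv_repetitions = 15, k_folds = 5, seed = 10)
  expect_lt(abs(pt$mean_permuted - 0.5), 0.06)
  expect_gt(pt$mean_cv, pt$mean_permuted)
  expect_lt(pt$p_value, 0.01)
  expect_length(pt$permuted_scores, 15)
  expect_error(permutationTest(sp$train, params, n_permutations = 1,
                               n_cv_repetitions = 10), "n_permutations")
})

test_that("the seeded pipeline is bit-reproducible", {
  fm <- or6Features(seed = 6)
  cfg <- modelConfig(grid = data.frame(depth = c(2, 3), learning_rate = 0.1,
                                       n_iter = 20, class_weight = TRUE),
                     seed = 99, n_permutations = 4, n_cv_repetitions = 4)
  run <- function() {
    sp <- stratifiedSplit(fm, cfg$split_fraction, seed = cfg$seed)
    gs <- gridSearchCV(sp$train, cfg)
    fit <- trainAndEvaluate(sp$train, sp$test, gs$best)
    pt <- permutationTest(sp$train, gs$best, cfg$n_permutations,
                          cfg$n_cv_repetitions, cfg$k_folds, seed = cfg$seed)
    list(gs$table, fit$metrics, pt$permuted_scores, pt$cv_scores)
  }
  expect_identical(run(), run())
})
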