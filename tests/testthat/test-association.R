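test_that("contingencyFromFlags partitions the drug set", {
  labels <- c(rep("AD_POSITIVE", 3), rep("AD_NEGATIVE", 3))
  ct <- contingencyFromFlags(labels, rep(TRUE, 6))
  expect_equal(c(ct@tp, ct@fp, ct@fn, ct@tn), c(3, 3, 0, 0))
  ct <- contingencyFromFlags(labels, rep(FALSE, 6))
  expect_equal(c(ct@tp, ct@fp), c(0, 0))
  # hand-counted mixed toy list
  flags <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  ct <- contingencyFromFlags(labels, flags)
  expect_equal(c(ct@tp, ct@fn, ct@fp, ct@tn), c(2, 1, 1, 2))
  # NA flags drop the drug (exclude-and-report policy upstream)
  ct <- contingencyFromFlags(labels, c(TRUE, NA, TRUE, FALSE, FALSE, TRUE))
  expect_equal(ct@tp + ct@fn + ct@fp + ct@tn, 5)
  expect_error(contingencyFromFlags(rep("AD_POSITIVE", 4), rep(TRUE, 4)),
               "both AD classes")
})

test_that("sample odds ratio is the cross-product, with Haldane-Anscombe on zeros", {
  or <- function(...) as.numeric(oddsRatio(contingencyTable(...)))
  expect_equal(or(tp = 10, fn = 40, fp = 14, tn = 343), 6.125, tolerance = 1e-12)
  expect_equal(or(tp = 3, fn = 47, fp = 1, tn = 356), 22.7234, tolerance = 1e-4)
  expect_equal(or(tp = 5, fn = 5, fp = 5, tn = 5), 1)
  z <- oddsRatio(contingencyTable(tp = 3, fn = 47, fp = 0, tn = 357))
  expect_true(attr(z, "zeroCellCorrected"))
  expect_equal(as.numeric(z), (3.5 * 357.5) / (47.5 * 0.5))
  expect_false(attr(oddsRatio(contingencyTable(1, 1, 1, 1)), "zeroCellCorrected"))
})

test_that("odds ratio is invariant under row+column swap and transpose", {
  set.seed(101)
  for (i in 1:25) {
    cells <- rpois(4, 20) + 1
    ct <- contingencyTable(cells[1], cells[2], cells[3], cells[4])
    swapped <- contingencyTable(cells[4], cells[3], cells[2], cells[1])
    transposed <- contingencyTable(cells[1], cells[3], cells[2], cells[4])
    expect_equal(as.numeric(oddsRatio(ct)), as.numeric(oddsRatio(swapped)))
    expect_equal(as.numeric(oddsRatio(ct)), as.numeric(oddsRatio(transposed)))
  }
})

test_that("exact test matches its examples and stats::fisher.test", {
  p <- function(...) fisherExactP(contingencyTable(...))
  expect_equal(p(tp = 2, fn = 1, fp = 1, tn = 2), 1)
  expect_equal(p(tp = 0, fn = 50, fp = 0, tn = 357), 1)
  expect_equal(p(tp = 14, fn = 36, fp = 42, tn = 315), 0.0038, tolerance = 0.05)
  # same two-sided convention as R's exact test on a spread of tables
  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, 8)
    ct <- contingencyTable(cells[1], cells[2], cells[3], cells[4])
    if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0) next
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(fisherExactP(ct), min(1, ref), tolerance = 1e-10)
  }
  # mid-p is never larger than the point-probability p
  expect_lt(fisherExactP(contingencyTable(5, 5, 2, 9), method = "midp"),
            fisherExactP(contingencyTable(5, 5, 2, 9)))
  expect_error(p(tp = 1.5, fn = 1, fp = 1, tn = 1), "integer")
})

test_that("confusion metrics report undefined ratios as missing", {
  m <- confusionMetrics(contingencyTable(tp = 36, fn = 14, fp = 141, tn = 216))
  expect_equal(round(100 * m[["sensitivity"]]), 72)
  expect_equal(round(100 * m[["fpr"]]), 39)
  m <- confusionMetrics(contingencyTable(tp = 10, fn = 40, fp = 14, tn = 343))
  expect_equal(round(100 * m[["ppv"]]), 42)
  expect_equal(round(100 * m[["fpr"]]), 4)
  m <- confusionMetrics(contingencyTable(tp = 0, fn = 5, fp = 0, tn = 5))
  expect_equal(m[["sensitivity"]], 0)
  expect_true(is.na(m[["ppv"]]))
})

test_that("co-factoring is logical AND; union flag is logical OR", {
  expect_true(cofactorFlag(TRUE, TRUE))
  expect_false(cofactorFlag(TRUE, FALSE))
  expect_false(cofactorFlag(FALSE, TRUE))
  m <- matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2)
  expect_identical(unname(anyAlertFlag(m)), c(TRUE, FALSE))
  expect_error(anyAlertFlag(matrix(logical(0), 2, 0)), "no alerts")
})

test_that("associateAll emits per-alert, co-factored, dose and union rows", {
  screen <- smallScreen()
  assoc <- associateAll(screen, doseRule(100))
  expect_setequal(unique(assoc$kind),
                  c("alert", "alert_dose", "dose", "union", "union_dose"))
  n_alerts <- nrow(screen)
  expect_equal(sum(assoc$kind == "alert"), n_alerts)
  expect_equal(sum(assoc$kind == "alert_dose"), n_alerts)
  expect_equal(sum(assoc$kind == "dose"), 1)

  # the table agrees with directly computed statistics for every alert row
  m <- matchMatrix(screen)
  labels <- SummarizedExperiment::colData(screen)$label
  for (a in colnames(m)) {
    ct <- contingencyFromFlags(labels, m[, a])
    row <- assoc[assoc$flag_id == a, ]
    expect_equal(row$n_pos_matched, ct@tp)
    expect_equal(row$odds_ratio, as.numeric(oddsRatio(ct)))
    expect_equal(row$p_value, fisherExactP(ct))
  }
  # co-factored counts never exceed the alert-alone counts
  for (a in colnames(m)) {
    expect_lte(assoc$n_pos_matched[assoc$flag_id == paste0(a, "+dose")],
               assoc$n_pos_matched[assoc$flag_id == a])
  }
  # all-false single alert: tp 0, p 1
  labels2 <- rep(c("AD_POSITIVE", "AD_NEGATIVE"), 3)
  ct0 <- contingencyFromFlags(labels2, rep(FALSE, 6))
  expect_equal(ct0@tp, 0)
  expect_equal(fisherExactP(ct0), 1)
  # optional BH column
  withfdr <- associateAll(screen, fdr = TRUE)
  expect_true("p_adj_bh" %in% colnames(withfdr))
})

test_that("printed-table rounding is half away from zero", {
  df <- data.frame(sensitivity = 0.115, ppv = 0.245, fpr = 0.125,
                   specificity = 0.5, npv = 0.5, odds_ratio = 6.125)
  out <- formatAssociationTable(df)
  expect_equal(out$sensitivity_pct, 12)  # IEEE half-even would give 11
  expect_equal(out$fpr_pct, 13)
  expect_equal(out$odds_ratio, 6.13)
})

test_that("exact-test p-values are super-uniform under an independent flag", {
  # planted odds ratio 1: P(p <= u) must not exceed u (conservative test)
  set.seed(303)
  n_pos <- 50; n_neg <- 357; reps <- 400
  ps <- replicate(reps, {
    flags <- c(rbinom(n_pos, 1, 0.2), rbinom(n_neg, 1, 0.2)) == 1
    fisherExactP(contingencyFromFlags(
      rep(c("AD_POSITIVE", "AD_NEGATIVE"), c(n_pos, n_neg)), flags))
  })
  u <- sort(ps)
  d_plus <- max(seq_along(u) / length(u) - u)
  crit <- sqrt(-log(0.01) / 2) / sqrt(reps)  # one-sided KS, alpha = 0.01
  expect_lt(d_plus, crit)
})
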