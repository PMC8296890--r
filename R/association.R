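#' Build a 2x2 contingency table
#'
#' @param tp,fn,fp,tn Non-negative counts: AD-positive flagged / unflagged,
#'   AD-negative flagged / unflagged.
#' @return A [ContingencyTable].
#' @export
contingencyTable <- function(tp, fn, fp, tn)
  new("ContingencyTable", tp = tp, fn = fn, fp = fp, tn = tn)

#' Contingency table from per-drug flags
#'
#' @param labels Character (`AD_POSITIVE`/`AD_NEGATIVE`) or logical/0-1 vector
#'   of AD labels.
#' @param flags Logical vector of the same length. `NA` flags (e.g. missing
#'   dose under the exclude policy) drop the drug from the table.
#' @return A [ContingencyTable].
#' @export
contingencyFromFlags <- function(labels, flags) {
  if (is.character(labels)) labels <- labels == "AD_POSITIVE"
  labels <- as.logical(labels)
  flags <- as.logical(flags)
  stopifnot(length(labels) == length(flags))
  keep <- !is.na(flags) & !is.na(labels)
  labels <- labels[keep]; flags <- flags[keep]
  if (length(unique(labels)) < 2)
    stop("both AD classes must be present")
  contingencyTable(tp = sum(labels & flags), fn = sum(labels & !flags),
                   fp = sum(!labels & flags), tn = sum(!labels & !flags))
}

#' Sample (cross-product) odds ratio
#'
#' `OR = (tp * tn) / (fn * fp)`. When any cell is zero the Haldane-Anscombe
#' correction adds 0.5 to every cell first; the result then carries the
#' attribute `zeroCellCorrected = TRUE`.
#'
#' @param x A [ContingencyTable].
#' @return Numeric odds ratio with attribute `zeroCellCorrected`.
#' @rdname oddsRatio
#' @export
setMethod("oddsRatio", "ContingencyTable", function(x, ...) {
  cells <- c(x@tp, x@fn, x@fp, x@tn)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  structure((cells[1] * cells[4]) / (cells[2] * cells[3]),
            zeroCellCorrected = corrected)
})

#' Two-sided exact test for a 2x2 table
#'
#' Conditional on both margins, the flagged count among AD-positives follows
#' a hypergeometric distribution. The two-sided p-value is computed by the
#' point-probability (minimum-likelihood) rule: the sum of probabilities of
#' all margin-fixed tables whose point probability does not exceed that of
#' the observed table (with a 1 + 1e-7 relative tolerance against floating
#' point ties). `method = "midp"` subtracts half the observed point
#' probability.
#'
#' @param x A [ContingencyTable] with integer counts.
#' @param method `"point"` (default) or `"midp"`.
#' @return p-value in [0, 1].
#' @rdname fisherExactP
#' @export
setMethod("fisherExactP", "ContingencyTable",
          function(x, method = c("point", "midp"), ...) {
  method <- match.arg(method)
  cells <- c(x@tp, x@fn, x@fp, x@tn)
  if (any(cells != round(cells))) stop("exact test needs integer counts")
  npos <- x@tp + x@fn; nneg <- x@fp + x@tn; m <- x@tp + x@fp
  ks <- max(0, m - nneg):min(m, npos)
  pr <- stats::dhyper(ks, npos, nneg, m)
  pobs <- stats::dhyper(x@tp, npos, nneg, m)
  p <- sum(pr[pr <= pobs * (1 + 1e-7)])
  if (method == "midp") p <- p - pobs / 2
  min(1, p)
})

#' Confusion metrics of a 2x2 table
#'
#' Standard ratios: sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, FPR `fp/(fp+tn)`. Ratios with a zero
#' denominator are reported as `NA`, not 0.
#'
#' @param x A [ContingencyTable].
#' @return Named numeric vector.
#' @rdname confusionMetrics
#' @export
setMethod("confusionMetrics", "ContingencyTable", function(x, ...) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = ratio(x@tp, x@tp + x@fn),
    specificity = ratio(x@tn, x@tn + x@fp),
    ppv = ratio(x@tp, x@tp + x@fp),
    npv = ratio(x@tn, x@tn + x@fn),
    fpr = ratio(x@fp, x@fp + x@tn))
})

setMethod("show", "ContingencyTable", function(object) {
  cat("ContingencyTable (flag x AD label)\n")
  print(matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
               dimnames = list(c("flagged", "unflagged"),
                               c("AD_POSITIVE", "AD_NEGATIVE"))))
})

#' Dose co-factoring AND rule
#'
#' A drug is flagged iff it carries the structural alert AND is high-dose.
#'
#' @param alert_flag,dose_flag Logical vectors (recycled per R rules must be
#'   equal length).
#' @return Logical vector.
#' @export
cofactorFlag <- function(alert_flag, dose_flag) {
  stopifnot(length(alert_flag) == length(dose_flag))
  alert_flag & dose_flag
}

## Rounding conventions of the printed tables: percentages to the nearest
## integer and odds ratios to 2 dp, both half away from zero (IEEE half-even
## would print 6.125 as 6.12).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-alert association statistics with dose co-factoring
#'
#' Builds one association row per alert, one per alert AND high-dose, plus a
#' dose-alone row and the any-alert union row (and its dose co-factored
#' counterpart), each against the AD label: 2x2 counts, sensitivity, PPV,
#' FPR, specificity, NPV, sample odds ratio (Haldane-Anscombe corrected on
#' zero cells, flagged) and the two-sided exact p-value. Drugs with missing
#' dose are excluded from dose-co-factored rows and reported via the
#' `n_dose_missing` attribute.
#'
#' @param screen An [AlertScreen].
#' @param rule A [DoseRule] (default cutoff 100 mg/day).
#' @param sort `"pos_count"` (descending AD-positive matches, the printed
#'   table ordering), `"p"` (ascending p-value) or `"none"` (library order).
#' @param cofactor Also emit `<alert>+dose` rows (default `TRUE`).
#' @param fdr Append a Benjamini-Hochberg adjusted p-value column (off by
#'   default; the printed tables report raw p-values).
#' @return data.frame of association results.
#' @export
associateAll <- function(screen, rule = doseRule(),
                         sort = c("pos_count", "p", "none"),
                         cofactor = TRUE, fdr = FALSE) {
  sort <- match.arg(sort)
  stopifnot(is(screen, "AlertScreen"))
  m <- matchMatrix(screen)
  cd <- colData(screen)
  labels <- cd$label
  if (length(unique(labels)) < 2) stop("both AD classes must be present")
  dose_flag <- highDoseFlag(cd$daily_dose_mg, rule, missing = "na")
  n_dose_missing <- sum(is.na(dose_flag))

  desc <- stats::setNames(rowData(screen)$description, rownames(screen))
  rows <- list()
  addRow <- function(flag_id, description, flags, kind) {
    ct <- contingencyFromFlags(labels, flags)
    or <- oddsRatio(ct)
    met <- confusionMetrics(ct)
    rows[[length(rows) + 1]] <<- data.frame(
      flag_id = flag_id, description = description, kind = kind,
      n_pos_matched = ct@tp, n_neg_matched = ct@fp,
      sensitivity = met[["sensitivity"]], ppv = met[["ppv"]],
      fpr = met[["fpr"]], specificity = met[["specificity"]],
      npv = met[["npv"]],
      odds_ratio = as.numeric(or), p_value = fisherExactP(ct),
      zero_cell_corrected = attr(or, "zeroCellCorrected"))
  }

  for (a in colnames(m)) addRow(a, desc[[a]], m[, a], "alert")
  addRow("any_alert", "all structural alerts combined", anyAlertFlag(m),
         "union")
  addRow("high_dose", sprintf("high daily dose (>= %g mg)",
                              if (is(rule, "DoseRule")) rule@cutoff_mg else rule),
         dose_flag, "dose")
  if (cofactor) {
    for (a in colnames(m))
      addRow(paste0(a, "+dose"), paste0(desc[[a]], " + high daily dose"),
             cofactorFlag(m[, a], dose_flag), "alert_dose")
    addRow("any_alert+dose", "all structural alerts combined + high daily dose",
           cofactorFlag(anyAlertFlag(m), dose_flag), "union_dose")
  }
  out <- do.call(rbind, rows)
  if (fdr) {
    out$p_adj_bh <- NA_real_
    is_alert <- out$kind == "alert"
    out$p_adj_bh[is_alert] <- stats::p.adjust(out$p_value[is_alert], "BH")
  }
  if (sort == "pos_count")
    out <- out[order(out$kind, -out$n_pos_matched, out$flag_id), ]
  else if (sort == "p")
    out <- out[order(out$kind, out$p_value, out$flag_id), ]
  rownames(out) <- NULL
  attr(out, "n_dose_missing") <- n_dose_missing
  out
}

#' Format an association table the way the printed tables round
#'
#' Percent columns round to the nearest integer percent and odds ratios to
#' 2 decimals, both half away from zero.
#'
#' @param assoc data.frame from [associateAll()].
#' @return data.frame with `*_pct` columns and a rounded `odds_ratio`.
#' @export
formatAssociationTable <- function(assoc) {
  out <- assoc
  for (col in c("sensitivity", "ppv", "fpr", "specificity", "npv"))
    out[[paste0(col, "_pct")]] <- roundHalfUp(100 * assoc[[col]])
  out$odds_ratio <- roundHalfUp(assoc$odds_ratio, 2)
  out
}
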