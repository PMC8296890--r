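#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Library of structural alerts
#'
#' An `AlertLibrary` holds an ordered collection of SMARTS structural alerts
#' for reactive-metabolite formation. Each alert has a unique `alert_id`, a
#' SMARTS pattern, a free-text description, an optional `family` tag grouping
#' variants (e.g. the nitrogen-on-benzene N-H-count family) and a `source`
#' citation. Iteration order is the order of the source file and is stable.
#'
#' @slot alerts A [S4Vectors::DataFrame] with columns `alert_id`, `smarts`,
#'   `description`, `family`, `source`.
#' @slot name Library name.
#' @slot version Library version string.
#'
#' @seealso [readAlertLibrary()], [builtinAlerts()]
#' @export
setClass("AlertLibrary",
         representation(alerts = "DataFrame",
                        name = "character",
                        version = "character"))

setValidity("AlertLibrary", function(object) {
  al <- object@alerts
  need <- c("alert_id", "smarts", "description", "family", "source")
  if (!all(need %in% colnames(al)))
    return(paste("alerts must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(al$alert_id))
    return("duplicate alert_id in library")
  if (nrow(al) > 0 && any(!nzchar(al$description)))
    return("empty alert description")
  if (nrow(al) > 0 && any(!nzchar(al$smarts)))
    return("empty SMARTS pattern")
  TRUE
})

#' Screening result: alerts x drugs match matrix
#'
#' `AlertScreen` extends [SummarizedExperiment::SummarizedExperiment]: the
#' `"matches"` assay is a logical matrix with one row per structural alert and
#' one column per drug, `rowData` carries the alert metadata and `colData` the
#' drug metadata (`drug_id`, `name`, `smiles` as standardized, `daily_dose_mg`,
#' `label`). Drugs whose SMILES failed to parse are excluded from the matrix
#' and recorded in `metadata(x)$excluded`.
#'
#' @export
setClass("AlertScreen", contains = "SummarizedExperiment")

setValidity("AlertScreen", function(object) {
  if (!"matches" %in% SummarizedExperiment::assayNames(object))
    return("AlertScreen needs a 'matches' assay")
  m <- assay(object, "matches")
  if (!is.logical(m)) return("'matches' assay must be logical")
  need <- c("drug_id", "daily_dose_mg", "label")
  if (!all(need %in% colnames(colData(object))))
    return(paste("colData must have columns:", paste(need, collapse = ", ")))
  lab <- colData(object)$label
  if (length(lab) && !all(lab %in% c("AD_POSITIVE", "AD_NEGATIVE")))
    return("label must be AD_POSITIVE or AD_NEGATIVE")
  TRUE
})

#' 2x2 contingency table of a flag against the AD label
#'
#' Counts are `tp` (AD-positive and flagged), `fn` (AD-positive, unflagged),
#' `fp` (AD-negative, flagged), `tn` (AD-negative, unflagged). Slots are
#' numeric so that real-valued expected tables (from the synthetic-data
#' planted truth) are representable; the exact test requires integer counts.
#'
#' @slot tp,fn,fp,tn Non-negative counts.
#' @seealso [contingencyTable()], [oddsRatio()], [fisherExactP()],
#'   [confusionMetrics()]
#' @export
setClass("ContingencyTable",
         representation(tp = "numeric", fn = "numeric",
                        fp = "numeric", tn = "numeric"))

setValidity("ContingencyTable", function(object) {
  v <- c(object@tp, object@fn, object@fp, object@tn)
  if (length(v) != 4 || anyNA(v)) return("all four cells must be single non-NA numbers")
  if (any(v < 0)) return("negative cell count")
  TRUE
})

#' Daily-dose cutoff rule
#'
#' The high-dose flag is `daily_dose_mg >= cutoff_mg`, inclusive at the
#' boundary; the default cutoff is 100 mg/day.
#'
#' @slot cutoff_mg Positive cutoff in mg/day.
#' @export
setClass("DoseRule", representation(cutoff_mg = "numeric"),
         prototype(cutoff_mg = 100))

setValidity("DoseRule", function(object) {
  if (length(object@cutoff_mg) != 1 || is.na(object@cutoff_mg) ||
      object@cutoff_mg <= 0)
    return("cutoff_mg must be a single positive number")
  TRUE
})

#' Binary feature matrix for the risk model
#'
#' Drugs in rows; one binary column per structural alert plus exactly one
#' high-dose column named `"high_dose"`. Labels are 1 for AD-positive drugs,
#' 0 for AD-negative.
#'
#' @slot x Numeric 0/1 matrix, drugs x features, with row and column names.
#' @slot labels Integer 0/1 vector aligned to rows of `x`.
#' @export
setClass("FeatureMatrix",
         representation(x = "matrix", labels = "integer"))

setValidity("FeatureMatrix", function(object) {
  x <- object@x
  if (!is.numeric(x)) return("x must be numeric")
  if (length(object@labels) != nrow(x)) return("labels length != nrow(x)")
  if (!all(x %in% c(0, 1))) return("x entries must be 0/1")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    return("x needs unique column names")
  if (sum(colnames(x) == "high_dose") != 1)
    return("exactly one 'high_dose' feature column is required")
  TRUE
})
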