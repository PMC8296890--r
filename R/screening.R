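#' Daily-dose rule constructor
#'
#' @param cutoff_mg Positive cutoff in mg/day; the flag is inclusive
#'   (`dose >= cutoff_mg`). Default 100.
#' @return A [DoseRule].
#' @export
doseRule <- function(cutoff_mg = 100) new("DoseRule", cutoff_mg = cutoff_mg)

#' High daily-dose flag
#'
#' `TRUE` iff `dose_mg >= cutoff`, with the boundary included (a 100 mg/day
#' drug is high-dose under the default rule). Missing doses follow the
#' `missing` policy: `"na"` (default; callers exclude-and-report), `"error"`,
#' or `"false"`.
#'
#' @param dose_mg Numeric vector of daily doses (mg/day).
#' @param rule A [DoseRule] or numeric cutoff.
#' @param missing Policy for `NA` doses.
#' @return Logical vector.
#' @export
highDoseFlag <- function(dose_mg, rule = doseRule(),
                         missing = c("na", "error", "false")) {
  missing <- match.arg(missing)
  cutoff <- if (is(rule, "DoseRule")) rule@cutoff_mg else as.numeric(rule)
  stopifnot(length(cutoff) == 1, cutoff > 0)
  if (any(dose_mg < 0, na.rm = TRUE)) stop("negative daily dose")
  out <- dose_mg >= cutoff
  if (anyNA(out)) {
    if (missing == "error") stop("missing daily dose")
    if (missing == "false") out[is.na(out)] <- FALSE
  }
  out
}

#' Read a drug set from CSV
#'
#' Expected columns: `drug_id,name,smiles,daily_dose_mg,label` with labels
#' `AD_POSITIVE`/`AD_NEGATIVE`. `drug_id` must be unique; doses must be
#' non-negative or missing.
#'
#' @param path CSV file path.
#' @return data.frame of drug records.
#' @export
readDrugSet <- function(path) {
  if (!file.exists(path)) stop("drug file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "name", "smiles", "daily_dose_mg", "label")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("drug table is missing column(s): ", paste(missing, collapse = ", "))
  df$drug_id <- as.character(df$drug_id)
  df$daily_dose_mg <- as.numeric(df$daily_dose_mg)
  validateDrugSet(df)
  df
}

#' Validate a drug record table
#'
#' @param df data.frame with at least `drug_id`, `smiles`, `daily_dose_mg`,
#'   `label` columns.
#' @return `df` invisibly; stops on violation.
#' @export
validateDrugSet <- function(df) {
  if (anyDuplicated(df$drug_id))
    stop("duplicate drug_id: ",
         paste(unique(df$drug_id[duplicated(df$drug_id)]), collapse = ", "))
  if (!all(df$label %in% c("AD_POSITIVE", "AD_NEGATIVE")))
    stop("label must be AD_POSITIVE or AD_NEGATIVE")
  if (any(df$daily_dose_mg < 0, na.rm = TRUE))
    stop("negative daily_dose_mg")
  invisible(df)
}

#' Screen a drug set against an alert library
#'
#' Structures are standardized first ([standardizeStructure()]: largest
#' fragment, stereo stripped), then matched against every alert SMARTS.
#' Drugs whose SMILES fail to parse are excluded from the matrix and reported
#' in `metadata(result)$excluded` so that batch screening always completes.
#' Screening is deterministic and order-independent: permuting the drug order
#' permutes the matrix columns identically.
#'
#' @param drugs data.frame of drug records (see [readDrugSet()]).
#' @param library An [AlertLibrary]; must be non-empty.
#' @param standardize Standardize/desalt structures before matching (default
#'   `TRUE`).
#' @return An [AlertScreen] (alerts x drugs).
#' @export
screenDrugs <- function(drugs, library, standardize = TRUE) {
  stopifnot(is(library, "AlertLibrary"))
  if (length(library) == 0) stop("empty alert library")
  validateDrugSet(drugs)
  if (nrow(drugs) == 0) stop("empty drug set")

  smi <- as.character(drugs$smiles)
  if (standardize) smi <- standardizeStructure(smi, onError = "na")
  parse_ok <- !is.na(smi)
  r <- .matchRaw(ifelse(parse_ok, smi, "C"), alertSmarts(library))
  ok <- parse_ok & r$smiles_ok

  excluded <- drugs$drug_id[!ok]
  kept <- drugs[ok, , drop = FALSE]
  m <- t(r$matches[ok, , drop = FALSE])  # alerts x drugs
  dimnames(m) <- list(alertIds(library), kept$drug_id)

  cd <- DataFrame(drug_id = kept$drug_id,
                  name = if ("name" %in% colnames(kept)) kept$name else kept$drug_id,
                  smiles = smi[ok],
                  daily_dose_mg = kept$daily_dose_mg,
                  label = kept$label,
                  row.names = kept$drug_id)
  se <- SummarizedExperiment(assays = list(matches = m),
                             rowData = library@alerts, colData = cd)
  metadata(se)$excluded <- excluded
  metadata(se)$library <- list(name = library@name, version = library@version)
  if (length(excluded))
    message(length(excluded), " drug(s) excluded (unparsable SMILES): ",
            paste(utils::head(excluded, 5), collapse = ", "))
  new("AlertScreen", se)
}

#' Match matrix of a screening result
#'
#' @param x An [AlertScreen].
#' @return Logical matrix, drugs x alerts (drugs in rows, mirroring the
#'   drug-table orientation of the wide CSV export).
#' @rdname matchMatrix
#' @export
setMethod("matchMatrix", "AlertScreen", function(x) t(assay(x, "matches")))

#' Per-drug any-alert union flag
#'
#' A drug carries a structural alert if any alert in the library matches it.
#'
#' @param x An [AlertScreen] or a logical matrix (drugs x alerts).
#' @return Named logical vector over drugs.
#' @export
anyAlertFlag <- function(x) {
  m <- if (is(x, "AlertScreen")) matchMatrix(x) else x
  if (ncol(m) == 0) stop("no alerts")
  apply(m, 1, any)
}

#' Write the match matrix as wide 0/1 CSV
#'
#' @param x An [AlertScreen].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
writeMatchMatrix <- function(x, path) {
  m <- matchMatrix(x)
  df <- data.frame(drug_id = rownames(m), 1L * m,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

setMethod("show", "AlertScreen", function(object) {
  cat("AlertScreen: ", nrow(object), " alerts x ", ncol(object), " drugs; ",
      sum(colData(object)$label == "AD_POSITIVE"), " AD-positive, ",
      sum(colData(object)$label == "AD_NEGATIVE"), " AD-negative\n", sep = "")
  ex <- metadata(object)$excluded
  if (length(ex)) cat("  excluded (unparsable):", length(ex), "\n")
})
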