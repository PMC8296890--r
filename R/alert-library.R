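#' Construct an alert library from a data.frame
#'
#' Validates every record: `alert_id` unique, `description` non-empty, and
#' every SMARTS pattern must compile (checked with RDKit). Offending records
#' are reported by `alert_id`.
#'
#' @param df data.frame with columns `alert_id`, `smarts`, `description` and
#'   optionally `family`, `source`.
#' @param name,version Library metadata.
#' @param checkSmarts Validate patterns with the matching engine (default
#'   `TRUE`; needs python/RDKit).
#' @return An [AlertLibrary].
#' @export
AlertLibrary <- function(df, name = "user", version = "0",
                         checkSmarts = TRUE) {
  need <- c("alert_id", "smarts", "description")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("alert table is missing column(s): ", paste(missing, collapse = ", "))
  if (!"family" %in% colnames(df)) df$family <- rep("", nrow(df))
  if (!"source" %in% colnames(df)) df$source <- rep("", nrow(df))
  df$family[is.na(df$family)] <- ""
  df$source[is.na(df$source)] <- ""
  df <- df[, c("alert_id", "smarts", "description", "family", "source")]
  for (col in colnames(df)) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$alert_id))
    stop("duplicate alert_id: ",
         paste(unique(df$alert_id[duplicated(df$alert_id)]), collapse = ", "))
  if (nrow(df) > 0 && checkSmarts) {
    ok <- validSmarts(df$smarts)
    if (any(!ok))
      stop("unparsable SMARTS for alert_id(s): ",
           paste(df$alert_id[!ok], collapse = ", "))
  }
  new("AlertLibrary", alerts = DataFrame(df), name = name, version = version)
}

#' Read an alert library from CSV
#'
#' The file must have a header with at least `alert_id,smarts,description`;
#' `family` and `source` columns are optional. Records are validated as in
#' [AlertLibrary()]. A header-only file yields an empty library with a
#' warning.
#'
#' @param path CSV file path.
#' @inheritParams AlertLibrary
#' @return An [AlertLibrary] preserving file order.
#' @export
readAlertLibrary <- function(path, name = basename(path), version = "0",
                             checkSmarts = TRUE) {
  if (!file.exists(path)) stop("alert file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) warning("alert library '", path, "' is empty")
  AlertLibrary(df, name = name, version = version, checkSmarts = checkSmarts)
}

#' Built-in structural alert library
#'
#' The packaged library covers the nitrogen-on-benzene alert family (any
#' substitution, and the two / one / no N-H variants, i.e. primary, secondary
#' and tertiary aromatic amines), the other frequently matched
#' reactive-metabolite alerts (alkenes, halogenated methylbenzene, phenol,
#' halogenated carbon, methoxy/methyl aromatic variants, methoxybenzene), and
#' the decomposed `nitrogen-containing compound` and `benzene` patterns.
#' The full published 171-alert collection is data, not code: load your own
#' CSV with [readAlertLibrary()] for an extended library.
#'
#' @return An [AlertLibrary].
#' @examples \dontrun{alertIds(builtinAlerts())}
#' @export
builtinAlerts <- function() {
  path <- system.file("extdata", "builtin_alerts.csv", package = "AlertAD")
  readAlertLibrary(path, name = "builtin", version = "1",
                   checkSmarts = FALSE)  # patterns are validated by tests
}

#' Export a library as a SMARTS flat file
#'
#' One pattern per line, tab-separated `alert_id<TAB>smarts`.
#'
#' @param x An [AlertLibrary].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
exportSmartsFile <- function(x, path) {
  stopifnot(is(x, "AlertLibrary"))
  writeLines(paste(x@alerts$alert_id, x@alerts$smarts, sep = "\t"), path)
  invisible(path)
}

#' Alert accessors
#'
#' `alertIds()` and `alertSmarts()` return the per-alert identifier and SMARTS
#' vectors in library order.
#'
#' @param x An [AlertLibrary].
#' @return Character vector.
#' @rdname alertIds
#' @export
setMethod("alertIds", "AlertLibrary", function(x) x@alerts$alert_id)

#' @rdname alertIds
#' @export
setMethod("alertSmarts", "AlertLibrary", function(x) {
  stats::setNames(x@alerts$smarts, x@alerts$alert_id)
})

#' @export
#' @describeIn AlertLibrary-class Number of alerts.
setMethod("length", "AlertLibrary", function(x) nrow(x@alerts))

#' @export
#' @describeIn AlertLibrary-class Subset by position, logical mask or alert_id.
setMethod("[", "AlertLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@alerts$alert_id)
  if (anyNA(i)) stop("unknown alert_id")
  initialize(x, alerts = x@alerts[i, , drop = FALSE])
})

#' @export
setMethod("as.data.frame", "AlertLibrary", function(x, ...) {
  as.data.frame(x@alerts)
})

setMethod("show", "AlertLibrary", function(object) {
  cat("AlertLibrary '", object@name, "' (v", object@version, "): ",
      nrow(object@alerts), " alerts\n", sep = "")
  if (nrow(object@alerts))
    cat("  ", paste(utils::head(object@alerts$alert_id, 8), collapse = ", "),
        if (nrow(object@alerts) > 8) ", ..." else "", "\n", sep = "")
})
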