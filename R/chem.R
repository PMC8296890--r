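## Bridge to RDKit via the system python interpreter. All calls are batch:
## one JSON request on stdin, one JSON response on stdout, so a screening run
## pays interpreter start-up once regardless of library size.

.pythonBin <- function() {
  bin <- getOption("AlertAD.python", Sys.which("python"))
  if (!nzchar(bin))
    stop("no 'python' interpreter found on PATH; RDKit is required for ",
         "structure handling (set options(AlertAD.python = ...))")
  bin
}

.chemScript <- function() {
  path <- system.file("python", "chem_tools.py", package = "AlertAD")
  if (!nzchar(path)) stop("bundled chem_tools.py not found")
  path
}

.chemCall <- function(op, payload) {
  payload$op <- op
  req <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  infile <- tempfile(fileext = ".json")
  on.exit(unlink(infile), add = TRUE)
  writeLines(req, infile)
  out <- suppressWarnings(system2(.pythonBin(), shQuote(.chemScript()),
                                  stdout = TRUE, stderr = FALSE,
                                  stdin = infile))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("chemistry helper failed (exit ", status, ")")
  res <- jsonlite::fromJSON(paste(out, collapse = "\n"),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!is.null(res$error)) stop("chemistry helper: ", res$error)
  res
}

#' Canonicalize SMILES and strip salts
#'
#' Returns the canonical SMILES of the largest covalently-bonded fragment of
#' each input (counter-ions of salts are dropped), with stereochemistry
#' removed — structural alerts are 2D substructure patterns. The operation is
#' idempotent: standardizing a standardized SMILES returns it unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @param onError `"error"` (default) stops at the first unparsable SMILES;
#'   `"na"` returns `NA` for unparsable entries instead.
#' @return Character vector of canonical SMILES.
#' @examples \dontrun{standardizeStructure("Nc1ccccc1.Cl")  # "Nc1ccccc1"}
#' @export
standardizeStructure <- function(smiles, onError = c("error", "na")) {
  onError <- match.arg(onError)
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  if (any(is.na(smiles) | !nzchar(smiles)))
    stop("empty or NA SMILES input")
  res <- .chemCall("canonicalize", list(smiles = as.list(unname(smiles))))$results
  ok <- vapply(res, `[[`, logical(1), "ok")
  if (any(!ok) && onError == "error")
    stop("unparsable SMILES: ",
         paste(utils::head(smiles[!ok], 5), collapse = ", "))
  out <- rep(NA_character_, length(smiles))
  out[ok] <- vapply(res[ok], `[[`, character(1), "smiles")
  out
}

#' Validate SMARTS patterns
#'
#' @param smarts Character vector of SMARTS.
#' @return Logical vector: does each pattern compile?
#' @export
validSmarts <- function(smarts) {
  stopifnot(is.character(smarts))
  if (length(smarts) == 0) return(logical(0))
  unlist(.chemCall("validate_smarts",
                   list(smarts = as.list(unname(smarts))))$ok)
}

## Raw matcher: molecules x patterns logical matrix + per-molecule parse flag.
.matchRaw <- function(smiles, smarts) {
  res <- .chemCall("match", list(smiles = as.list(unname(smiles)),
                                 smarts = as.list(unname(smarts))))
  m <- matrix(unlist(res$matches), nrow = length(smiles),
              ncol = length(smarts), byrow = TRUE)
  list(matches = m, smiles_ok = unlist(res$smiles_ok))
}

#' Match one structure against one alert
#'
#' `TRUE` iff at least one substructure embedding of the alert's SMARTS exists
#' in the molecule.
#'
#' @param smiles A single SMILES string.
#' @param alert An [AlertLibrary] row (1-alert library) or a SMARTS string.
#' @return Logical scalar.
#' @export
matchAlert <- function(smiles, alert) {
  stopifnot(length(smiles) == 1)
  sma <- if (is(alert, "AlertLibrary")) alertSmarts(alert) else as.character(alert)
  stopifnot(length(sma) == 1)
  if (!validSmarts(sma)) stop("invalid SMARTS pattern: ", sma)
  r <- .matchRaw(smiles, sma)
  if (!r$smiles_ok) stop("unparsable SMILES: ", smiles)
  r$matches[1, 1]
}

#' Classify aromatic amines by N-H count
#'
#' For every nitrogen bonded directly to a carbon of a benzene ring
#' (six-membered all-carbon aromatic ring), counts its hydrogens (implicit +
#' explicit) and classifies it as `TWO_NH` (primary aromatic amine), `ONE_NH`
#' (secondary) or `NO_NH` (tertiary). A molecule with no such nitrogen is
#' `NONE`. Because one molecule can carry several such nitrogens, the
#' molecule-level result is one flag per class (a drug can be both `ONE_NH`
#' and `NO_NH`); classes are mutually exclusive per nitrogen.
#'
#' @param smiles Character vector of SMILES.
#' @return A data.frame with logical columns `two_nh`, `one_nh`, `no_nh`, a
#'   character column `class` (the per-molecule class, or `"NONE"`; if several
#'   classes are present, the most-substituted hydrogens first ordering
#'   `TWO_NH > ONE_NH > NO_NH` is reported with a `multiple` flag), and a
#'   list column `n_h_counts` of per-nitrogen H counts.
#' @export
classifyAromaticAmine <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  res <- .chemCall("amine_classes",
                   list(smiles = as.list(unname(smiles))))$results
  ok <- vapply(res, `[[`, logical(1), "ok")
  if (any(!ok))
    stop("unparsable SMILES: ",
         paste(utils::head(smiles[!ok], 5), collapse = ", "))
  two <- vapply(res, `[[`, logical(1), "two_nh")
  one <- vapply(res, `[[`, logical(1), "one_nh")
  no  <- vapply(res, `[[`, logical(1), "no_nh")
  cls <- ifelse(two, "TWO_NH", ifelse(one, "ONE_NH", ifelse(no, "NO_NH", "NONE")))
  data.frame(smiles = smiles, class = cls,
             two_nh = two, one_nh = one, no_nh = no,
             multiple = (two + one + no) > 1,
             n_h_counts = I(lapply(res, function(r) unlist(r$n_h_counts))),
             row.names = NULL)
}
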