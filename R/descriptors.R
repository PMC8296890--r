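#' Conceptual-DFT reactivity descriptors from frontier orbital energies
#'
#' Given the highest occupied and lowest unoccupied molecular orbital
#' energies, computes the global hardness `eta = (E_LUMO - E_HOMO)/2`, the
#' chemical potential `mu = (E_LUMO + E_HOMO)/2` and the electrophilicity
#' index `omega = mu^2 / (2 eta)`. Units are preserved from the input (one
#' unit for both energies; hartree by convention). The gap must be positive.
#' Note `omega` is not shift-invariant: adding a constant to both energies
#' changes `mu` but not `eta`.
#'
#' @param e_homo,e_lumo Numeric vectors of orbital energies (same unit).
#' @return data.frame with columns `eta`, `mu`, `omega`.
#' @examples computeDescriptors(-0.3, -0.1)  # eta 0.1, mu -0.2, omega 0.2
#' @export
computeDescriptors <- function(e_homo, e_lumo) {
  stopifnot(length(e_homo) == length(e_lumo))
  if (any(!is.finite(e_homo)) || any(!is.finite(e_lumo)))
    stop("non-finite orbital energy")
  if (any(e_lumo <= e_homo))
    stop("E_LUMO must exceed E_HOMO (positive HOMO-LUMO gap)")
  eta <- (e_lumo - e_homo) / 2
  mu <- (e_lumo + e_homo) / 2
  data.frame(eta = eta, mu = mu, omega = mu^2 / (2 * eta))
}

#' Rank compounds by electrophilicity
#'
#' Orders compounds by descending electrophilicity index `omega`, breaking
#' ties by ascending `E_LUMO` (a lower LUMO accepts electrons more easily),
#' then by `compound_id` for a stable order. Highly electrophilic reactive
#' metabolites (e.g. nitrosobenzene, quinone imine) rank above their parent
#' aromatic amine under this ordering.
#'
#' @param energies data.frame with columns `compound_id`, `e_homo`, `e_lumo`.
#' @return The input with `eta`, `mu`, `omega` appended, ordered by rank.
#' @export
rankByElectrophilicity <- function(energies) {
  need <- c("compound_id", "e_homo", "e_lumo")
  stopifnot(all(need %in% colnames(energies)), nrow(energies) >= 1)
  d <- cbind(energies,
             computeDescriptors(energies$e_homo, energies$e_lumo))
  d <- d[order(-d$omega, d$e_lumo, d$compound_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Hartree/electron-volt conversion
#'
#' 1 hartree = 27.211386 eV. Ratios of `omega` between compounds are
#' preserved under the round trip.
#'
#' @param x Numeric energies.
#' @return Converted energies.
#' @export
hartreeToEV <- function(x) x * 27.211386

#' @rdname hartreeToEV
#' @export
evToHartree <- function(x) x / 27.211386

#' Read frontier orbital energies from CSV
#'
#' Expected columns `compound_id,e_homo,e_lumo` and optionally `unit`
#' (`"hartree"` or `"ev"`; must be the single same unit for all rows — mixed
#' units are an error). Energies are returned in hartree.
#'
#' @param path CSV file path.
#' @return data.frame with `compound_id`, `e_homo`, `e_lumo` in hartree.
#' @export
readOrbitalEnergies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "e_homo", "e_lumo")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("orbital energy table is missing column(s): ",
         paste(missing, collapse = ", "))
  if ("unit" %in% colnames(df)) {
    unit <- unique(tolower(df$unit))
    if (length(unit) > 1) stop("mixed energy units in one file")
    if (!unit %in% c("hartree", "ev")) stop("unknown unit: ", unit)
    if (unit == "ev") {
      df$e_homo <- evToHartree(df$e_homo)
      df$e_lumo <- evToHartree(df$e_lumo)
    }
    df$unit <- NULL
  }
  df
}
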