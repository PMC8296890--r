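#' Default planted-alert set for the synthetic generator
#'
#' Four structurally independent alerts, each with a carrier fragment that is
#' attached to the scaffold when (and only when) the drug's indicator is
#' drawn, and whose SMARTS matches its own carrier and no other default
#' carrier — so the indicator matrix round-trips exactly through screening.
#' Class-conditional prevalences mirror the frequently matched alerts of the
#' curated 407-drug set (e.g. the primary aromatic amine at 14/50 positives
#' and 42/357 negatives, planted odds ratio ~ 2.91).
#'
#' @return data.frame with columns `alert_id`, `smarts`, `description`,
#'   `fragment`, `p_pos`, `p_neg`.
#' @export
defaultSyntheticAlerts <- function() {
  data.frame(
    alert_id = c("aromatic_primary_amine", "alkene",
                 "halogenated_carbon", "phenol"),
    smarts = c("[NX3;H2]c1ccccc1", "[CX3]=[CX3]",
               "[CX4][Cl]", "[OX2H]c1ccccc1"),
    description = c("benzene ring with nitrogen-containing substituent (two N-H bond)",
                    "alkenes", "halogenated carbon",
                    "benzene ring with hydroxyl group"),
    fragment = c("c1ccc(N)cc1", "C=C", "CCl", "c1ccc(O)cc1"),
    p_pos = c(14 / 50, 12 / 50, 11 / 50, 6 / 50),
    p_neg = c(42 / 357, 51 / 357, 64 / 357, 60 / 357),
    stringsAsFactors = FALSE)
}

#' Synthetic drug-set configuration
#'
#' The defaults state the emulated world: 50 AD-positive vs 357 AD-negative
#' drugs, per-alert class-conditional prevalences from the frequently
#' matched alerts, high-dose probability 36/50 for positives and 141/357 for
#' negatives, and a log-uniform dose sampler over \[1, 1000\] mg partitioned
#' at the 100 mg cutoff. Alerts are independent across drugs and independent
#' of dose given the class.
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param alerts data.frame as in [defaultSyntheticAlerts()].
#' @param p_dose_pos,p_dose_neg High-dose probability per class.
#' @param dose_range Dose support in mg (log-uniform).
#' @param dose_cutoff High/low dose partition point (mg).
#' @param scaffolds Inert SMILES backbones used when a drug carries no alert.
#' @param seed Integer seed; all draws flow from it.
#' @return Validated config list.
#' @export
syntheticConfig <- function(n_pos = 50, n_neg = 357,
                            alerts = defaultSyntheticAlerts(),
                            p_dose_pos = 36 / 50, p_dose_neg = 141 / 357,
                            dose_range = c(1, 1000), dose_cutoff = 100,
                            scaffolds = c("CCCCCC", "C1CCCCC1", "CC(C)CCC",
                                          "CCC1CCCC1"),
                            seed = 42) {
  stopifnot(n_pos >= 1, n_neg >= 1,
            all(c("alert_id", "smarts", "fragment", "p_pos", "p_neg") %in%
                  colnames(alerts)),
            all(alerts$p_pos >= 0 & alerts$p_pos <= 1),
            all(alerts$p_neg >= 0 & alerts$p_neg <= 1),
            p_dose_pos >= 0, p_dose_pos <= 1, p_dose_neg >= 0, p_dose_neg <= 1,
            dose_range[1] > 0, dose_range[2] > dose_range[1],
            dose_cutoff > dose_range[1], dose_cutoff < dose_range[2])
  if (!"description" %in% colnames(alerts))
    alerts$description <- alerts$alert_id
  list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg), alerts = alerts,
       p_dose_pos = p_dose_pos, p_dose_neg = p_dose_neg,
       dose_range = dose_range, dose_cutoff = dose_cutoff,
       scaffolds = scaffolds, seed = as.integer(seed))
}

#' Closed-form planted odds ratio
#'
#' `OR = p1 (1 - p0) / ((1 - p1) p0)` for alert prevalence `p1` among
#' AD-positives and `p0` among AD-negatives.
#'
#' @param p1,p0 Class-conditional prevalences.
#' @return Numeric odds ratio.
#' @export
plantedOddsRatio <- function(p1, p0) (p1 * (1 - p0)) / ((1 - p1) * p0)

#' Expected contingency table under a synthetic config
#'
#' Real-valued expectations: `tp = n_pos * p1`, etc.
#'
#' @param config A [syntheticConfig()].
#' @param alert_id One of the configured alert ids.
#' @return A [ContingencyTable] of expectations.
#' @export
expectedContingency <- function(config, alert_id) {
  i <- match(alert_id, config$alerts$alert_id)
  if (is.na(i)) stop("unknown alert: ", alert_id)
  p1 <- config$alerts$p_pos[i]; p0 <- config$alerts$p_neg[i]
  contingencyTable(tp = config$n_pos * p1, fn = config$n_pos * (1 - p1),
                   fp = config$n_neg * p0, tn = config$n_neg * (1 - p0))
}

#' Alert library of the planted alerts
#'
#' @param config A [syntheticConfig()].
#' @param checkSmarts Validate SMARTS with RDKit (default `FALSE`: the
#'   default set is validated by tests and validation needs python).
#' @return An [AlertLibrary].
#' @export
syntheticAlertLibrary <- function(config, checkSmarts = FALSE) {
  AlertLibrary(config$alerts[, c("alert_id", "smarts", "description")],
               name = "synthetic", version = "1", checkSmarts = checkSmarts)
}

## SMILES assembly: each drawn alert contributes its carrier fragment as a
## branch on a short alkane backbone; alert-free drugs get an inert scaffold.
.assembleSmiles <- function(fragments, scaffold) {
  if (length(fragments) == 0) return(scaffold)
  paste0(paste0("C(", fragments, ")", collapse = ""), "CC")
}

#' Generate a synthetic drug set with planted alert odds ratios
#'
#' Labels are fixed at `n_pos`/`n_neg`; alert indicators and the high-dose
#' flag are drawn independently per drug, class-conditionally. Each drug's
#' SMILES is an inert scaffold carrying the alert fragments for exactly the
#' drawn indicators, so re-screening the emitted SMILES against the planted
#' alert library reproduces the indicator matrix (verified at generation
#' time when `verify = TRUE`; any accidental cross-pattern match is reported
#' in `truth$cross_reactive`). Doses are log-uniform on the configured range,
#' partitioned at the cutoff by the drawn high-dose flag.
#'
#' With `smiles = FALSE` only the statistical layer (indicators, doses,
#' labels) is generated — orders of magnitude faster, used for large-n
#' parameter-recovery studies that never touch the chemistry layer.
#'
#' @param config A [syntheticConfig()].
#' @param smiles Emit and verify structures (default `TRUE`; needs RDKit).
#' @param verify Re-screen emitted SMILES against the planted library.
#' @return List: `drugs` (data.frame `drug_id,name,smiles,daily_dose_mg,label`),
#'   `indicators` (logical drugs x alerts matrix), `high_dose` (logical),
#'   `library` ([AlertLibrary] of planted alerts), `truth` (planted ORs,
#'   expected tables, config echo, cross-reactivity report).
#' @export
generateDrugSet <- function(config = syntheticConfig(), smiles = TRUE,
                            verify = smiles) {
  rng <- .seededRNG(config$seed)
  n <- config$n_pos + config$n_neg
  label <- rep(c("AD_POSITIVE", "AD_NEGATIVE"), c(config$n_pos, config$n_neg))
  pos <- label == "AD_POSITIVE"
  k <- nrow(config$alerts)

  ind <- matrix(FALSE, n, k,
                dimnames = list(NULL, config$alerts$alert_id))
  for (j in seq_len(k)) {
    p <- ifelse(pos, config$alerts$p_pos[j], config$alerts$p_neg[j])
    ind[, j] <- .withRNG(rng, stats::rbinom(n, 1, p)) == 1
  }
  p_dose <- ifelse(pos, config$p_dose_pos, config$p_dose_neg)
  high <- .withRNG(rng, stats::rbinom(n, 1, p_dose)) == 1
  lo <- log(config$dose_range[1]); cut <- log(config$dose_cutoff)
  hi <- log(config$dose_range[2])
  u <- .withRNG(rng, stats::runif(n))
  dose <- exp(ifelse(high, cut + u * (hi - cut), lo + u * (cut - lo)))
  dose <- pmin(dose, config$dose_range[2])
  dose[!high] <- pmin(dose[!high], config$dose_cutoff * (1 - 1e-9))

  drug_id <- sprintf("SYN%05d", seq_len(n))
  smi <- rep(NA_character_, n)
  if (smiles) {
    scaffold_pick <- config$scaffolds[
      .withRNG(rng, sample.int(length(config$scaffolds), n, replace = TRUE))]
    for (i in seq_len(n))
      smi[i] <- .assembleSmiles(config$alerts$fragment[ind[i, ]],
                                scaffold_pick[i])
  }
  drugs <- data.frame(drug_id = drug_id, name = paste0("synthetic-", drug_id),
                      smiles = smi, daily_dose_mg = dose, label = label,
                      stringsAsFactors = FALSE)
  rownames(ind) <- drug_id

  lib <- syntheticAlertLibrary(config)
  cross <- NULL
  if (smiles && verify) {
    r <- .matchRaw(smi, alertSmarts(lib))
    if (any(!r$smiles_ok))
      stop("scaffold/alert combination not synthesizable for drug(s): ",
           paste(utils::head(drug_id[!r$smiles_ok], 5), collapse = ", "))
    mismatch <- which(r$matches != ind, arr.ind = TRUE)
    if (nrow(mismatch)) {
      cross <- data.frame(drug_id = drug_id[mismatch[, 1]],
                          alert_id = colnames(ind)[mismatch[, 2]])
      warning("cross-reactive planted fragments: ",
              nrow(cross), " indicator mismatch(es); see truth$cross_reactive")
    }
  }
  truth <- list(
    planted_or = stats::setNames(
      plantedOddsRatio(config$alerts$p_pos, config$alerts$p_neg),
      config$alerts$alert_id),
    expected_tables = stats::setNames(
      lapply(config$alerts$alert_id, expectedContingency, config = config),
      config$alerts$alert_id),
    cross_reactive = cross,
    config = config)
  list(drugs = drugs, indicators = ind, high_dose = high,
       library = lib, truth = truth)
}

#' Write a drug set CSV
#'
#' @param drugs data.frame of drug records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeDrugSet <- function(drugs, path) {
  utils::write.csv(drugs, path, row.names = FALSE)
  invisible(path)
}
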