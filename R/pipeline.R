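#' End-to-end association run
#'
#' Screens a drug set against an alert library and writes the association
#' report files: `association_alerts.csv` (per-alert rows plus the any-alert
#' union and the dose-alone row, printed-table rounding applied),
#' `association_dose_cofactor.csv` (alert AND high-dose rows),
#' `exclusions.csv` (drugs dropped for unparsable SMILES or missing dose) and
#' `run_manifest.json`. Reports are byte-identical across reruns with the
#' same inputs and seed (no timestamps).
#'
#' @param drugs data.frame of drug records or path to a drug CSV.
#' @param alerts An [AlertLibrary] or path to an alert CSV; default the
#'   built-in library.
#' @param out_dir Output directory (created if needed).
#' @param dose_cutoff Daily-dose cutoff in mg (default 100).
#' @param seed Integer seed recorded in the manifest (screening itself is
#'   deterministic).
#' @param sort Report row ordering, see [associateAll()].
#' @return Invisibly, the association data.frame.
#' @export
runAssociation <- function(drugs, alerts = builtinAlerts(), out_dir,
                           dose_cutoff = 100, seed = 42,
                           sort = "pos_count") {
  if (is.character(drugs)) drugs <- readDrugSet(drugs)
  if (is.character(alerts)) alerts <- readAlertLibrary(alerts)
  if (!any(drugs$label == "AD_POSITIVE"))
    stop("no AD-positive drugs: association statistics are undefined")
  if (!any(drugs$label == "AD_NEGATIVE"))
    stop("no AD-negative drugs: association statistics are undefined")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  screen <- screenDrugs(drugs, alerts)
  rule <- doseRule(dose_cutoff)
  assoc <- associateAll(screen, rule, sort = sort)
  out <- formatAssociationTable(assoc)

  main <- out[out$kind %in% c("alert", "union", "dose"), , drop = FALSE]
  cof <- out[out$kind %in% c("alert_dose", "union_dose"), , drop = FALSE]
  utils::write.csv(main, file.path(out_dir, "association_alerts.csv"),
                   row.names = FALSE)
  utils::write.csv(cof, file.path(out_dir, "association_dose_cofactor.csv"),
                   row.names = FALSE)
  ex_ids <- metadata(screen)$excluded
  excl <- data.frame(drug_id = ex_ids,
                     reason = rep("unparsable_smiles", length(ex_ids)))
  nd <- attr(assoc, "n_dose_missing")
  utils::write.csv(excl, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  .writeManifest(file.path(out_dir, "run_manifest.json"), list(
    stage = "association", seed = seed, dose_cutoff = dose_cutoff,
    n_drugs = ncol(screen), n_alerts = nrow(screen),
    n_pos = sum(colData(screen)$label == "AD_POSITIVE"),
    n_neg = sum(colData(screen)$label == "AD_NEGATIVE"),
    n_excluded_smiles = length(metadata(screen)$excluded),
    n_dose_missing = nd,
    package_version = as.character(utils::packageVersion("AlertAD"))))
  invisible(assoc)
}

#' End-to-end model run
#'
#' Builds the binary feature matrix (alert flags + high-dose flag), performs
#' the stratified 80/20 split, grid-searches hyperparameters by 5-fold CV
#' balanced accuracy, evaluates on the held-out test set, runs the
#' permutation-null test, and writes `metrics.json`,
#' `attribution_summary.csv`, `permutation_scores.csv` and
#' `run_manifest.json`. All stages share the run seed.
#'
#' @param drugs data.frame of drug records or path to a drug CSV (must
#'   contain a `daily_dose_mg` column; missing column is a config error).
#' @param alerts An [AlertLibrary] or alert CSV path.
#' @param out_dir Output directory.
#' @param config A [modelConfig()]; its `seed` drives every random draw.
#' @param dose_cutoff Daily-dose cutoff in mg.
#' @return Invisibly, a list with `split`, `search`, `fit`, `perm`,
#'   `attributions`.
#' @export
runModel <- function(drugs, alerts = builtinAlerts(), out_dir,
                     config = modelConfig(), dose_cutoff = 100) {
  if (is.character(drugs)) drugs <- readDrugSet(drugs)
  if (is.character(alerts)) alerts <- readAlertLibrary(alerts)
  if (!"daily_dose_mg" %in% colnames(drugs))
    stop("config error: drug table has no daily_dose_mg column")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  screen <- screenDrugs(drugs, alerts)
  fm <- buildFeatureMatrix(screen, doseRule(dose_cutoff))
  split <- stratifiedSplit(fm, config$split_fraction, seed = config$seed)
  search <- gridSearchCV(split$train, config)
  fit <- trainAndEvaluate(split$train, split$test, search$best)
  perm <- permutationTest(split$train, search$best,
                          n_permutations = config$n_permutations,
                          n_cv_repetitions = config$n_cv_repetitions,
                          k_folds = config$k_folds, seed = config$seed + 1L)
  attr_train <- featureAttributions(fit$model, split$train@x)

  metrics <- as.list(fit$metrics)
  metrics$permutation <- list(mean_cv = perm$mean_cv,
                              mean_permuted = perm$mean_permuted,
                              t_statistic = perm$t_statistic,
                              p_value = perm$p_value)
  metrics$best_params <- search$best
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(data.frame(feature = names(attr_train$mean_abs),
                              mean_abs_attribution = attr_train$mean_abs,
                              row.names = NULL),
                   file.path(out_dir, "attribution_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(
    arm = rep(c("cv", "permuted"),
              c(length(perm$cv_scores), length(perm$permuted_scores))),
    balanced_accuracy = c(perm$cv_scores, perm$permuted_scores)),
    file.path(out_dir, "permutation_scores.csv"), row.names = FALSE)
  .writeManifest(file.path(out_dir, "run_manifest.json"), list(
    stage = "model", seed = config$seed, dose_cutoff = dose_cutoff,
    n_train = nrow(split$train@x), n_test = nrow(split$test@x),
    k_folds = config$k_folds,
    n_permutations = config$n_permutations,
    n_cv_repetitions = config$n_cv_repetitions,
    package_version = as.character(utils::packageVersion("AlertAD"))))
  invisible(list(split = split, search = search, fit = fit, perm = perm,
                 attributions = attr_train))
}

.writeManifest <- function(path, fields) {
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
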