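# Shared fixtures, built in code. Expensive objects are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Independent two-sided exact-test oracle: exhaustive enumeration of all 2x2
# tables with the observed margins, point probabilities via log binomial
# coefficients (a different route than the package's dhyper-based code).
fisherOracle <- function(tp, fn, fp, tn) {
  npos <- tp + fn; nneg <- fp + tn; m <- tp + fp
  ks <- max(0, m - nneg):min(m, npos)
  pr <- exp(lchoose(npos, ks) + lchoose(nneg, m - ks) -
              lchoose(npos + nneg, m))
  pobs <- pr[ks == tp]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

toyDrugs <- function() {
  data.frame(
    drug_id = c("aniline", "toluene", "benzene", "nmethylaniline",
                "dimethylaniline", "hexane"),
    name = c("aniline", "toluene", "benzene", "N-methylaniline",
             "N,N-dimethylaniline", "hexane"),
    smiles = c("Nc1ccccc1", "Cc1ccccc1", "c1ccccc1", "CNc1ccccc1",
               "CN(C)c1ccccc1", "CCCCCC"),
    daily_dose_mg = c(150, 50, 200, 100, 99.9, NA),
    label = c("AD_POSITIVE", "AD_NEGATIVE", "AD_NEGATIVE", "AD_POSITIVE",
              "AD_NEGATIVE", "AD_NEGATIVE"),
    stringsAsFactors = FALSE)
}

# a small synthetic world shared across tests (default 50/357 config)
smallSim <- function() cached("smallSim",
                              generateDrugSet(syntheticConfig(seed = 11)))

smallScreen <- function() cached("smallScreen", {
  sim <- smallSim()
  screenDrugs(sim$drugs, sim$library)
})

# single planted alert with odds ratio 6 at n = 400 (50 positives)
or6Config <- function(seed = 42) {
  alerts <- data.frame(alert_id = "planted_or6", smarts = "[NX3;H2]c1ccccc1",
                       description = "planted alert, odds ratio 6",
                       fragment = "c1ccc(N)cc1",
                       p_pos = 0.5, p_neg = 1 / 7, stringsAsFactors = FALSE)
  syntheticConfig(n_pos = 50, n_neg = 350, alerts = alerts, seed = seed)
}

or6Features <- function(seed = 42) {
  sim <- generateDrugSet(or6Config(seed), smiles = FALSE)
  featureMatrix(sim$indicators, sim$high_dose, sim$drugs$label)
}
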