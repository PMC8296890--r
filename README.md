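# AlertAD

Structural alerts and daily dose for flagging drug-induced autoimmune
disease (AD) risk.

Reactive metabolites — electrophilic biotransformation products that bind
covalently to proteins — are a well-documented trigger of drug-induced
autoimmunity. AlertAD screens drug structures (SMILES) against a library of
reactive-metabolite structural alerts (SMARTS), tests each alert flag
against the AD label with 2×2 contingency statistics, co-factors the flag
with a high daily-dose rule (≥ 100 mg/day), trains a gradient-boosted risk
classifier on the binary flags with a permutation-null validation and
additive feature attributions, and computes conceptual-DFT reactivity
descriptors from frontier orbital energies:

* sample odds ratio `OR = tp·tn / (fn·fp)` (Haldane–Anscombe +0.5 on zero
  cells), two-sided exact test by the point-probability rule, sensitivity /
  PPV / FPR / specificity / NPV;
* balanced accuracy `(sensitivity + specificity)/2`, MCC, rank-statistic AUC;
* global hardness `η = (E_LUMO − E_HOMO)/2`, chemical potential
  `μ = (E_LUMO + E_HOMO)/2`, electrophilicity index `ω = μ²/2η`.

A synthetic drug-set generator plants alerts with known class-conditional
prevalences (hence known odds ratios) into valid SMILES, so the entire
pipeline is testable end-to-end without external data.

Substructure chemistry is delegated to RDKit through the system `python`
interpreter (`python` with `rdkit` must be on PATH); statistics, the boosted
trees and everything else are in R.

## Worked example

```r
library(AlertAD)

sim    <- generateDrugSet(syntheticConfig(seed = 1))   # 50 AD+ / 357 AD-
screen <- screenDrugs(sim$drugs, sim$library)
assoc  <- formatAssociationTable(associateAll(screen, doseRule(100)))
assoc[assoc$kind %in% c("alert", "dose"),
      c("flag_id", "sensitivity_pct", "ppv_pct", "fpr_pct", "odds_ratio", "p_value")]
#>                 flag_id sensitivity_pct ppv_pct fpr_pct odds_ratio      p_value
#>  aromatic_primary_amine              30      26      12       3.21 1.618690e-03
#>                  alkene              26      20      15       2.06 6.063660e-02
#>      halogenated_carbon              22      15      17       1.40 4.249080e-01
#>                  phenol              14       9      19       0.68 4.416759e-01
#>               high_dose              72      22      36       4.60 1.920662e-06
```

The primary aromatic amine alert (planted odds ratio 2.91) comes out
significantly associated with the AD label, and high daily dose is the
strongest single flag — sensitive (72%) but unspecific (FPR 36%). AND-ing an
alert with the dose flag (the `alert_dose` rows of the same table) trades a
little sensitivity for a much lower false positive rate.

```r
fm  <- buildFeatureMatrix(screen, doseRule(100))
sp  <- stratifiedSplit(fm, 0.8, seed = 1)              # 325 train / 82 test
gs  <- gridSearchCV(sp$train, modelConfig(seed = 1))
fit <- trainAndEvaluate(sp$train, sp$test, gs$best)
pt  <- permutationTest(sp$train, gs$best, 100, 100, seed = 2)
round(c(fit$metrics["balanced_accuracy"], cv = pt$mean_cv, null = pt$mean_permuted), 3)
#> balanced_accuracy                cv              null
#>             0.526             0.719             0.506
```

Cross-validated balanced accuracy (0.72) is far above the label-reshuffled
null (0.51, Welch p ≈ 1e-65 at 100/100 arms), i.e. the model performs above
chance; the held-out estimate on 82 drugs is noisier. Feature attributions
(`featureAttributions(fit$model, sp$train@x)`) rank `high_dose` first, then
the planted amine alert.

```r
rankByElectrophilicity(data.frame(
  compound_id = c("aromatic_amine", "methyl_control",
                  "nitroso_metabolite", "quinone_imine_metabolite"),
  e_homo = c(-0.22, -0.24, -0.26, -0.25),
  e_lumo = c(-0.01, -0.01, -0.12, -0.14)))
#>               compound_id e_homo e_lumo   eta     mu      omega
#>  quinone_imine_metabolite  -0.25  -0.14 0.055 -0.195 0.34568182
#>        nitroso_metabolite  -0.26  -0.12 0.070 -0.190 0.25785714
#>            methyl_control  -0.24  -0.01 0.115 -0.125 0.06793478
#>            aromatic_amine  -0.22  -0.01 0.105 -0.115 0.06297619
```

The electrophilic metabolites rank far above the parent aromatic amine —
consistent with toxicity being mediated by the metabolites, not the parent.

A thin command-line wrapper with `simulate`, `screen`, `associate`, `train`,
`descriptors` and `run-all` subcommands ships at
`inst/scripts/alertad.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch against the installed package:
generates the synthetic drug set for the given seed, verifies the
screening round trip, prints the association table, grid-searches and
evaluates the risk model, runs the permutation null (100/100 arms), ranks
the descriptor panel, and writes the JSON result file.

## Package layout

- `R/` — alert library, screening, association statistics, boosted trees,
  risk model, descriptors, synthetic generator, pipeline runners
- `inst/python/chem_tools.py` — batch RDKit helper (stdin/stdout JSON)
- `inst/extdata/builtin_alerts.csv` — built-in alert library
- `vignettes/alert-screening-methods.Rmd` — methods and design choices
- `tests/testthat/` — unit, property and acceptance tests
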