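---
title: "Structural alerts, daily dose, and drug-induced autoimmune disease risk: methods"
author: "AlertAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural alerts, daily dose, and AD risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AlertAD)
```

## The problem and the model

Drug-induced autoimmune disease (AD) is strongly linked to reactive
metabolites: electrophilic biotransformation products that bind covalently to
proteins (haptenization) and can break immune tolerance. A compound's
propensity to form reactive metabolites is largely encoded in its 2D
structure, so *structural alerts* — SMARTS substructure patterns curated for
reactive-metabolite formation — are a natural prescreening signal. Alerts
alone, however, are notoriously over-sensitive: safe and toxic drugs often
share the same alert, so the false positive rate of alert-only flagging is
high. AlertAD implements the two-layer remedy this package is built around:

1. **Contingency association with dose co-factoring.** Each alert flag is
   crossed with the binary AD label in a 2×2 table. Because
   reactive-metabolite toxicity is strongly exposure-dependent, the alert
   flag is additionally AND-ed with a *high daily dose* flag
   (dose ≥ 100 mg/day, boundary inclusive). The statistics per flag are the
   sample odds ratio, the two-sided exact test, and the confusion ratios
   (sensitivity, PPV, FPR, specificity, NPV).
2. **A gradient-boosted risk classifier** on the binary feature set
   (one column per alert plus the dose flag), validated by a
   label-reshuffling permutation null and explained by additive per-feature
   attributions.

A conceptual-DFT module complements this: from frontier orbital energies it
computes global hardness $\eta = (E_{LUMO}-E_{HOMO})/2$, chemical potential
$\mu = (E_{LUMO}+E_{HOMO})/2$ and the electrophilicity index
$\omega = \mu^2 / 2\eta$, and ranks compounds by $\omega$ (ties broken by
ascending $E_{LUMO}$). Electrophilic metabolites such as nitroso or quinone
imine species rank far above their parent aromatic amines.

## The alert library

The built-in library ships the nitrogen-on-benzene family — any substitution
plus the two / one / no N–H variants (primary, secondary, tertiary aromatic
amines) — together with the other frequently matched reactive-metabolite
alerts (alkenes, halogenated methylbenzene, phenol, halogenated carbon,
methoxy/methyl aromatic patterns) and the decomposed "nitrogen-containing
compound" and "benzene" patterns. The published alert collections contain on
the order of 171 patterns, but only the top patterns are printed as
descriptions and depictions; the full list is *data, not code*. Users load
extended libraries from CSV (`alert_id,smarts,description[,family,source]`,
UTF-8); every SMARTS must compile, and offending records are reported by id.

SMARTS matching, SMILES parsing, canonicalization and salt stripping are
delegated to RDKit through the system `python` interpreter, in batch JSON
calls (one interpreter start-up per screening run). Structures are
standardized before matching: the largest covalent fragment is kept and
stereochemistry is dropped, because alerts are 2D patterns. Drugs whose
SMILES fail to parse are excluded and reported, never silently dropped, so
batch screening always completes.

## Association statistics and their conventions

For a flag with counts $(tp, fn, fp, tn)$ the package reports the
uncorrected cross-product odds ratio $OR = tp \cdot tn / (fn \cdot fp)$.
When any cell is zero, the Haldane–Anscombe correction adds 0.5 to every
cell and the result is marked `zero_cell_corrected`. The uncorrected
estimator is the one under which every dose-co-factored published table
value reproduces exactly; several alert-alone published ORs sit slightly
above the cross-product value recomputed from their own printed counts (the
estimator behind those rows is unstated upstream), and the package documents
rather than imitates that discrepancy.

The exact test conditions on both margins: the flagged count among positives
is hypergeometric, and the two-sided p-value follows the point-probability
(minimum-likelihood) rule — the sum of probabilities of all margin-fixed
tables whose point probability does not exceed the observed one, with a
$1 + 10^{-7}$ relative tolerance against floating-point ties. A mid-p
variant is available (`method = "midp"`). No multiple-testing correction is
applied by default because the emulated workflow reports raw p-values across
the whole library; a Benjamini–Hochberg column can be switched on.

Printed-table rounding is half *away from zero*: percentages to the nearest
integer and odds ratios to 2 decimals. This matters: IEEE half-even rounding
would print $6.125$ as $6.12$ where the published table prints $6.13$.

Ratios with zero denominators (e.g. PPV when nothing is flagged) are
reported as missing, not zero.

## The risk model

No gradient-boosting package is available in this R environment, so the
classifier is implemented in the package: second-order (Newton) boosting
with logistic loss on binary features, depth-limited greedy trees, L2 leaf
regularization ($\lambda = 1$), shrinkage, and optional balanced class
weights $w = n / (2 n_{class})$ — with a 50:357 imbalance the minority class
would otherwise be ignored. Because features are binary, a node can split a
feature at most once and the candidate scan vectorizes; the fit is fully
deterministic given the data (no row or column subsampling).

* **Split and tuning.** The stratified 80/20 split takes
  $\lfloor 0.8\,n_{class} \rfloor$ of each class for training (407 drugs →
  325/82). Hyperparameters are grid-searched — default grid depth
  $\{2,4,6\}$ × learning rate $\{0.03,0.1,0.3\}$ × iterations $\{100,300\}$,
  class weighting on — by mean balanced accuracy over 5 stratified folds,
  with all grid points paired on the same fold draw and a first-in-grid tie
  break. The published grid is in an appendix that is not reproduced, so
  this default is the package's own choice for a small categorical feature
  space.
* **Permutation null.** 1000 label-reshuffled copies (each scored by k-fold
  CV) against 1000 repeated CVs on intact labels with fresh fold sampling,
  compared by a two-sided Welch t-test. The permutation arm re-uses the
  tuned hyperparameters rather than re-tuning per permutation: re-tuning
  ×1000 is disproportionate, and either convention is slightly
  anti-conservative in some direction; this is the documented choice.
  Balanced accuracy of reshuffled labels is centred on 0.5 regardless of
  class imbalance, which is why it is the scoring function.
* **Attribution.** Per-feature attributions use the exact tree-path
  decomposition: walking from the root, each split credits its feature with
  the change in the node's Newton value, summed over trees. By telescoping,
  `base_value + rowSums(phi)` equals the margin output to machine precision
  (local accuracy). This is the "Saabas" decomposition, not Shapley-weighted
  averaging over orderings; for shallow trees on near-independent binary
  features the rankings agree well, and the local-accuracy invariant is
  exact by construction.
* **Metrics.** Balanced accuracy is computed as
  $(\text{sensitivity}+\text{specificity})/2$ identically, MCC from the
  confusion matrix, and AUC as the rank-sum statistic with average-rank tie
  handling (`NA` for a single-class test set).

All randomness (splits, folds, reshuffles) flows from one seeded generator
that never touches the caller's global RNG state; runs with the same config
and seed are bit-reproducible.

## The synthetic world

The generator emulates the statistical structure of the curated 407-drug
dataset, and its defaults *are* that stated world:

* 50 AD-positive / 357 AD-negative drugs;
* four planted alerts with class-conditional prevalences taken from the
  frequently matched alerts (e.g. the primary aromatic amine at 14/50
  positives vs 42/357 negatives, planted odds ratio
  $OR = p_1(1-p_0)/[(1-p_1)p_0] \approx 2.91$);
* high-dose probability 36/50 for positives, 141/357 for negatives;
* dose values log-uniform on [1, 1000] mg partitioned at the 100 mg cutoff
  by the drawn flag;
* alerts independent of each other and of dose given the class, mirroring
  the separate co-factoring of the emulated analysis.

Each drug's SMILES is an inert alkane/cyclohexane scaffold to which the
carrier fragment of every drawn alert is chemically attached (e.g. an
aminophenyl branch for the primary aromatic amine). The four default
carriers were chosen mutually non-cross-reactive, so screening the emitted
SMILES reproduces the drawn indicator matrix exactly; any accidental
cross-pattern match would be detected at generation time and reported in
`truth$cross_reactive`.

What a green test does and does not establish: the generator reproduces
class imbalance, planted effect sizes, and alert/dose prevalences, but not
real medicinal-chemistry structure — no correlated alert co-occurrence, no
realistic property distributions, no matched decoys, and far simpler
molecules than marketed drugs. Pipeline-level results on synthetic data
validate the machinery, not the published test-set metrics, which depend on
the unpublished 407-drug table.

Two statistical subtleties are deliberate:

* **Exact-test conservativeness.** Under a planted odds ratio of 1 the
  exact p-value is *super-uniform* (discrete tables make the test
  conservative). The null-calibration test therefore checks one-sided
  deviation of the ECDF above the diagonal ($D^+$), not two-sided
  uniformity, which would reject for the wrong reason.
* **OR-recovery variance.** At tenfold scale (500/3570) the canonical
  planted alert's sample OR lands within 20% relative error of the planted
  value in about 92% of draws (observed 90/100 at the fixed seed set). This
  margin is a property of the estimator's sampling variance, not of the
  implementation: for the low-prevalence phenol alert (planted OR 0.68) the
  normal-approximation coverage of a ±20% band is only ≈ 83%, so a pooled
  all-alert version of the same check would sit below 90% by construction.

## Numerical choices and degenerate inputs

* Dose boundary inclusive at the cutoff (100 mg exactly is high-dose).
* Missing doses follow an exclude-and-report policy (configurable to error).
* Single-class label vectors are an error for every association operation.
* The exact test requires integer counts; expected (real-valued) tables from
  the planted truth support the other statistics but not the test.
* Orbital energies must have a positive HOMO–LUMO gap; mixed units in one
  input file are an error (hartree is the working unit, with an eV
  conversion helper; note $\omega$ is *not* invariant under a common shift
  of both energies).
* Grid-search ties break first-in-grid; ranking ties in the descriptor
  module break by ascending $E_{LUMO}$, then compound id.

## Limitations

* The built-in alert library covers the printed top patterns, not the full
  published collection; SMARTS were authored from the printed descriptions.
* The boosted-tree implementation is a standard second-order GBDT; it does
  not replicate the ordered-boosting or symmetric-tree variants of some
  production boosting libraries, so published test metrics are not expected
  to reproduce number-for-number even with the real data.
* Attributions are tree-path (Saabas) values, exact for local accuracy but
  not Shapley-symmetric.
* DFT itself (geometry optimization, functionals, solvation) is out of
  scope; the descriptor module consumes orbital energies from any source.
```{r example, eval = FALSE}
sim <- generateDrugSet(syntheticConfig(seed = 1))
screen <- screenDrugs(sim$drugs, sim$library)
head(formatAssociationTable(associateAll(screen)))
```
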