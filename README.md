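# spatmap

Subcellular spatial proteome maps from differential-centrifugation
fractionation profiles, for comparing the cellular architecture of two
cell lines.

In a LOPIT-DC experiment, organelles are partially separated into ten
sequential centrifugation pellets, TMT 10-plex labeled and quantified in
one MS run, so every protein acquires a 10-point relative abundance
profile that fingerprints its subcellular compartment. `spatmap`
implements the full analysis chain over such data:

* **Preprocessing** of MaxQuant-style `proteinGroups` tables: decoy /
  contaminant / site-only filtering, complete reporter-series retention
  (30 channels across three replicates for combined maps), per-replicate
  profile normalization `x_ij / sum_j x_ij`, replicate merging, and
  Perseus-style left-shifted imputation of lysate LFQ values
  (`N(mean - 1.8 sd, (0.3 sd)^2)` per sample).
* **Localization prediction**: a marker-trained multiclass RBF SVM
  (`K(x,y) = exp(-sigma ||x-y||^2)`), tuned by grid search (cost 20..60
  step 2, sigma 0.01..100 in powers of ten) on the mean **macro F1** of
  repeated stratified 80/20 marker splits, with 5-fold cross-validation
  of the chosen point; predictions with SVM score < 0.7 are labeled
  `unknown`. Map resolution is scored by **QSep** (between- over
  within-cluster marker distances).
* **Concordance** between map pairs, overall and stratified by SVM-score
  class (>= 0.9 / 0.7-0.9 / 0.5-0.7 / < 0.5).
* **Differential localization (DL)**: each protein is described by its
  **Mahalanobis distance profile** to every compartment,
  `d_c = sqrt((x - mu_c)' Sigma_c^{-1} (x - mu_c))`, with robust
  (minimum covariance determinant) compartment statistics estimated per
  replicate map; distances are compared between cell lines by two-sided
  Student t-tests with Benjamini-Hochberg correction over all
  protein x compartment tests, and a protein is DL when its closest
  compartment changes with both relevant distance changes significant —
  or when its map classification changes outright.
* **Proteomic ruler**: copies per cell anchored on the histones,
  `copies_i = (I_i / sum_h I_h) * (genome_size * ploidy * 615.8771) /
  MW_i`, from yield-weighted TMT fractions or lysate LFQ; relative
  organelle protein masses under a nucleus / organelle / cytosol
  fraction-group weighting.
* **Expression**: moderated differential expression with a
  peptide-count-informed variance prior (DEqMS-style, via a trended
  empirical-Bayes shrinkage), Fisher-exact term enrichment, and
  profile-correlation colocalization ranking within a cluster.
* A **ground-truthed synthetic generator** (two cell lines x three
  replicate maps, systematic organelle-profile shifts between lines,
  planted translocators, log-normal abundances with a histone anchor,
  left-censored lysates) that makes every stage testable end to end.

See `vignettes/spatmap-methods.Rmd` for the models, parameter meanings
and design choices, and `analysis/01_simulate.R` ... `06_expression.R`
for the narrative workflow over a benchmark experiment.

## Worked example

```r
library(spatmap)

# a two-line benchmark: 3000 proteins, 720 markers over 11 compartments,
# 12 proteins translocating ER -> PM in line B
cfg <- simulation_config(
  translocations = data.frame(from = rep("ER", 12), to = rep("PM", 12)),
  seed = 2026)
exp_ <- simulate_experiment(cfg)

# preprocess and classify both combined maps
pre <- lapply(exp_$maps, function(m) {
  singles <- lapply(m, normalize_profiles)
  list(singles = singles, combined = combine_replicates(singles))
})
cA <- classify_map(pre$A$combined, exp_$markers, cost = 48, sigma = 1)
cB <- classify_map(pre$B$combined, exp_$markers, cost = 48, sigma = 1)
print(cA)
#> classified_map: 3000 proteins (720 markers), 2280 classified, 0 unknown

# differential localization between the lines
dl <- detect_dl(pre$A$singles, pre$B$singles, cA, cB, alpha = 0.05)
nrow(dl$table)
#> [1] 12
head(dl$table, 2)
#>   accession                    stage compartment_A compartment_B
#> 1  SIM00011 qualitative+quantitative            ER            PM
#> 2  SIM00027              qualitative            ER            PM
```

All 12 planted translocators are recovered with the correct (ER, PM)
compartment pair and no false positives. On this benchmark the tuned
classifier reaches a 5-fold CV macro F1 of 1.000, the mean off-diagonal
QSep is ~27, replicate-map concordance is 1.000 overall, and
ruler-estimated copy numbers recover the simulated truth with a median
|log2(estimated/true)| of 0.049 (lysate- vs fraction-derived copies:
Pearson r = 1.00, slope = 1.00). Rerunning the `analysis/` scripts
prints these numbers and writes the underlying tables to `results/`.

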