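---
title: "Spatial proteome maps from fractionation profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial proteome maps from fractionation profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatmap)
```

# The problem

In LOPIT-DC style spatial proteomics, a gentle cell lysate is separated
by sequential differential centrifugation into ten fractions, each
labeled with one channel of a TMT 10-plex and quantified in a single MS
run. Organelles pellet at characteristic speeds, so the relative
abundance profile of a protein across the ten fractions fingerprints its
subcellular compartment. Marker proteins of known residence train a
classifier that transfers compartment labels to the rest of the
quantified proteome; comparing two cell lines then asks which proteins
change compartment (differential localization, DL) and how the protein
mass of whole organelles differs (proteomic ruler).

`spatmap` implements this chain end to end: preprocessing of
MaxQuant-style `proteinGroups` tables, SVM localization prediction, map
concordance, DL detection by Mahalanobis distance profiles, and
proteomic-ruler copy-number and organelle-mass estimation — together
with a ground-truthed synthetic generator so that every stage can be
validated without access to raw MS data.

# Preprocessing model

Identifications flagged as reverse-database decoys, potential
contaminants, or "only identified by site" are removed. A protein enters
a single-replicate map only with a complete reporter-ion series (a zero
reporter intensity is treated as missing, because MaxQuant writes zeros
for absent reporter ions); it enters the *combined* map only when the
series is complete across all replicates of the cell line (30 channels
for a 3 x 10-plex design). Profiles are normalized per protein to
relative intensities within each replicate's ten channels, and combined
maps are the per-protein mean of the replicate profiles, renormalized.
We normalize within each 10-channel replicate block (rather than once
over all 30 channels) so that replicates contribute equally to the
mean regardless of their global intensity level.

Whole-cell lysate LFQ values are log2-transformed; proteins must be
observed in all replicates of at least one line, and remaining missing
values are drawn per sample from a normal distribution down-shifted by
1.8 column SDs with width 0.3 column SDs — the standard Perseus
treatment of left-censored (below detection limit) missingness.

# Localization prediction

A multiclass SVM with RBF kernel `exp(-sigma * ||x - y||^2)` is trained
on the marker profiles (`sigma` is e1071's `gamma`). Hyperparameters are
selected on a grid (cost 20..60 in steps of two, sigma 0.01..100 in
powers of ten) by the mean macro F1 — the unweighted mean over
compartments of the harmonic mean of precision and recall — across
repeated stratified 80/20 splits of the markers, with ties broken toward
the smaller cost and sigma (the smoother model). A final stratified
5-fold cross-validation of the chosen point is reported.

**The SVM score.** Published marker-based localization pipelines report
a per-protein "SVM score" without an algebraic definition. We define it
as the maximum per-class membership probability obtained by pairwise
coupling of the one-vs-one decision values (Wu-Lin), where each binary
decision value is passed through a sigmoid of fixed slope: 5 per unit of
that pair's typical training margin, measured as the median absolute
decision value of the pair's own markers. Fitting the sigmoids to the
data instead (Platt scaling, as libsvm does) is ill-conditioned when the
binary subproblems are cleanly separable — on synthetic marker clusters
the fitted maximum probability can collapse for some datasets while
reaching ~0.95 for statistically identical ones — whereas the fixed-slope
score is deterministic, stable, close to 1 deep inside a marker cluster,
and low both between clusters and far away from all of them. The slope
constant was chosen once so that a marker sitting at the typical
within-cluster margin receives a coupled probability of about 0.95.
Non-marker proteins scoring below the classification threshold (default
0.7) are labeled `unknown`; marker proteins always retain their
annotated compartment, so the threshold invariant applies to non-markers.

Map resolution is summarized by QSep: the mean euclidean distance
between the markers of two clusters, normalized to the mean
within-cluster distance of the reference cluster (diagonal 1; larger
off-diagonal entries mean better separation).

# Concordance

Concordance of two classified maps is the fraction of overlapping
non-marker proteins with identical labels, `unknown` counting as a
label. It is stratified by score classes (>= 0.9, 0.7-0.9, 0.5-0.7,
< 0.5); because the two maps score a protein differently, the stratum is
assigned by the *minimum* of the two scores — the conservative,
symmetric choice.

# Differential localization

DL detection is two-staged. Stage 1 (qualitative): proteins classified
to different, non-`unknown` compartments in the two combined maps.
Stage 2 (quantitative): each protein's position is expressed as a
profile of Mahalanobis distances to every compartment,
`d_c = sqrt((x - mu_c)' Sigma_c^{-1} (x - mu_c))`, with compartment
center and scatter estimated robustly by the minimum covariance
determinant (MCD) over the compartment's members (SVM-classified
proteins plus markers). Because the two nuclear subcompartments are not
resolved in every cell line, nuclear labels are merged into one
`nucleus` class first, giving a common 10-class taxonomy.

Several numerical choices matter here:

* **Rank deficiency.** Normalized profiles live on a simplex, so their
  covariance is singular. All distances are computed after an isometric
  projection onto the 9-dimensional orthogonal complement of the
  all-ones vector, plus a ridge floor of `1e-8 * trace/dim` keeping the
  MCD scatter positive definite (identical member profiles degrade to a
  spherical floor rather than an error).
* **MCD.** `mcd_cov()` implements FAST-MCD (concentration steps from
  random starts) with support size `floor((n + dim + 1)/2)` and the
  usual Gaussian consistency factor; for small n the search is
  exhaustive, making the estimate exactly the MCD (and testable against
  brute-force subset search).
* **Replicate statistics.** Distances are computed per replicate map
  against that replicate's own compartment statistics (membership taken
  from the combined map), so each condition contributes three
  independent distance measurements per protein and compartment.
  Closest compartments are decided on the combined maps, which are the
  reference for localization.
* **Testing.** Each protein x compartment distance is compared between
  conditions by a two-sided two-sample Student t-test and adjusted by
  Benjamini-Hochberg over the full protein x compartment family. A
  protein is quantitatively DL when its closest compartment changes
  *and* the distances to both closest compartments change significantly
  (q <= 0.05). Zero replicate variance in both groups yields p = 1 when
  the means agree, and is treated as significant (with a warning) when
  they differ. Exact closest-compartment ties resolve to the earlier
  taxonomy class, with a warning.

The procedure deliberately does not correct for cluster size: a large,
diffuse compartment has systematically smaller Mahalanobis distances
and can "overlay" small tight ones, which slightly biases closest-
compartment calls toward large clusters. This is a known limitation of
distance-based DL detection.

# Proteomic ruler

Copy numbers follow the histone ruler: histones are stoichiometric with
DNA, so `copies_i = (I_i / sum of histone intensities) * (genome_size *
ploidy * 615.8771 g/mol) / MW_i` (615.8771 g/mol is the mean molar mass
of a DNA base pair, the Perseus default). Ploidy can be derived from a
genome-size ratio as `2 * genome/reference` (e.g. 2 x 2.399/2.72 = 1.76
for a hamster line referenced to mouse). The estimate is invariant to
rescaling all intensities.

For TMT fractions, channels are first normalized to the total channel
intensity and weighted by the fraction's protein yield, making the
weighted value an estimate of the protein mass recovered in the
fraction; weighted values are summed into one quantity per protein and
replicate. Organelle protein masses weight each protein's mass per cell
by the share of its signal in the fraction group matching its assigned
compartment — nucleus (fraction 1), organelle (fractions 2-9), cytosol
(fraction 10); nuclear classes use the nucleus share, the cytosol class
the cytosol share, every other class (including the ribosome and
proteasome particles, which pellet across the organellar fractions) the
organelle share. This three-group weighting is our documented
interpretation of the published construction, whose full detail lives in
supplementary material we treat as unavailable. Mass not captured by a
compartment (unclassified proteins plus each protein's out-of-group
remainder) is pooled as `unassigned`, so the reported fractions always
close to 1 within 1e-9.

# Differential expression and enrichment

Two-group differential expression uses a moderated t-statistic whose
per-protein variance is shrunk by empirical Bayes toward a trend over
log peptide count (proteins quantified by few peptides are noisier);
the prior degrees of freedom and the count-dependent prior variance are
estimated with `limma::squeezeVar`, and the posterior variance
`(d0 s0^2 + d s^2)/(d0 + d)` enters a t-statistic with `d0 + d` degrees
of freedom. As the prior df tends to 0 this reduces to the ordinary
t-test, and as it tends to infinity the variance collapses onto the
trend — both limits are exercised in the tests. Term enrichment is a
two-sided Fisher exact test per term with BH adjustment (default FDR
0.02). Colocalization ranking computes, for every non-anchor member of a
cluster, the mean Pearson correlation of its combined-map profile with
the anchor proteins' profiles (the anchors themselves are excluded).

# The synthetic generator

`simulation_config()` / `simulate_experiment()` emulate the study
design: two conditions x three replicate maps x ten fractions, plus
lysate triplicates. What it reproduces, and what not:

* **Compartment profiles.** Each compartment's mean profile is drawn
  from a Dirichlet with one dominant fraction placed along the
  pelleting order (nuclei first, cytosol last);
  `profile_concentration` (default 400) tunes sharpness and hence
  separability. Condition B's means are log-normally perturbed
  (`organelle_shift_sd`, default 0.15), reproducing the systematic
  whole-organelle profile shifts observed between cell lines — which is
  exactly why DL detection works on distances within each map rather
  than on profile differences across maps.
* **Noise.** Reporter noise is multiplicative log-normal per channel
  (`noise_sd`, default 0.1), applied before row renormalization, as
  reporter-ion noise is intensity-proportional. At `noise_sd = 0` every
  protein's normalized profile equals its compartment mean exactly — a
  limit the tests rely on. Within-compartment biological heterogeneity
  (multilocal proteins, microheterogeneity) is *not* modeled, so
  synthetic clusters are cleaner than real ones; passing tests
  demonstrate correctness of the machinery, not field performance.
* **Markers.** Default 3000 proteins with marker fraction 0.24 give 720
  markers (~65 per class), matching the per-class marker density of
  curated organelle marker sets; every compartment is guaranteed
  `max(8, n_fractions + 2)` markers so covariance estimation stays
  feasible. Marker density is what drives realistic score behavior.
* **Abundances and the ruler anchor.** Copies per cell are log-normal
  (median 2e4, sigma 1.8 on the natural log — a realistic proteome
  dynamic range); a configurable histone set (default 8 proteins near
  14 kg/mol) resides in the chromatin compartment, never translocates,
  and its summed mass is scaled to equal the DNA mass
  `genome_size * ploidy * 615.8771`, so ruler estimates are exactly
  recoverable at zero noise. TMT intensities are simulated
  mass-proportional (`copies x MW x profile x noise`) as MS signal
  tracks mass, which the ruler arithmetic requires; fraction yields are
  the column mass totals.
* **Lysates.** Log2 intensity is `log2(copies x MW)` plus noise scaling
  as `1/sqrt(peptide count)` (the premise of count-informed variance
  moderation); missingness is left-censored with probability
  `clamp(intercept + slope * (q25 - log2 intensity))`.
* **Not modeled.** Spectra, peptide-level quantification, isotope
  impurity, chromatographic artifacts, protein complexes, multilocal
  proteins.

# Problem sizes of the validation studies

The stochastic validation studies are sized to run on a laptop and are
the package's own choices: the null false-discovery study uses 200
simulations of a reduced 600-protein experiment over the full 11-class
taxonomy (marker fraction 0.25 keeps >= 12 markers per class); the
power study plants 12 ER->PM translocators per run over 5 runs of the
default-size benchmark; the concordance-strata study raises `noise_sd`
to 0.4 because at the default noise nearly every protein scores in the
top stratum and the lower strata would be empty.

# Known limitations

* The score calibration constant (slope 5) is definitional; scores are
  comparable across maps built by this package but not numerically
  identical to other pipelines' SVM scores.
* DL closest-compartment calls inherit the cluster-size bias discussed
  above.
* The organelle mass weighting is an interpretation (see above).
* `tune_svm` with the full default grid (105 points x 100 repeats) is
  expensive on large marker sets; the analysis scripts use a reduced
  grid that reaches the same optimum on the benchmark.
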