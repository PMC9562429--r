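# Simulation studies over the full pipeline: null false-positive control
# and power of the differential-localization procedure, and concordance
# behavior across SVM-score strata. These drive the repository's
# analysis scripts and the acceptance checks.

# preprocess one condition's raw maps into singles + combined
.pre_maps <- function(raw_maps) {
  singles <- lapply(raw_maps, normalize_profiles)
  list(singles = singles, combined = combine_replicates(singles))
}

# run the classification + DL chain on one simulated experiment
.dl_chain <- function(sim, seed, cost = 48, sigma = 1, alpha = 0.05) {
  pA <- .pre_maps(sim$maps$A)
  pB <- .pre_maps(sim$maps$B)
  cA <- classify_map(pA$combined, sim$markers, cost, sigma,
                     seed = derive_seed(seed, "chain-A"))
  cB <- classify_map(pB$combined, sim$markers, cost, sigma,
                     seed = derive_seed(seed, "chain-B"))
  detect_dl(pA$singles, pB$singles, cA, cB, alpha = alpha)
}

#' Null study: DL false-positive control
#'
#' Repeatedly simulates two-condition experiments without any planted
#' translocations and runs the full classification + DL chain; every DL
#' call is a false positive. Reports the per-simulation false-positive
#' proportion among the proteins entering the quantitative stage.
#'
#' @param n_sims number of simulated experiments.
#' @param config simulation configuration template (its seed is replaced
#'   per simulation); the default is a reduced 600-protein experiment
#'   over the full 11-class taxonomy.
#' @param seed master seed.
#' @param alpha BH false-discovery level of the DL stage.
#' @return data frame per simulation: `n_tested`, `n_false`, `fp_rate`.
#' @export
dl_null_study <- function(n_sims = 200,
                          config = simulation_config(n_proteins = 600,
                                                     marker_fraction = 0.25),
                          seed = 1, alpha = 0.05) {
  out <- lapply(seq_len(n_sims), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste("null", i))
    cfg$translocations <- NULL
    sim <- simulate_experiment(cfg)
    dl <- .dl_chain(sim, seed = cfg$seed, alpha = alpha)
    n_tested <- nrow(dl$quantitative)
    n_false <- nrow(dl$table)  # no translocations: every call is false
    data.frame(n_tested = n_tested, n_false = n_false,
               fp_rate = n_false / n_tested)
  })
  do.call(rbind, out)
}

#' Power study: recovery of planted translocators
#'
#' Simulates experiments with `n_translocations` proteins moved from one
#' compartment to another between conditions and measures how many are
#' recovered by the DL chain with the correct closest-compartment pair.
#'
#' @param n_runs number of simulated experiments.
#' @param n_translocations planted translocators per experiment.
#' @param from,to source and destination compartments.
#' @param config simulation configuration template.
#' @param seed master seed.
#' @param alpha BH false-discovery level.
#' @return data frame per run: `n_planted`, `n_detected` (correct pair),
#'   `n_false`.
#' @export
dl_power_study <- function(n_runs = 5, n_translocations = 12,
                           from = "ER", to = "PM",
                           config = simulation_config(), seed = 1,
                           alpha = 0.05) {
  out <- lapply(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste("power", i))
    cfg$translocations <- data.frame(from = rep(from, n_translocations),
                                     to = rep(to, n_translocations))
    sim <- simulate_experiment(cfg)
    dl <- .dl_chain(sim, seed = cfg$seed, alpha = alpha)
    tr <- sim$truth$proteins
    planted <- tr$accession[tr$compartment_A != tr$compartment_B]
    tab <- dl$table
    hit <- tab$accession %in% planted &
      tab$compartment_A == from & tab$compartment_B == to
    data.frame(n_planted = length(planted), n_detected = sum(hit),
               n_false = length(setdiff(tab$accession, planted)))
  })
  do.call(rbind, out)
}

#' Concordance across SVM-score strata on replicate map pairs
#'
#' Classifies every single-replicate map of one simulated condition and
#' aggregates pairwise concordance per score stratum over all map pairs.
#'
#' @param config simulation configuration; the default uses a higher
#'   channel noise (0.4) so that the lower score strata are populated.
#' @param cost,sigma SVM hyperparameters.
#' @param seed classification seed.
#' @return data frame per stratum: `n`, `concordance` (pooled over
#'   pairs; `NA` for empty strata).
#' @export
concordance_strata_study <- function(
    config = simulation_config(noise_sd = 0.4, seed = 17),
    cost = 48, sigma = 1, seed = 2) {
  sim <- simulate_experiment(config)
  singles <- lapply(sim$maps$A, function(m)
    classify_map(normalize_profiles(m), sim$markers, cost, sigma,
                 seed = seed))
  strata <- c("very_high", "high", "medium", "low")
  n <- agree <- stats::setNames(numeric(4), strata)
  prs <- utils::combn(length(singles), 2)
  for (j in seq_len(ncol(prs))) {
    st <- stratified_concordance(singles[[prs[1, j]]],
                                 singles[[prs[2, j]]])
    ok <- !is.na(st$concordance)
    n[st$stratum[ok]] <- n[st$stratum[ok]] + st$n[ok]
    agree[st$stratum[ok]] <- agree[st$stratum[ok]] +
      st$n[ok] * st$concordance[ok]
  }
  data.frame(stratum = strata, n = as.integer(n),
             concordance = ifelse(n > 0, agree / pmax(n, 1), NA_real_))
}
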