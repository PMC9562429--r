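# Ground-truthed synthetic experiment generator.
#
# Emulates a two-cell-line LOPIT-DC style design: organelles are partially
# separated over 10 sequential centrifugation fractions, so each protein's
# relative abundance profile across fractions fingerprints its compartment.
# Two conditions ("A" and "B", standing in for two cell lines) share a
# protein complement; compartment mean profiles shift systematically
# between conditions, and designated translocator proteins change their
# true compartment outright.

#' Default 11-class organelle marker taxonomy
#' @export
default_taxonomy <- function() {
  c("cytosol", "ER", "Golgi", "lysosome", "mitochondrion",
    "nucleus_chromatin", "nucleus_nonchromatin", "peroxisome", "PM",
    "proteasome", "ribosome")
}

# Pelleting order used to place each compartment's dominant fraction:
# nuclei pellet first, soluble material last.
.pellet_order <- c("nucleus_chromatin", "nucleus_nonchromatin", "nucleus",
                   "mitochondrion", "lysosome", "peroxisome", "ER",
                   "Golgi", "PM", "proteasome", "ribosome", "cytosol")

#' Simulation configuration
#'
#' Parameters of the synthetic two-condition spatial-proteomics
#' experiment: three replicate maps of 10 fractions per condition plus
#' whole-cell lysate triplicates.
#'
#' @param n_proteins number of proteins.
#' @param compartments ordered compartment taxonomy.
#' @param n_fractions fractions per map (TMT channels).
#' @param n_replicates replicate maps per condition.
#' @param marker_fraction proportion of proteins designated organelle
#'   markers (in (0,1)).
#' @param profile_concentration Dirichlet concentration placed on each
#'   compartment's dominant fraction; larger values give sharper, better
#'   separated mean profiles.
#' @param noise_sd per-channel multiplicative log-normal sigma (natural
#'   log scale) of reporter-ion noise.
#' @param organelle_shift_sd log-scale magnitude of the systematic
#'   between-condition shift applied to compartment mean profiles.
#' @param translocations data frame with columns `protein`, `from`, `to`;
#'   `protein` may be `NA` to let the generator pick an unused non-marker
#'   protein resident in `from`.
#' @param abundance_mu,abundance_sigma log-normal parameters (natural
#'   log) of protein copies per cell.
#' @param histone_count number of histone-flagged proteins (chromatin
#'   residents anchoring the proteomic ruler).
#' @param genome_size_bp haploid genome size in base pairs.
#' @param ploidy cell ploidy (dimensionless).
#' @param missing_rate_slope,missing_rate_intercept parameters of the
#'   abundance-dependent left-censoring of lysate LFQ values; the
#'   missingness probability is
#'   `clamp(intercept + slope * (q25 - log2_intensity), 0, 1)`.
#' @param seed master integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 3000,
                              compartments = default_taxonomy(),
                              n_fractions = 10,
                              n_replicates = 3,
                              marker_fraction = 0.24,
                              profile_concentration = 400,
                              noise_sd = 0.1,
                              organelle_shift_sd = 0.15,
                              translocations = NULL,
                              abundance_mu = log(2e4),
                              abundance_sigma = 1.8,
                              histone_count = 8,
                              genome_size_bp = 2.72e9,
                              ploidy = 2,
                              missing_rate_slope = 0.3,
                              missing_rate_intercept = 0,
                              seed = 1) {
  stopifnot(n_fractions >= 2, n_proteins > 0, n_replicates > 0,
            histone_count >= 1, genome_size_bp > 0, ploidy > 0,
            length(compartments) >= 2, !anyDuplicated(compartments))
  if (marker_fraction <= 0 || marker_fraction >= 1)
    stop("marker_fraction must be in (0, 1)")
  if (!is.null(translocations)) {
    translocations <- as.data.frame(translocations)
    if (!all(c("from", "to") %in% names(translocations)))
      stop("translocations needs columns 'from' and 'to'")
    if (is.null(translocations$protein))
      translocations$protein <- NA_character_
    bad <- setdiff(c(translocations$from, translocations$to), compartments)
    if (length(bad))
      stop("translocation names unknown compartment(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    compartments = compartments,
    n_fractions = as.integer(n_fractions),
    n_replicates = as.integer(n_replicates),
    marker_fraction = marker_fraction,
    profile_concentration = profile_concentration,
    noise_sd = noise_sd,
    organelle_shift_sd = organelle_shift_sd,
    translocations = translocations,
    abundance_mu = abundance_mu,
    abundance_sigma = abundance_sigma,
    histone_count = as.integer(histone_count),
    genome_size_bp = genome_size_bp,
    ploidy = ploidy,
    missing_rate_slope = missing_rate_slope,
    missing_rate_intercept = missing_rate_intercept,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Dominant-fraction center per compartment, placed along the pelleting
# order (unknown compartment names are appended in taxonomy order).
.profile_peaks <- function(compartments, n_fractions) {
  rank <- match(compartments, .pellet_order)
  ord <- order(rank, seq_along(compartments), na.last = TRUE)
  peaks <- numeric(length(compartments))
  peaks[ord] <- seq(1, n_fractions, length.out = length(compartments))
  names(peaks) <- compartments
  peaks
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate the simulation ground truth
#'
#' Assigns each protein a compartment per condition, copy numbers,
#' molecular weight and peptide count; designates markers covering every
#' compartment with at least `max(8, n_fractions + 2)` members (so
#' downstream covariance estimation stays feasible); flags histones,
#' whose summed mass is anchored to the DNA mass
#' `genome_size_bp * ploidy * 615.8771 g/mol` so the proteomic ruler is
#' exactly recoverable at zero noise; and draws the per-condition
#' compartment mean profiles (Dirichlet with one dominant fraction,
#' condition B's means log-normally shifted from condition A's).
#'
#' @param config a [simulation_config()].
#' @return a `ground_truth` list with elements `proteins` (data frame),
#'   `profiles` (list of compartment-by-fraction mean profile matrices
#'   for conditions `A` and `B`) and `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, "truth"), {
    n <- config$n_proteins
    K <- length(config$compartments)
    Fn <- config$n_fractions
    acc <- sprintf("SIM%05d", seq_len(n))
    comp_a <- sample(config$compartments, n, replace = TRUE)

    # histones live in the chromatin compartment (or the first nuclear
    # compartment available, else the first taxonomy class)
    chrom <- intersect(c("nucleus_chromatin", "nucleus"),
                       config$compartments)
    chrom <- if (length(chrom)) chrom[1] else config$compartments[1]
    if (config$histone_count > n)
      stop("histone_count exceeds n_proteins")
    is_histone <- seq_len(n) <= config$histone_count
    comp_a[is_histone] <- chrom
    comp_b <- comp_a

    # resolve translocations before marker designation
    trans <- config$translocations
    trans_idx <- integer(0)
    if (!is.null(trans) && nrow(trans)) {
      if (is.null(trans$protein)) trans$protein <- NA_character_
      for (i in seq_len(nrow(trans))) {
        p <- trans$protein[i]
        if (is.na(p)) {
          cand <- which(comp_a == trans$from[i] & !is_histone &
                          !(seq_len(n) %in% trans_idx))
          if (!length(cand))
            stop("no eligible protein left in compartment ", trans$from[i],
                 " for translocation ", i)
          j <- cand[1]
        } else {
          j <- match(p, acc)
          if (is.na(j)) stop("unknown translocator accession: ", p)
          if (is_histone[j])
            stop("histone proteins cannot be translocators: ", p)
        }
        comp_a[j] <- trans$from[i]
        comp_b[j] <- trans$to[i]
        trans_idx <- c(trans_idx, j)
      }
    }

    # marker designation: translocators are excluded (markers are fixed
    # single-residence training anchors)
    n_mark <- round(config$marker_fraction * n)
    need <- max(8, Fn + 2)
    is_marker <- rep(FALSE, n)
    for (cmp in config$compartments) {
      cand <- which(comp_a == cmp & !(seq_len(n) %in% trans_idx))
      if (length(cand) < need)
        stop("compartment ", cmp, " has only ", length(cand),
             " eligible proteins; needs >= ", need, " markers")
      is_marker[cand[seq_len(need)]] <- TRUE
    }
    extra <- n_mark - sum(is_marker)
    if (extra > 0) {
      pool <- which(!is_marker & !(seq_len(n) %in% trans_idx))
      is_marker[sample(pool, min(extra, length(pool)))] <- TRUE
    }

    mw <- stats::rlnorm(n, log(45000), 0.4)
    mw[is_histone] <- pmax(8000, stats::rnorm(sum(is_histone), 14000, 400))
    copies <- stats::rlnorm(n, config$abundance_mu, config$abundance_sigma)
    # anchor: summed histone mass (copies * MW, in g/mol units) equals
    # DNA mass * Avogadro = genome_size * ploidy * mean bp molar mass
    dna_anchor <- config$genome_size_bp * config$ploidy * 615.8771
    h <- which(is_histone)
    copies[h] <- copies[h] * dna_anchor / sum(copies[h] * mw[h])
    peptides <- pmax(1L, stats::rpois(n, mw / 4000))

    # compartment mean profiles
    peaks <- .profile_peaks(config$compartments, Fn)
    prof_a <- matrix(0, K, Fn,
                     dimnames = list(config$compartments, NULL))
    for (k in seq_len(K)) {
      alpha <- 0.5 + config$profile_concentration *
        exp(-(seq_len(Fn) - peaks[k])^2 / (2 * 0.75^2))
      prof_a[k, ] <- .rdirichlet1(alpha)
    }
    prof_b <- prof_a
    if (config$organelle_shift_sd > 0) {
      for (k in seq_len(K)) {
        shift <- exp(stats::rnorm(Fn, 0, config$organelle_shift_sd))
        v <- prof_a[k, ] * shift
        prof_b[k, ] <- v / sum(v)
      }
    }

    structure(list(
      proteins = data.frame(
        accession = acc,
        compartment_A = comp_a,
        compartment_B = comp_b,
        copies_A = copies,
        copies_B = copies,
        mw = mw,
        peptides = peptides,
        is_histone = is_histone,
        is_marker = is_marker,
        stringsAsFactors = FALSE
      ),
      profiles = list(A = prof_a, B = prof_b),
      config = config
    ), class = "ground_truth")
  })
}

.truth_col <- function(truth, what, condition) {
  condition <- match.arg(condition, c("A", "B"))
  truth$proteins[[paste0(what, "_", condition)]]
}

#' Simulate one raw replicate map
#'
#' Each protein's row is `copies * (MW/1000) * compartment mean profile
#' (condition-specific) * per-channel log-normal noise`: reporter-ion
#' intensity is proportional to protein mass in a fraction, and noise is
#' intensity-proportional. Seeded per (condition, replicate).
#'
#' @param truth a [generate_truth()] result.
#' @param condition `"A"` or `"B"`.
#' @param replicate replicate index.
#' @return strictly positive proteins-by-fractions intensity matrix.
#' @export
simulate_replicate_map <- function(truth, condition, replicate) {
  stopifnot(inherits(truth, "ground_truth"))
  condition <- match.arg(condition, c("A", "B"))
  cfg <- truth$config
  pr <- truth$proteins
  prof <- truth$profiles[[condition]]
  comp <- .truth_col(truth, "compartment", condition)
  copies <- .truth_col(truth, "copies", condition)
  base <- copies * (pr$mw / 1000)
  with_seed(derive_seed(cfg$seed, paste("map", condition, replicate)), {
    noise <- matrix(exp(stats::rnorm(nrow(pr) * cfg$n_fractions,
                                     0, cfg$noise_sd)),
                    nrow(pr), cfg$n_fractions)
    raw <- base * prof[comp, , drop = FALSE] * noise
    dimnames(raw) <- list(pr$accession,
                          paste0("F", seq_len(cfg$n_fractions)))
    raw
  })
}

#' Simulate whole-cell lysate LFQ replicates for one condition
#'
#' Log2 intensity is `log2(copies * MW)` plus noise whose standard
#' deviation scales as `1/sqrt(peptide count)` (fewer quantified peptides
#' give noisier protein quantification). Low-abundance values are
#' left-censored: the probability that a value is missing is
#' `clamp(intercept + slope * (q25 - log2_intensity), 0, 1)` with `q25`
#' the noiseless 25% intensity quantile.
#'
#' @inheritParams simulate_replicate_map
#' @param n_replicates lysate replicates (default from config).
#' @return list with `log2` (matrix with `NA` for missing values),
#'   `peptides`, `condition`.
#' @export
simulate_lysate <- function(truth, condition,
                            n_replicates = truth$config$n_replicates) {
  stopifnot(inherits(truth, "ground_truth"))
  condition <- match.arg(condition, c("A", "B"))
  cfg <- truth$config
  pr <- truth$proteins
  copies <- .truth_col(truth, "copies", condition)
  clean <- log2(copies * pr$mw)
  sd_i <- (cfg$noise_sd / log(2)) / sqrt(pr$peptides)
  with_seed(derive_seed(cfg$seed, paste("lysate", condition)), {
    m <- matrix(clean, nrow(pr), n_replicates) +
      matrix(stats::rnorm(nrow(pr) * n_replicates, 0, sd_i),
             nrow(pr), n_replicates)
    q25 <- stats::quantile(clean, 0.25)
    p_miss <- pmin(1, pmax(0, cfg$missing_rate_intercept +
                             cfg$missing_rate_slope * (q25 - m)))
    m[stats::runif(length(m)) < p_miss] <- NA
    dimnames(m) <- list(pr$accession,
                        paste0(condition, "_L", seq_len(n_replicates)))
    list(log2 = m, peptides = stats::setNames(pr$peptides, pr$accession),
         condition = condition)
  })
}

#' Simulate a complete two-condition experiment
#'
#' Bundles ground truth, raw replicate maps, per-fraction protein yields
#' (column mass totals, the quantity a BCA assay of each pellet would
#' report), whole-cell lysates and the marker set.
#'
#' @param config a [simulation_config()].
#' @return list with `truth`, `maps` (`$A`/`$B`: lists of raw matrices),
#'   `yields` (`$A`/`$B`: replicate-by-fraction matrices, micrograms),
#'   `lysates` (`$A`/`$B`), and `markers` (a [marker_set()]).
#' @export
simulate_experiment <- function(config) {
  truth <- generate_truth(config)
  conds <- c("A", "B")
  maps <- yields <- lysates <- list()
  for (cond in conds) {
    maps[[cond]] <- lapply(seq_len(config$n_replicates), function(r)
      simulate_replicate_map(truth, cond, r))
    yields[[cond]] <- do.call(rbind, lapply(maps[[cond]], function(m) {
      cs <- colSums(m)
      cs / sum(cs) * 1500  # ~1.5 mg recovered per replicate
    }))
    lysates[[cond]] <- simulate_lysate(truth, cond)
  }
  pr <- truth$proteins
  mk <- marker_set(stats::setNames(pr$compartment_A[pr$is_marker],
                                   pr$accession[pr$is_marker]),
                   taxonomy = config$compartments)
  list(truth = truth, maps = maps, yields = yields, lysates = lysates,
       markers = mk)
}

#' Write a ground truth table to TSV
#' @param truth a `ground_truth` object.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$proteins, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
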