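# Config-driven orchestration of the full two-condition workflow:
# simulate (or ingest) -> preprocess -> classify -> concordance -> DL
# detection -> proteomic ruler -> DE. Every stage's table is written as
# TSV into the run directory together with a plain-text summary report.

#' Pipeline configuration
#'
#' @param simulation a [simulation_config()] (simulate mode), or `NULL`
#'   for ingest mode.
#' @param paths ingest-mode file paths: list with `maps` (per condition,
#'   character vector of proteinGroups TSVs, one per replicate),
#'   `markers`, `lysates` (per condition), `yields` (per condition,
#'   replicate x fraction TSV).
#' @param svm_threshold classification threshold on the SVM score.
#' @param dl_alpha,de_alpha,enrich_alpha BH false-discovery levels.
#' @param grid an [svm_grid()] used when `cost`/`sigma` are NULL.
#' @param cost,sigma fixed SVM hyperparameters (skip tuning when given).
#' @param ruler list with per-condition [ruler_config()]s (`A`, `B`) —
#'   plus, in ingest mode, `histone_accessions` — or NULL to use the
#'   simulation's genome size, ploidy and histone truth.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            paths = NULL,
                            svm_threshold = 0.7,
                            dl_alpha = 0.05, de_alpha = 0.05,
                            enrich_alpha = 0.02,
                            grid = svm_grid(),
                            cost = NULL, sigma = NULL,
                            ruler = NULL, seed = 1) {
  for (v in c(svm_threshold, dl_alpha, de_alpha, enrich_alpha))
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0, 1)")
  if (is.null(simulation)) {
    if (is.null(paths)) stop("give either a simulation block or paths")
    need <- c("maps", "markers", "lysates", "yields")
    miss <- setdiff(need, names(paths))
    if (length(miss)) stop("paths block missing: ",
                           paste(miss, collapse = ", "))
    files <- c(unlist(paths$maps), paths$markers, unlist(paths$lysates),
               unlist(paths$yields))
    absent <- files[!file.exists(files)]
    if (length(absent)) stop("input file(s) not found: ",
                             paste(absent, collapse = ", "))
  }
  structure(list(simulation = simulation, paths = paths,
                 svm_threshold = svm_threshold, dl_alpha = dl_alpha,
                 de_alpha = de_alpha, enrich_alpha = enrich_alpha,
                 grid = grid, cost = cost, sigma = sigma, ruler = ruler,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

# single-replicate and combined profile maps for one condition's raw maps
.preprocess_condition <- function(raw_maps) {
  complete_each <- lapply(raw_maps, require_complete_reporters)
  singles <- lapply(complete_each, normalize_profiles)
  # combined map: complete series over all replicates (30 channels)
  common <- Reduce(intersect, lapply(raw_maps, rownames))
  stacked <- do.call(cbind, lapply(raw_maps, function(m)
    m[common, , drop = FALSE]))
  stacked <- require_complete_reporters(stacked)
  keep <- rownames(stacked)
  combined <- combine_replicates(lapply(singles, function(s)
    profile_matrix(s$intensities[intersect(rownames(s$intensities), keep), ,
                                 drop = FALSE], normalized = TRUE)))
  list(singles = singles, combined = combined,
       n_quantified = nrow(stacked))
}

#' Run the full two-condition pipeline
#'
#' Executes every stage on simulated (or ingested) data and writes the
#' stage tables plus a summary report into `out_dir`. Deterministic
#' given the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with all stage results (`classified`,
#'   `concordance`, `dl`, `ruler`, `de`, `report`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    report <<- c(report, line)
    line
  }
  conds <- c("A", "B")

  ## ---- inputs -------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- simulate_experiment(config$simulation)
    raw <- sim$maps
    yields <- sim$yields
    lysates <- sim$lysates
    markers <- sim$markers
    mw <- stats::setNames(sim$truth$proteins$mw,
                          sim$truth$proteins$accession)
    histones <- sim$truth$proteins$accession[sim$truth$proteins$is_histone]
    write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.tsv"))
  } else {
    p <- config$paths
    mw <- numeric(0)
    raw <- lapply(p$maps, function(files) lapply(files, function(f) {
      pg <- filter_identifications(read_protein_groups(f, "tmt"))
      mw <<- c(mw, stats::setNames(pg$mol_weight, pg$accession)[
        setdiff(pg$accession, names(mw))])
      pg$intensities
    }))
    names(raw) <- conds
    markers <- load_markers(p$markers)
    yields <- lapply(p$yields, function(f)
      as.matrix(utils::read.delim(f, header = FALSE)))
    lysates <- lapply(conds, function(cond) {
      pg <- filter_identifications(read_protein_groups(
        p$lysates[[cond]], "lfq"))
      li <- pg$intensities
      li[li <= 0] <- NA
      list(log2 = log2(li),
           peptides = stats::setNames(pg$peptides, pg$accession))
    })
    names(lysates) <- conds
    histones <- config$ruler$histone_accessions %||% character(0)
    if (!is.null(config$ruler) && !length(histones))
      stop("ingest mode with a ruler block needs ruler$histone_accessions")
  }

  ## ---- preprocess + classify ---------------------------------------
  pre <- lapply(raw, .preprocess_condition)
  if (is.null(config$cost)) {
    tuned <- tune_svm(pre$A$combined, markers, grid = config$grid,
                      seed = derive_seed(config$seed, "tune"))
    cost <- tuned$cost
    sigma <- tuned$sigma
    note("SVM tuning: cost=%g sigma=%g (inner macro F1 %.3f)",
         cost, sigma, max(tuned$grid_scores$macro_f1))
  } else {
    cost <- config$cost
    sigma <- config$sigma
  }
  classified <- singles_cls <- list()
  for (cond in conds) {
    classified[[cond]] <- classify_map(
      pre[[cond]]$combined, markers, cost, sigma,
      threshold = config$svm_threshold,
      seed = derive_seed(config$seed, paste("classify", cond)))
    singles_cls[[cond]] <- lapply(seq_along(pre[[cond]]$singles),
      function(r) classify_map(pre[[cond]]$singles[[r]], markers, cost,
                               sigma, threshold = config$svm_threshold,
                               seed = derive_seed(config$seed,
                                                  paste("classify", cond, r))))
    a <- classified[[cond]]$assignments
    cv <- cv_macro_f1(pre[[cond]]$combined, markers, cost, sigma,
                      seed = derive_seed(config$seed, paste("cv", cond)))
    note("condition %s: %d combined-map proteins, %d classified (%.0f%%), CV macro F1 %.3f",
         cond, nrow(a), sum(!a$marker & a$compartment != "unknown"),
         100 * mean(a$compartment[!a$marker] != "unknown"), cv)
    .write_tsv(a, out_dir, paste0("classified_", cond))
  }

  ## ---- concordance --------------------------------------------------
  concord <- list()
  for (cond in conds) {
    prs <- utils::combn(length(singles_cls[[cond]]), 2)
    tabs <- lapply(seq_len(ncol(prs)), function(j) {
      s <- stratified_concordance(singles_cls[[cond]][[prs[1, j]]],
                                  singles_cls[[cond]][[prs[2, j]]])
      s$pair <- paste0(prs[1, j], "-", prs[2, j])
      s
    })
    concord[[cond]] <- do.call(rbind, tabs)
    .write_tsv(concord[[cond]], out_dir, paste0("concordance_", cond))
    overall <- mean(vapply(seq_len(ncol(prs)), function(j)
      pairwise_concordance(singles_cls[[cond]][[prs[1, j]]],
                           singles_cls[[cond]][[prs[2, j]]]), 1.0))
    note("condition %s: mean pairwise concordance %.3f", cond, overall)
  }

  ## ---- differential localization -----------------------------------
  dl <- detect_dl(pre$A$singles, pre$B$singles,
                  classified$A, classified$B, alpha = config$dl_alpha)
  .write_tsv(dl$table, out_dir, "dl_proteins")
  note("DL proteins: %d total (%d qualitative, %d quantitative)",
       nrow(dl$table), nrow(dl$qualitative),
       sum(dl$quantitative$is_DL))

  ## ---- proteomic ruler ---------------------------------------------
  ruler_res <- NULL
  if (!is.null(config$simulation) || !is.null(config$ruler)) {
    rcfgs <- config$ruler %||% {
      sc <- config$simulation
      rc <- ruler_config(sc$genome_size_bp, ploidy = sc$ploidy)
      list(A = rc, B = rc)
    }
    ruler_res <- list()
    for (cond in conds) {
      wt <- weight_tmt_fractions(raw[[cond]], yields[[cond]])
      acc <- rownames(wt$summed)
      cp <- copies_per_cell(stats::setNames(rowMeans(wt$summed), acc),
                            mw[acc], acc %in% histones, rcfgs[[cond]])
      lab_df <- classified[[cond]]$assignments
      labels <- stats::setNames(
        ifelse(acc %in% lab_df$accession,
               lab_df$compartment[match(acc, lab_df$accession)], "unknown"),
        acc)
      om_reps <- lapply(seq_len(dim(wt$shares_by_replicate)[3]),
        function(r) {
          cp_r <- copies_per_cell(
            stats::setNames(wt$summed[, r], acc), mw[acc],
            acc %in% histones, rcfgs[[cond]])
          om <- organelle_masses(cp_r, labels,
                                 wt$shares_by_replicate[, , r])
          stats::setNames(om$mass_fraction, om$compartment)
        })
      om_mat <- do.call(rbind, om_reps)
      om <- data.frame(compartment = colnames(om_mat),
                       mass_fraction = colMeans(om_mat),
                       sd = apply(om_mat, 2, stats::sd), row.names = NULL)
      # lysate-derived copies for the cross-method check
      ly <- lysates[[cond]]
      obs <- rowSums(!is.na(ly$log2)) == ncol(ly$log2)
      li <- impute_lysate(ly$log2[obs, , drop = FALSE],
                          seed = derive_seed(config$seed,
                                             paste("impute", cond)))
      lys_cp <- copies_per_cell(
        stats::setNames(rowMeans(2^li), rownames(li)),
        mw[rownames(li)], rownames(li) %in% histones, rcfgs[[cond]])
      agr <- cross_method_agreement(
        stats::setNames(lys_cp$copies_per_cell, lys_cp$accession),
        stats::setNames(cp$copies_per_cell, cp$accession))
      ruler_res[[cond]] <- list(copies = cp, organelle_masses = om,
                                organelle_masses_by_replicate = om_mat,
                                lysate_copies = lys_cp, agreement = agr)
      .write_tsv(cp, out_dir, paste0("copies_", cond))
      .write_tsv(om, out_dir, paste0("organelle_mass_", cond))
      note("condition %s: lysate/fraction copy agreement r=%.2f slope=%.2f (n=%d)",
           cond, agr$r, agr$slope, agr$n)
    }
  }

  ## ---- differential expression -------------------------------------
  de <- NULL
  if (!is.null(lysates$A$peptides)) {
    keep <- lapply(conds, function(cond) {
      m <- lysates[[cond]]$log2
      rownames(m)[rowSums(!is.na(m)) == ncol(m)]
    })
    common <- intersect(keep[[1]], keep[[2]])
    if (length(common) >= 3) {
      mat <- cbind(lysates$A$log2[common, , drop = FALSE],
                   lysates$B$log2[common, , drop = FALSE])
      grp <- rep(conds, c(ncol(lysates$A$log2), ncol(lysates$B$log2)))
      de <- moderated_de(mat, grp, lysates$A$peptides[common],
                         alpha = config$de_alpha)
      .write_tsv(de, out_dir, "de_proteins")
      note("DE: %d of %d proteins significant at BH-FDR %.2f",
           sum(de$significant), nrow(de), config$de_alpha)
    }
  }

  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(classified = classified, singles = singles_cls,
                 concordance = concord, dl = dl, ruler = ruler_res,
                 de = de, report = report,
                 hyperparameters = c(cost = cost, sigma = sigma)))
}
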