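#!/usr/bin/env Rscript
# Proteomic ruler: copy numbers per cell from yield-weighted TMT
# fractions anchored on the histones, agreement with lysate-derived
# copies, relative organelle protein masses per replicate with a
# between-line comparison, and top mass contributors per organelle.

source(file.path("analysis", "00_common.R"))

exp_ <- benchmark_experiment()
cfg <- exp_$truth$config
tr <- exp_$truth$proteins
rc <- ruler_config(cfg$genome_size_bp, ploidy = cfg$ploidy)

om_reps <- list()
for (cond in c("A", "B")) {
  wt <- weight_tmt_fractions(exp_$maps[[cond]], exp_$yields[[cond]])
  acc <- rownames(wt$summed)
  cp <- copies_per_cell(stats::setNames(rowMeans(wt$summed), acc),
                        tr$mw, tr$is_histone, rc)
  err <- abs(log2(cp$copies_per_cell /
                    tr[[paste0("copies_", cond)]]))
  message(sprintf("condition %s: median |log2 est/true copies| = %.3f",
                  cond, median(err)))
  write_tsv(cp, paste0("copies_", cond))

  cm <- classify_map(combine_replicates(lapply(exp_$maps[[cond]],
                                               normalize_profiles)),
                     exp_$markers, 48, 1,
                     seed = derive_seed(SEED, paste("ruler", cond)))
  labels <- stats::setNames(cm$assignments$compartment,
                            cm$assignments$accession)
  om <- do.call(rbind, lapply(1:cfg$n_replicates, function(r) {
    cp_r <- copies_per_cell(stats::setNames(wt$summed[, r], acc),
                            tr$mw, tr$is_histone, rc)
    o <- organelle_masses(cp_r, labels, wt$shares_by_replicate[, , r])
    o$replicate <- r
    o
  }))
  om_reps[[cond]] <- om
  write_tsv(om, paste0("organelle_mass_", cond))

  top <- top_contributors(cp, labels, "ER", k = 10)
  write_tsv(top, paste0("top_ER_contributors_", cond))

  # lysate route for the cross-method check
  ly <- exp_$lysates[[cond]]
  obs <- rowSums(!is.na(ly$log2)) == ncol(ly$log2)
  li <- impute_lysate(ly$log2[obs, , drop = FALSE],
                      seed = derive_seed(SEED, paste("imp", cond)))
  lys <- copies_per_cell(stats::setNames(rowMeans(2^li), rownames(li)),
                         tr$mw[match(rownames(li), tr$accession)],
                         tr$is_histone[match(rownames(li), tr$accession)],
                         rc)
  agr <- cross_method_agreement(
    stats::setNames(lys$copies_per_cell, lys$accession),
    stats::setNames(cp$copies_per_cell, cp$accession))
  message(sprintf("condition %s: lysate vs fraction copies r = %.2f, slope = %.2f (n = %d)",
                  cond, agr$r, agr$slope, agr$n))
}

# per-compartment between-line comparison over replicates
comps <- intersect(unique(om_reps$A$compartment),
                   unique(om_reps$B$compartment))
cmp_tab <- do.call(rbind, lapply(comps, function(cmp) {
  a <- om_reps$A$mass_fraction[om_reps$A$compartment == cmp]
  b <- om_reps$B$mass_fraction[om_reps$B$compartment == cmp]
  data.frame(compartment = cmp, mean_A = mean(a), mean_B = mean(b),
             p = tryCatch(t.test(a, b)$p.value, error = function(e) NA))
}))
write_tsv(cmp_tab, "organelle_mass_comparison")
message("organelle mass comparison written (t-test over replicates)")
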