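#!/usr/bin/env Rscript
# Generate the benchmark experiment and export its raw artifacts in the
# proteinGroups-like exchange format: one TMT table per replicate map,
# one LFQ lysate table per cell line, the marker set, and the ground
# truth the later stages are scored against.

source(file.path("analysis", "00_common.R"))

exp_ <- benchmark_experiment()
tr <- exp_$truth$proteins
message(sprintf("simulated %d proteins (%d markers, %d histones, %d translocators)",
                nrow(tr), sum(tr$is_marker), sum(tr$is_histone),
                sum(tr$compartment_A != tr$compartment_B)))

data_dir <- file.path(RESULTS, "data")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

for (cond in c("A", "B")) {
  for (r in seq_along(exp_$maps[[cond]])) {
    m <- exp_$maps[[cond]][[r]]
    pg <- protein_groups(rownames(m), m, dialect = "tmt",
                         peptides = tr$peptides, mol_weight = tr$mw)
    write_protein_groups(pg, file.path(data_dir,
      sprintf("proteinGroups_%s_rep%d.tsv", cond, r)))
  }
  ly <- exp_$lysates[[cond]]
  li <- 2^ly$log2
  li[is.na(li)] <- 0
  write_protein_groups(
    protein_groups(rownames(li), li, dialect = "lfq",
                   peptides = unname(ly$peptides), mol_weight = tr$mw),
    file.path(data_dir, sprintf("lysate_%s.tsv", cond)))
  utils::write.table(exp_$yields[[cond]],
                     file.path(data_dir, sprintf("yields_%s.tsv", cond)),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}
write_markers(exp_$markers, file.path(data_dir, "markers.tsv"))
write_ground_truth(exp_$truth, file.path(data_dir, "ground_truth.tsv"))
message("raw artifacts in ", data_dir)
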