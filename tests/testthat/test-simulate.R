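# Synthetic-data generator: determinism, ground-truth invariants,
# zero-noise limits, lysate properties, proteinGroups round-trips.

test_that("ground truth is deterministic and satisfies its invariants", {
  cfg <- small_config()
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1, t2)

  pr <- t1$proteins
  expect_equal(nrow(pr), cfg$n_proteins)
  expect_equal(sum(pr$is_histone), cfg$histone_count)
  expect_true(all(pr$mw > 0))
  expect_true(all(pr$peptides >= 1))
  # every compartment covered by >= max(8, n_fractions + 2) markers
  need <- max(8, cfg$n_fractions + 2)
  counts <- table(pr$compartment_A[pr$is_marker])
  expect_true(all(cfg$compartments %in% names(counts)))
  expect_true(all(counts >= need))
  # histones reside in the chromatin compartment and never translocate
  expect_true(all(pr$compartment_A[pr$is_histone] == "nucleus_chromatin"))
  expect_true(all(pr$compartment_A[pr$is_histone] ==
                    pr$compartment_B[pr$is_histone]))
  # histone mass anchors the DNA mass exactly
  h <- pr$is_histone
  expect_equal(sum(pr$copies_A[h] * pr$mw[h]),
               cfg$genome_size_bp * cfg$ploidy * 615.8771)
})

test_that("translocations change the true compartment between conditions", {
  cfg <- small_config(
    translocations = data.frame(from = c("ER", "ER"), to = c("PM", "Golgi")))
  tr <- generate_truth(cfg)
  moved <- tr$proteins[tr$proteins$compartment_A !=
                         tr$proteins$compartment_B, ]
  expect_equal(nrow(moved), 2)
  expect_setequal(moved$compartment_B, c("PM", "Golgi"))
  expect_true(all(moved$compartment_A == "ER"))
  expect_false(any(moved$is_marker))
  # naming a histone explicitly is rejected
  cfg2 <- small_config(
    translocations = data.frame(protein = "SIM00001", from = "ER", to = "PM"))
  expect_error(generate_truth(cfg2), "histone")
  # unknown compartment is rejected at config time
  expect_error(
    simulation_config(translocations = data.frame(from = "ER", to = "vacuole")),
    "vacuole")
})

test_that("zero-noise maps reproduce compartment mean profiles exactly", {
  cfg <- simulation_config(n_proteins = 300, marker_fraction = 0.45,
                           noise_sd = 0, organelle_shift_sd = 0, seed = 3)
  tr <- generate_truth(cfg)
  raw <- simulate_replicate_map(tr, "A", 1)
  expect_true(all(raw > 0))
  expect_false(anyNA(raw))
  prof <- raw / rowSums(raw)
  expected <- tr$profiles$A[tr$proteins$compartment_A, ]
  expect_equal(unname(prof), unname(expected), tolerance = 1e-12)
  # two proteins of one compartment share one normalized profile
  er <- which(tr$proteins$compartment_A == "ER")[1:2]
  expect_equal(prof[er[1], ], prof[er[2], ])
  # shift off: conditions share compartment means
  expect_equal(tr$profiles$A, tr$profiles$B)
})

test_that("between-condition organelle shifts move compartment means", {
  cfg <- small_config()  # organelle_shift_sd default > 0
  tr <- generate_truth(cfg)
  # compare condition means over many simulated proteins per compartment
  rawA <- simulate_replicate_map(tr, "A", 1)
  rawB <- simulate_replicate_map(tr, "B", 1)
  pa <- rawA / rowSums(rawA)
  pb <- rawB / rowSums(rawB)
  shifts <- vapply(cfg$compartments, function(cmp) {
    ix <- tr$proteins$compartment_A == cmp &
      tr$proteins$compartment_B == cmp
    sum(abs(colMeans(pa[ix, , drop = FALSE]) -
              colMeans(pb[ix, , drop = FALSE])))
  }, 1.0)
  expect_true(all(shifts > 1e-3))
  # and the empirical condition means track the configured truth
  expect_gt(max(abs(tr$profiles$A - tr$profiles$B)), 0.005)
})

test_that("replicate maps are seeded per condition and replicate", {
  tr <- generate_truth(small_config())
  expect_identical(simulate_replicate_map(tr, "A", 1),
                   simulate_replicate_map(tr, "A", 1))
  expect_false(identical(simulate_replicate_map(tr, "A", 1),
                         simulate_replicate_map(tr, "A", 2)))
  expect_false(identical(simulate_replicate_map(tr, "A", 1),
                         simulate_replicate_map(tr, "B", 1)))
})

test_that("lysate simulation reflects abundance, censoring and histone mass", {
  # no censoring when both missingness parameters are zero
  cfg0 <- small_config(missing_rate_slope = 0, missing_rate_intercept = 0)
  ly0 <- simulate_lysate(generate_truth(cfg0), "A")
  expect_false(anyNA(ly0$log2))

  cfg <- small_config(noise_sd = 0.1)
  tr <- generate_truth(cfg)
  ly <- simulate_lysate(tr, "A")
  expect_true(anyNA(ly$log2))
  # missingness hits low-abundance proteins: mean abundance of missing
  # cells below that of observed cells
  clean <- log2(tr$proteins$copies_A * tr$proteins$mw)
  miss_rate <- rowMeans(is.na(ly$log2))
  expect_lt(mean(clean[miss_rate > 0]), mean(clean[miss_rate == 0]))
  # rank correlation between truth and simulated intensity
  obs <- rowSums(!is.na(ly$log2)) == ncol(ly$log2)
  expect_gt(cor(clean[obs], rowMeans(ly$log2[obs, ]),
                method = "spearman"), 0.9)
  # histone share of summed linear intensity ~ histone mass share
  li <- 2^ly$log2
  li[is.na(li)] <- 0
  hist_share <- sum(li[tr$proteins$is_histone, ]) / sum(li)
  mass <- tr$proteins$copies_A * tr$proteins$mw
  expect_equal(hist_share, sum(mass[tr$proteins$is_histone]) / sum(mass),
               tolerance = 0.05)
})

test_that("proteinGroups files round-trip and carry the flag convention", {
  tr <- generate_truth(small_config())
  raw <- simulate_replicate_map(tr, "A", 1)
  pg <- protein_groups(rownames(raw), raw, dialect = "tmt",
                       peptides = tr$proteins$peptides,
                       mol_weight = tr$proteins$mw,
                       reverse = c(TRUE, rep(FALSE, nrow(raw) - 1)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_groups(pg, path)
  back <- read_protein_groups(path, "tmt")
  expect_equal(unname(back$intensities), unname(pg$intensities))
  expect_identical(back$accession, pg$accession)
  expect_identical(back$reverse, pg$reverse)
  # the flagged row is removed by the standard identification filter
  filtered <- filter_identifications(back)
  expect_equal(length(filtered$accession), length(pg$accession) - 1)
  expect_false(pg$accession[1] %in% filtered$accession)
  # lfq dialect round-trips sample names
  ly <- simulate_lysate(tr, "A")
  pg2 <- protein_groups(rownames(ly$log2), 2^ly$log2, dialect = "lfq",
                        peptides = unname(ly$peptides))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_protein_groups(pg2, path2)
  back2 <- read_protein_groups(path2, "lfq")
  expect_identical(colnames(back2$intensities), colnames(pg2$intensities))
})
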