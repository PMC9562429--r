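# Proteomic ruler: ploidy, fraction weighting, copy numbers, organelle
# masses, cross-method agreement.

test_that("ploidy derives from the genome-size ratio", {
  expect_equal(derive_ploidy(2.399e9, 2.72e9), 1.76)
  expect_equal(derive_ploidy(1e9, 1e9), 2)
  expect_equal(derive_ploidy(5e8, 1e9), 1)
  expect_error(derive_ploidy(-1, 1e9), "positive")
})

test_that("fraction weighting normalizes channels and forms group shares", {
  yields <- matrix(1, 1, 10)
  # a protein present only in fraction 1 has share vector (1, 0, 0)
  m1 <- rbind(P1 = c(5, rep(1e-12, 9)),
              P2 = rep(1, 10), P3 = rep(1, 10))
  wt1 <- weight_tmt_fractions(list(m1), yields)
  expect_equal(unname(wt1$shares["P1", ]), c(1, 0, 0), tolerance = 1e-9)
  # uniform protein, equal yields: shares (0.1, 0.8, 0.1)
  m2 <- matrix(1, 3, 10, dimnames = list(paste0("P", 1:3), NULL))
  wt2 <- weight_tmt_fractions(list(m2), yields)
  expect_equal(unname(wt2$shares["P2", ]), c(0.1, 0.8, 0.1),
               tolerance = 1e-9)
  # equal yields: weighted sum proportional to the plain normalized sum
  m3 <- matrix(runif(30, 1, 4), 3, 10,
               dimnames = list(paste0("P", 1:3), NULL))
  wt3 <- weight_tmt_fractions(list(m3), yields)
  expect_equal(wt3$summed[, 1],
               rowSums(sweep(m3, 2, colSums(m3), "/")), tolerance = 1e-9)
  expect_error(weight_tmt_fractions(list(m2 * 0), yields), "zero total")
})

test_that("copy numbers follow the ruler formula and scale invariance", {
  # hand oracle: I = 10, histone total 100, anchor 3.613e12, MW 1e4
  anchor <- 3.613e12
  rc <- ruler_config(genome_size_bp = anchor / 615.8771, ploidy = 1)
  expect_equal(rc$dna_mass_mol, anchor)
  ints <- c(A = 10, H = 100)
  cp <- copies_per_cell(ints, c(1e4, 14000), c(FALSE, TRUE), rc)
  expect_equal(cp$copies_per_cell[1], 0.1 * anchor / 1e4)  # 3.613e7
  expect_equal(cp$copies_per_cell[1], 3.613e7)
  # mass = copies * MW / N_A
  expect_equal(cp$mass_per_cell,
               cp$copies_per_cell * cp$mol_weight / 6.02214076e23)
  # doubling all intensities changes nothing
  cp2 <- copies_per_cell(ints * 2, c(1e4, 14000), c(FALSE, TRUE), rc)
  expect_equal(cp2$copies_per_cell, cp$copies_per_cell)
  expect_error(copies_per_cell(ints, c(1e4, 14000), c(FALSE, FALSE), rc),
               "histone")
})

test_that("copy numbers recover the simulated ground truth", {
  exp_ <- small_experiment()
  cfg <- exp_$truth$config
  tr <- exp_$truth$proteins
  rc <- ruler_config(cfg$genome_size_bp, ploidy = cfg$ploidy)
  wt <- weight_tmt_fractions(exp_$maps$A, exp_$yields$A)
  cp <- copies_per_cell(
    stats::setNames(rowMeans(wt$summed), rownames(wt$summed)),
    tr$mw, tr$is_histone, rc)
  err <- abs(log2(cp$copies_per_cell / tr$copies_A))
  expect_lte(median(err), 0.15)
})

test_that("organelle masses weight by group share and close to one", {
  acc <- c("P1", "P2", "P3")
  cp <- data.frame(accession = acc, intensity = 1,
                   mol_weight = c(1e4, 2e4, 3e4),
                   copies_per_cell = c(1e6, 2e6, 3e6),
                   mass_per_cell = c(1, 2, 3) * 1e-14)
  shares <- matrix(c(0, 1, 0,   0, 1, 0,   0.2, 0.3, 0.5), 3, 3,
                   byrow = TRUE,
                   dimnames = list(acc, c("nucleus", "organelle",
                                          "cytosol")))
  labels <- c(P1 = "ER", P2 = "unknown", P3 = "cytosol")
  om <- organelle_masses(cp, labels, shares)
  total <- sum(cp$mass_per_cell)
  expect_equal(om$mass_fraction[om$compartment == "ER"],
               1e-14 * 1 / total)
  expect_equal(om$mass_fraction[om$compartment == "cytosol"],
               3e-14 * 0.5 / total)
  expect_equal(sum(om$mass_fraction), 1, tolerance = 1e-9)
  # all unknown -> everything pools as unassigned
  om2 <- organelle_masses(cp, c(P1 = "unknown", P2 = "unknown",
                                P3 = "unknown"), shares)
  expect_equal(om2$mass_fraction[om2$compartment == "unassigned"], 1)
  expect_error(organelle_masses(cp, labels[1:2], shares), "label")
})

test_that("an inflated ER compartment yields higher ER mass in that condition", {
  cfgA <- small_config()
  simA <- small_experiment()
  trB <- generate_truth(cfgA)
  # inflate ER copies x1.5 (both conditions of this second experiment)
  er <- trB$proteins$compartment_A == "ER"
  trB$proteins$copies_A[er] <- trB$proteins$copies_A[er] * 1.5
  rc <- ruler_config(cfgA$genome_size_bp, ploidy = cfgA$ploidy)
  tr <- simA$truth$proteins
  labels <- stats::setNames(tr$compartment_A, tr$accession)
  er_frac <- function(truth) {
    maps <- lapply(1:3, function(r) simulate_replicate_map(truth, "A", r))
    yields <- do.call(rbind, lapply(maps, colSums))
    wt <- weight_tmt_fractions(maps, yields)
    vapply(1:3, function(r) {
      cp <- copies_per_cell(
        stats::setNames(wt$summed[, r], rownames(wt$summed)),
        truth$proteins$mw, truth$proteins$is_histone, rc)
      om <- organelle_masses(cp, labels, wt$shares_by_replicate[, , r])
      om$mass_fraction[om$compartment == "ER"]
    }, 1.0)
  }
  fA <- er_frac(simA$truth)
  fB <- er_frac(trB)
  expect_lt(t.test(fB, fA, alternative = "greater")$p.value, 0.05)
})

test_that("top contributors rank by weighted mass with a short-list warning", {
  cp <- data.frame(accession = paste0("P", 1:3), intensity = 1,
                   mol_weight = 1e4, copies_per_cell = c(1, 5, 2) * 1e6,
                   mass_per_cell = c(1, 5, 2) * 1e-14)
  labels <- stats::setNames(rep("ER", 3), cp$accession)
  expect_warning(out <- top_contributors(cp, labels, "ER", k = 10),
                 "only 3")
  expect_identical(out$accession, c("P2", "P3", "P1"))
  expect_lte(sum(out$mass_share), 1 + 1e-12)
  expect_error(top_contributors(cp, labels, "Golgi"), "no member")
})

test_that("cross-method agreement sees through a constant scale factor", {
  x <- stats::setNames(10^runif(50, 3, 7), paste0("P", 1:50))
  self <- cross_method_agreement(x, x)
  expect_equal(self$r, 1)
  expect_equal(self$slope, 1)
  doubled <- cross_method_agreement(x, 2 * x)
  expect_equal(doubled$r, 1)
  expect_equal(doubled$slope, 1)
  expect_error(cross_method_agreement(x[1:2], x[1:2]), "fewer than 3")
})
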