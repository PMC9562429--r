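# SVM localization prediction: macro F1, tuning, scoring, QSep.

test_that("macro F1 matches hand-computed cases and is permutation-invariant", {
  # perfect diagonal
  d <- diag(c(5, 3, 7))
  dimnames(d) <- list(letters[1:3], letters[1:3])
  expect_equal(macro_f1(d), 1)
  # two classes: [[10,0],[10,0]]: F1 = 2/3 and 0 -> macro 1/3
  m <- matrix(c(10, 10, 0, 0), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_equal(macro_f1(m), 1 / 3)
  # permuting class order leaves the score unchanged
  perm <- c(2, 1)
  expect_equal(macro_f1(m[perm, perm]), macro_f1(m))
  # an empty class (no truths, no predictions) is excluded
  m3 <- rbind(cbind(m, c = c(0, 0)), c = c(0, 0, 0))
  expect_equal(macro_f1(m3), 1 / 3)
  expect_error(macro_f1(matrix(0, 2, 2)), "all-zero")
})

test_that("the default hyperparameter grid spans 105 points", {
  g <- svm_grid()
  expect_length(g$cost, 21)
  expect_length(g$sigma, 5)
  expect_equal(nrow(expand.grid(g$cost, g$sigma)), 105)
  expect_equal(g$cost, seq(20, 60, by = 2))
  expect_equal(g$sigma, c(0.01, 0.1, 1, 10, 100))
})

test_that("grid tuning is seeded, reports CV macro F1 and breaks ties low", {
  comb <- small_combined()$combined
  mk <- small_experiment()$markers
  g <- svm_grid(cost = c(20, 40), sigma = c(0.1, 1), inner_reps = 3)
  t1 <- tune_svm(comb, mk, g, seed = 5)
  t2 <- tune_svm(comb, mk, g, seed = 5)
  expect_identical(t1[c("cost", "sigma")], t2[c("cost", "sigma")])
  expect_equal(nrow(t1$grid_scores), 4)
  expect_true(t1$cv_macro_f1 >= 0 && t1$cv_macro_f1 <= 1)
  # on cleanly separated markers all points tie at F1 1 -> lowest cost,
  # then lowest sigma
  if (max(t1$grid_scores$macro_f1) == 1 &&
      sum(t1$grid_scores$macro_f1 == 1) > 1) {
    best <- t1$grid_scores[t1$grid_scores$macro_f1 == 1, ]
    expect_equal(t1$cost, min(best$cost))
  }
})

test_that("marker self-prediction is perfect on zero-noise data", {
  cfg <- simulation_config(n_proteins = 400, marker_fraction = 0.4,
                           noise_sd = 0, seed = 21)
  sim <- simulate_experiment(cfg)
  comb <- combine_replicates(lapply(sim$maps$A, normalize_profiles))
  expect_equal(cv_macro_f1(comb, sim$markers, cost = 48, sigma = 1,
                           seed = 2), 1)
})

test_that("classification thresholds scores into unknown labels", {
  cm <- small_classified()
  a <- cm$assignments
  truth <- small_experiment()$truth$proteins
  # invariant: non-marker "unknown" iff score < 0.7
  nm <- a[!a$marker, ]
  expect_identical(nm$compartment == "unknown", nm$score < 0.7)
  # markers retain their annotation
  mk <- small_experiment()$markers
  mrk <- a[a$marker, ]
  expect_identical(mrk$compartment, unname(mk$entries[mrk$accession]))
  # classified non-markers match the ground truth on clean data
  cl <- nm[nm$compartment != "unknown", ]
  expect_gt(mean(cl$compartment ==
                   truth$compartment_A[match(cl$accession,
                                             truth$accession)]), 0.99)
  # threshold 0 -> no unknowns; lowering the threshold never adds them
  cm0 <- classify_map(small_combined()$combined, mk, 48, 1,
                      threshold = 0, seed = 7)
  expect_false(any(cm0$assignments$compartment == "unknown"))
  for (th in c(0.9, 0.7, 0.5, 0)) {
    cmt <- classify_map(small_combined()$combined, mk, 48, 1,
                        threshold = th, seed = 7)
    n_unk <- sum(cmt$assignments$compartment == "unknown")
    if (exists("prev_unk")) expect_lte(n_unk, prev_unk)
    prev_unk <- n_unk
  }
})

test_that("scores behave at the extremes: marker-identical vs uniform", {
  exp_ <- small_experiment()
  comb <- small_combined()$combined
  mk <- exp_$markers
  # append a marker-identical profile and a flat profile
  m_acc <- names(mk$entries)[1]
  X <- rbind(comb$intensities,
             CLONE = comb$intensities[m_acc, ],
             FLAT = rep(0.1, ncol(comb$intensities)))
  cm <- classify_map(profile_matrix(X, normalized = TRUE), mk, 48, 1,
                     seed = 7)
  a <- cm$assignments
  clone <- a[a$accession == "CLONE", ]
  expect_identical(clone$compartment, unname(mk$entries[m_acc]))
  expect_gt(clone$score, 0.9)
  flat <- a[a$accession == "FLAT", ]
  expect_identical(flat$compartment, "unknown")
  expect_lt(flat$score, 0.7)
})

test_that("classification is deterministic given markers and parameters", {
  comb <- small_combined()$combined
  mk <- small_experiment()$markers
  c1 <- classify_map(comb, mk, 48, 1, seed = 7)
  c2 <- classify_map(comb, mk, 48, 1, seed = 7)
  expect_identical(c1$assignments, c2$assignments)
})

test_that("combining replicates does not hurt marker cross-validation", {
  cfg <- simulation_config(n_proteins = 500, marker_fraction = 0.3,
                           noise_sd = 0.45, seed = 13)
  sim <- simulate_experiment(cfg)
  pre <- preprocess_maps(sim$maps$A)
  singles_f1 <- vapply(pre$singles, function(s)
    cv_macro_f1(s, sim$markers, 48, 1, seed = 3), 1.0)
  comb_f1 <- cv_macro_f1(pre$combined, sim$markers, 48, 1, seed = 3)
  expect_gte(comb_f1 + 1e-9, max(singles_f1))
})

test_that("QSep normalizes distances to the reference cluster spread", {
  comb <- small_combined()$combined
  mk <- small_experiment()$markers
  q <- qsep(comb, mk)
  expect_equal(unname(diag(q)), rep(1, nrow(q)))
  expect_true(all(q[upper.tri(q)] > 1))  # well-separated synthetic map
  # two point-clusters far apart with tight spread give huge ratios
  x <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
             matrix(rnorm(20, 5, 0.01), 10, 2))
  rownames(x) <- paste0("P", 1:20)
  mk2 <- marker_set(stats::setNames(rep(c("ER", "PM"), each = 10),
                                    rownames(x)))
  q2 <- qsep(x, mk2)
  expect_gt(q2["ER", "PM"], 100)
  # shrinking within-cluster spread at fixed separation raises the ratio
  x3 <- x
  x3[11:20, ] <- 5 + (x[11:20, ] - 5) * 10
  q3 <- qsep(x3, mk2)
  expect_gt(q2["ER", "PM"], q3["ER", "PM"])
  # singleton cluster rejected
  mk3 <- marker_set(stats::setNames(c(rep("ER", 19), "PM"), rownames(x)))
  expect_error(qsep(x, mk3), "singleton")
})
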