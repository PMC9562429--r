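# Differential localization: nucleus merging, Mahalanobis distance
# profiles, closest-compartment logic, the t-test/BH stage, collation.

test_that("nucleus merging relabels both nuclear classes and is idempotent", {
  cm <- small_classified()
  expect_length(cm$taxonomy, 11)
  n_chr <- sum(cm$assignments$compartment == "nucleus_chromatin")
  n_non <- sum(cm$assignments$compartment == "nucleus_nonchromatin")
  merged <- merge_nuclear(cm)
  expect_length(merged$taxonomy, 10)
  expect_false(any(c("nucleus_chromatin", "nucleus_nonchromatin") %in%
                     merged$taxonomy))
  expect_equal(sum(merged$assignments$compartment == "nucleus"),
               n_chr + n_non)
  expect_identical(merge_nuclear(merged)$assignments, merged$assignments)
  # marker sets merge consistently
  mk <- merge_nuclear(small_experiment()$markers)
  expect_length(mk$taxonomy, 10)
  expect_true("nucleus" %in% unique(unname(mk$entries)))
})

test_that("qualitative stage lists reclassified proteins only", {
  mk_map <- function(labels, markers = rep(FALSE, length(labels))) {
    acc <- paste0("P", seq_along(labels))
    structure(list(profiles = matrix(0.1, length(labels), 10,
                                     dimnames = list(acc, NULL)),
                   assignments = data.frame(accession = acc,
                                            compartment = labels,
                                            score = 0.9, marker = markers,
                                            stringsAsFactors = FALSE),
                   taxonomy = default_taxonomy()),
              class = "classified_map")
  }
  a <- mk_map(c("ER", "ER", "unknown", "PM"))
  b <- mk_map(c("PM", "ER", "Golgi", "PM"))
  out <- qualitative_dl(a, b)
  expect_identical(out$accession, "P1")   # unknown-in-one not listed
  expect_identical(out$compartment_B, "PM")
  expect_equal(nrow(qualitative_dl(a, a)), 0)
})

test_that("the simplex projection is isometric", {
  V <- simplex_basis(10)
  expect_equal(crossprod(V), diag(9), tolerance = 1e-12)
  expect_equal(colSums(V), rep(0, 9), tolerance = 1e-12)  # kills 1-vector
  x <- matrix(runif(50), 5, 10)
  x <- x / rowSums(x)
  d_orig <- dist(x)
  d_proj <- dist(x %*% V)
  expect_equal(as.numeric(d_orig), as.numeric(d_proj), tolerance = 1e-12)
})

test_that("distance profiles reduce to hand-computable cases", {
  # 1-D: variance 4, offset 2 -> distance 1
  st <- list(ER = list(center = 0, cov = matrix(4, 1, 1), basis = NULL))
  expect_equal(unname(distance_profile(matrix(2, 1, 1), st)[1, 1]), 1)
  # x = mu -> 0
  expect_equal(unname(distance_profile(matrix(0, 1, 1), st)[1, 1]), 0)
  # identity covariance -> euclidean distance
  mu <- c(1, 2, 3)
  st2 <- list(a = list(center = mu, cov = diag(3), basis = NULL))
  x <- matrix(c(2, 4, 5), 1, 3)
  expect_equal(unname(distance_profile(x, st2)[1, 1]),
               sqrt(sum((x - mu)^2)))
})

test_that("Mahalanobis distances are invariant to affine recoordinatization", {
  set.seed(9)
  x <- matrix(rnorm(600), 50, 12)
  members <- x[1:30, ]
  st <- list(c1 = compartment_stats(members, method = "classical",
                                    project = FALSE))
  d1 <- distance_profile(x, st)
  A <- matrix(rnorm(144), 12, 12)  # generically invertible
  st2 <- list(c1 = compartment_stats(members %*% A, method = "classical",
                                     project = FALSE))
  d2 <- distance_profile(x %*% A, st2)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("compartment stats handle degenerate and contaminated members", {
  # identical members: center = the profile, scatter = ridge floor
  prof <- matrix(rep(c(0.5, 0.3, 0.2), each = 8), 8, 3)
  st <- compartment_stats(prof)
  expect_equal(unname(st$center), unname((prof %*% simplex_basis(3))[1, ]),
               tolerance = 1e-9)
  ev <- eigen(st$cov, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # too few members errors
  expect_error(compartment_stats(matrix(runif(20), 2, 10)), ">=")
  # MCD centers ignore planted outliers (simulation check)
  set.seed(4)
  clean <- matrix(abs(rnorm(45 * 5, 1)), 45, 5)
  clean <- clean / rowSums(clean)
  out <- matrix(c(10, 0.1, 0.1, 0.1, 0.1), 5, 5, byrow = TRUE)
  out <- out / rowSums(out)
  members <- rbind(clean, out)
  st_mcd <- compartment_stats(members)
  st_cls <- compartment_stats(members, method = "classical")
  true_center <- colMeans(clean %*% simplex_basis(5))
  expect_lt(sqrt(sum((st_mcd$center - true_center)^2)),
            sqrt(sum((st_cls$center - true_center)^2)))
})

test_that("closest compartment is the argmin with taxonomy-order ties", {
  d <- matrix(c(3, 1, 2), 1, dimnames = list("P1",
                                             c("cytosol", "ER", "Golgi")))
  expect_identical(closest_compartment(d), "ER")
  tie <- matrix(c(2, 1, 1), 1, dimnames = list("P1",
                                               c("cytosol", "ER", "Golgi")))
  expect_warning(out <- closest_compartment(tie), "tie")
  expect_identical(out, "ER")
  allsame <- matrix(1, 1, 3, dimnames = list("P1",
                                             c("cytosol", "ER", "Golgi")))
  expect_warning(out2 <- closest_compartment(allsame), "tie")
  expect_identical(out2, "cytosol")
})

test_that("BH adjustment follows the hand-computed step-up procedure", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # m = 4: all adjust to 0.04
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  set.seed(12)
  for (i in 1:5) {
    pv <- runif(20)^2
    expect_equal(p.adjust(pv, "BH"), bh_oracle(pv))
  }
})

test_that("the t-test stage flags planted shifts and nothing under the null", {
  comps <- c("cytosol", "ER", "PM")
  acc <- paste0("P", 1:20)
  mk_dp <- function(shift_p1 = 0) {
    d <- array(1, c(20, 3, 3), dimnames = list(acc, comps, NULL))
    d[, "ER", ] <- 0.5
    set.seed(33)
    d <- d + array(abs(rnorm(length(d), 0, 0.05)), dim(d))
    closest <- rep("ER", 20)
    if (shift_p1 > 0) {        # move P1 toward PM
      d["P1", "PM", ] <- 0.2
      d["P1", "ER", ] <- d["P1", "ER", ] + shift_p1
      closest[1] <- "PM"
    }
    list(distances = d, closest = stats::setNames(closest, acc),
         taxonomy = comps)
  }
  null_res <- test_dl(mk_dp(), mk_dp())
  expect_false(any(null_res$is_DL))
  alt <- test_dl(mk_dp(), mk_dp(shift_p1 = 3))
  expect_true(alt$is_DL[alt$accession == "P1"])
  expect_identical(alt$closest_B[alt$accession == "P1"], "PM")
  expect_equal(sum(alt$is_DL), 1)
  # zero variance in both groups: equal means -> p 1, different -> flagged
  dpA <- list(distances = array(1, c(1, 1, 3),
                                dimnames = list("P1", "ER", NULL)),
              closest = c(P1 = "ER"), taxonomy = "ER")
  dpB <- dpA
  expect_equal(unname(attr(test_dl(dpA, dpB), "p")[1, 1]), 1)
  dpB$distances[] <- 2
  expect_warning(res <- test_dl(dpA, dpB), "zero replicate variance")
  expect_equal(unname(attr(res, "p")[1, 1]), 0)
})

test_that("collation unions the stages and tags shared proteins", {
  qual <- data.frame(accession = c("P1", "P2", "P3"),
                     compartment_A = "ER", compartment_B = "PM")
  quant <- data.frame(accession = c("P3", "P4", "P5", "P6", "P7"),
                      closest_A = "ER", closest_B = "PM",
                      q_closest_A = 0.01, q_closest_B = 0.01,
                      is_DL = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- collate_dl(qual, quant)
  expect_equal(nrow(out), 6)  # P1..P6; P7 is not DL
  expect_identical(out$stage[out$accession == "P3"],
                   "qualitative+quantitative")
  expect_identical(out$stage[out$accession == "P1"], "qualitative")
  empty <- collate_dl(qual[0, ], quant[quant$is_DL == FALSE, ])
  expect_equal(nrow(empty), 0)
})

test_that("a protein's smallest distance is to its own compartment on clean data", {
  exp_ <- small_experiment()
  cm <- merge_nuclear(small_classified())
  dp <- dl_distance_profiles(small_combined()$singles, cm)
  a <- cm$assignments
  cl <- a[!a$marker & a$compartment != "unknown", ]
  agree <- dp$closest[cl$accession] == cl$compartment
  expect_gt(mean(agree), 0.95)
})
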