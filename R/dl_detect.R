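# Detection of differentially localized (DL) proteins between two cell
# lines by the two-stage procedure: (1) qualitative reclassification
# between the combined maps, and (2) significance testing of Mahalanobis
# distance profiles computed per replicate against robust
# (minimum-covariance-determinant) compartment statistics.
#
# Normalized fraction profiles live on a simplex and are therefore rank
# deficient; all distance computations happen after an isometric
# projection onto the orthogonal complement of the all-ones direction,
# with a small ridge floor keeping covariances positive definite.

#' Orthonormal basis of the simplex-profile subspace
#'
#' Columns form an orthonormal basis of the (d-1)-dimensional orthogonal
#' complement of the all-ones vector in R^d, so that projecting
#' row-normalized profiles removes the constant-sum degeneracy
#' isometrically (euclidean distances are preserved).
#'
#' @param d profile length.
#' @return a d x (d-1) matrix.
#' @export
simplex_basis <- function(d) {
  stopifnot(d >= 2)
  H <- stats::contr.helmert(d)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Merge the two nuclear compartments into one
#'
#' Relabels `nucleus_chromatin` and `nucleus_nonchromatin` (markers and
#' predictions alike) to `nucleus` and shrinks the taxonomy accordingly,
#' so maps with and without subnuclear resolution become comparable.
#' Idempotent.
#'
#' @param x a `classified_map` or [marker_set()].
#' @return the relabeled object.
#' @export
merge_nuclear <- function(x) {
  nuc <- c("nucleus_chromatin", "nucleus_nonchromatin")
  relab_tax <- function(tax) {
    if (!any(nuc %in% tax)) return(tax)
    i <- which(tax %in% nuc)[1]
    tax <- tax[!tax %in% nuc]
    append(tax, "nucleus", after = i - 1)
  }
  if (inherits(x, "classified_map")) {
    x$assignments$compartment[x$assignments$compartment %in% nuc] <- "nucleus"
    x$taxonomy <- relab_tax(x$taxonomy)
    x
  } else if (inherits(x, "marker_set")) {
    e <- x$entries
    e[e %in% nuc] <- "nucleus"
    marker_set(e, taxonomy = relab_tax(x$taxonomy))
  } else stop("merge_nuclear expects a classified_map or marker_set")
}

#' Qualitatively differentially localized proteins
#'
#' Proteins in the overlap of two combined maps whose predicted
#' compartments are both non-"unknown", non-marker, and differ.
#'
#' @param combinedA,combinedB nucleus-merged `classified_map`s on a
#'   common taxonomy.
#' @return data frame: accession, compartment_A, compartment_B.
#' @export
qualitative_dl <- function(combinedA, combinedB) {
  stopifnot(inherits(combinedA, "classified_map"),
            inherits(combinedB, "classified_map"))
  a <- combinedA$assignments
  b <- combinedB$assignments
  common <- intersect(a$accession, b$accession)
  if (!length(common)) stop("empty overlap between combined maps")
  ia <- match(common, a$accession)
  ib <- match(common, b$accession)
  keep <- a$compartment[ia] != "unknown" & b$compartment[ib] != "unknown" &
    a$compartment[ia] != b$compartment[ib] &
    !(a$marker[ia] | b$marker[ib])
  data.frame(accession = common[keep],
             compartment_A = a$compartment[ia][keep],
             compartment_B = b$compartment[ib][keep],
             stringsAsFactors = FALSE)
}

#' Robust center and covariance of one compartment's profiles
#'
#' Computes the minimum-covariance-determinant (MCD) location and scatter
#' of the member profiles in the reduced (simplex-projected) coordinates,
#' with support fraction `floor((n + dim + 1)/2)` observations and a
#' ridge floor of `1e-8 * trace/dim` added to keep the covariance
#' positive definite. `method = "classical"` uses the ordinary mean and
#' covariance instead (useful for exact invariance checks).
#'
#' @param profiles matrix of member profiles (rows = member proteins), in
#'   original fraction coordinates.
#' @param method `"mcd"` or `"classical"`.
#' @param project project onto the simplex basis first (default TRUE;
#'   set FALSE when profiles are already full-rank coordinates).
#' @return list with `center`, `cov` (reduced coordinates), `best`
#'   (indices of the MCD support subset, or all rows for classical),
#'   `n`, and `basis` (the projection used, or NULL).
#' @export
compartment_stats <- function(profiles, method = c("mcd", "classical"),
                              project = TRUE) {
  method <- match.arg(method)
  x <- as.matrix(profiles)
  basis <- NULL
  if (project) {
    basis <- simplex_basis(ncol(x))
    x <- x %*% basis
  }
  n <- nrow(x)
  p <- ncol(x)
  if (n < p + 2)
    stop("compartment has ", n, " members; needs >= ", p + 2)
  if (method == "classical") {
    center <- colMeans(x)
    cv <- stats::cov(x)
    best <- seq_len(n)
  } else {
    fit <- mcd_cov(x)
    center <- fit$center
    cv <- fit$cov
    best <- fit$best
  }
  tr <- sum(diag(cv))
  ridge <- if (tr > 0) 1e-8 * tr / p else 1e-12
  cv <- cv + diag(ridge, p)
  list(center = center, cov = cv, best = best, n = n, basis = basis)
}

#' Mahalanobis distance profile of proteins to every compartment
#'
#' For each protein profile x and compartment c,
#' `d_c = sqrt((x - mu_c)' Sigma_c^{-1} (x - mu_c))` using that
#' compartment's (robust) center and covariance in the reduced
#' coordinates.
#'
#' @param profiles proteins-by-fractions matrix (original coordinates
#'   when the stats carry a projection basis).
#' @param stats named list of [compartment_stats()] results, one per
#'   compartment.
#' @return proteins-by-compartments matrix of distances.
#' @export
distance_profile <- function(profiles, stats) {
  x <- as.matrix(profiles)
  out <- matrix(NA_real_, nrow(x), length(stats),
                dimnames = list(rownames(x), names(stats)))
  for (k in seq_along(stats)) {
    s <- stats[[k]]
    z <- if (!is.null(s$basis)) x %*% s$basis else x
    d2 <- stats::mahalanobis(z, s$center, s$cov)
    if (any(!is.finite(d2))) stop("singular covariance for compartment ",
                                  names(stats)[k])
    out[, k] <- sqrt(pmax(d2, 0))
  }
  out
}

#' Closest compartment of each distance profile
#'
#' Argmin over compartments; exact ties resolve to the first compartment
#' in taxonomy order, with a warning.
#'
#' @param distances proteins-by-compartments distance matrix (columns in
#'   taxonomy order).
#' @return character vector of compartment labels.
#' @export
closest_compartment <- function(distances) {
  d <- as.matrix(distances)
  stopifnot(all(is.finite(d)))
  ties <- apply(d, 1, function(r) sum(r == min(r)) > 1)
  if (any(ties))
    warning(sum(ties), " tie(s) in closest-compartment assignment; ",
            "resolved to the first compartment in taxonomy order")
  colnames(d)[apply(d, 1, which.min)]
}

# vectorized two-sided two-sample Student t-test (equal variance) on the
# replicate axis; zero variance in both groups gives p = 1 when the means
# agree and p = 0 (flagged) when they differ
.student_t_rows <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- apply(a, 1, stats::var)
  vb <- apply(b, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  p <- rep(NA_real_, length(ma))
  zero <- se == 0
  if (any(zero & ma != mb))
    warning("zero replicate variance with differing means; ",
            "treating as significant")
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  t <- (ma[!zero] - mb[!zero]) / se[!zero]
  p[!zero] <- 2 * stats::pt(-abs(t), df = na + nb - 2)
  p
}

#' Replicate-wise distance profiles for one condition
#'
#' For every replicate map, compartment statistics are estimated by MCD
#' over the profiles of that compartment's members (SVM-classified
#' proteins plus markers, per the combined map), and every protein's
#' distance profile in that replicate is computed against them. Combined
#' map distances and closest compartments are computed the same way from
#' the combined profiles.
#'
#' @param replicate_maps list of normalized single-replicate
#'   `profile_matrix` objects (or matrices).
#' @param combined a nucleus-merged `classified_map` for the condition.
#' @param min_members smallest compartment size accepted.
#' @return list with `distances` (protein x compartment x replicate
#'   array), `combined_distances` (protein x compartment), `closest`
#'   (named character vector), `taxonomy`.
#' @export
dl_distance_profiles <- function(replicate_maps, combined,
                                 min_members = NULL) {
  stopifnot(inherits(combined, "classified_map"))
  a <- combined$assignments
  comps <- intersect(combined$taxonomy, unique(a$compartment))
  members <- lapply(comps, function(cmp) a$accession[a$compartment == cmp])
  names(members) <- comps
  dim_red <- ncol(combined$profiles) - 1
  min_members <- min_members %||% (dim_red + 2)
  small <- names(members)[vapply(members, length, 1L) < min_members]
  if (length(small))
    stop("compartment(s) below ", min_members, " members: ",
         paste(small, collapse = ", "))
  acc <- a$accession
  mats <- lapply(replicate_maps, .profiles_of)
  for (m in mats)
    if (!all(acc %in% rownames(m)))
      stop("replicate map is missing combined-map proteins")
  dist_arr <- array(NA_real_,
                    c(length(acc), length(comps), length(mats)),
                    dimnames = list(acc, comps, NULL))
  for (r in seq_along(mats)) {
    m <- mats[[r]][acc, , drop = FALSE]
    st <- lapply(members, function(mem) compartment_stats(m[mem, ,
                                                            drop = FALSE]))
    dist_arr[, , r] <- distance_profile(m, st)
  }
  comb_st <- lapply(members, function(mem)
    compartment_stats(combined$profiles[mem, , drop = FALSE]))
  comb_d <- distance_profile(combined$profiles[acc, , drop = FALSE],
                             comb_st)
  list(distances = dist_arr, combined_distances = comb_d,
       closest = stats::setNames(closest_compartment(comb_d), acc),
       taxonomy = comps)
}

#' Test distance profiles for differential localization
#'
#' Per protein and compartment, replicate Mahalanobis distances are
#' compared between conditions by a two-sided two-sample Student t-test;
#' p-values are BH-adjusted over the full protein x compartment family.
#' A protein is quantitatively DL when its closest compartment (from the
#' combined maps) changes between conditions and the distances to both
#' closest compartments change significantly (q <= alpha).
#'
#' @param dpA,dpB [dl_distance_profiles()] results for conditions A and
#'   B (common taxonomy).
#' @param alpha BH false-discovery level.
#' @return data frame: accession, closest_A, closest_B, q_closest_A,
#'   q_closest_B, is_DL; the full q-value matrices are attached as
#'   attributes `q_A` is not retained separately — `q` holds the shared
#'   family (protein x compartment).
#' @export
test_dl <- function(dpA, dpB, alpha = 0.05) {
  if (!identical(dpA$taxonomy, dpB$taxonomy))
    stop("distance profiles have different taxonomies")
  comps <- dpA$taxonomy
  common <- intersect(dimnames(dpA$distances)[[1]],
                      dimnames(dpB$distances)[[1]])
  if (!length(common)) stop("empty overlap between conditions")
  p <- matrix(NA_real_, length(common), length(comps),
              dimnames = list(common, comps))
  for (cmp in comps) {
    a <- matrix(dpA$distances[common, cmp, , drop = FALSE],
                nrow = length(common))
    b <- matrix(dpB$distances[common, cmp, , drop = FALSE],
                nrow = length(common))
    p[, cmp] <- .student_t_rows(a, b)
  }
  q <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  closest_a <- dpA$closest[common]
  closest_b <- dpB$closest[common]
  q_a <- q[cbind(common, closest_a)]
  q_b <- q[cbind(common, closest_b)]
  res <- data.frame(accession = common,
                    closest_A = unname(closest_a),
                    closest_B = unname(closest_b),
                    q_closest_A = unname(q_a),
                    q_closest_B = unname(q_b),
                    is_DL = unname(closest_a != closest_b &
                                     q_a <= alpha & q_b <= alpha),
                    stringsAsFactors = FALSE)
  attr(res, "q") <- q
  attr(res, "p") <- p
  attr(res, "alpha") <- alpha
  res
}

#' Collate qualitative and quantitative DL calls
#'
#' Union of the two stages, deduplicated by accession, each row tagged
#' with its stage(s).
#'
#' @param qualitative data frame from [qualitative_dl()].
#' @param quantitative data frame from [test_dl()].
#' @return data frame: accession, stage, compartment_A, compartment_B
#'   (classified compartments where available, else closest).
#' @export
collate_dl <- function(qualitative, quantitative) {
  qual <- if (nrow(qualitative)) data.frame(
    accession = qualitative$accession, stage = "qualitative",
    compartment_A = qualitative$compartment_A,
    compartment_B = qualitative$compartment_B,
    stringsAsFactors = FALSE) else NULL
  qdl <- quantitative[quantitative$is_DL, , drop = FALSE]
  quant <- if (nrow(qdl)) data.frame(
    accession = qdl$accession, stage = "quantitative",
    compartment_A = qdl$closest_A, compartment_B = qdl$closest_B,
    stringsAsFactors = FALSE) else NULL
  all <- rbind(qual, quant)
  if (is.null(all))
    return(data.frame(accession = character(0), stage = character(0),
                      compartment_A = character(0),
                      compartment_B = character(0)))
  out <- do.call(rbind, lapply(split(all, all$accession), function(d) {
    data.frame(accession = d$accession[1],
               stage = paste(sort(unique(d$stage)), collapse = "+"),
               compartment_A = d$compartment_A[1],
               compartment_B = d$compartment_B[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$accession), , drop = FALSE]
}

#' End-to-end differential-localization detection
#'
#' Runs the full two-stage procedure: nucleus merging, qualitative
#' comparison of the combined maps, replicate-wise Mahalanobis distance
#' profiles with MCD compartment statistics, the t-test/BH stage, and
#' collation.
#'
#' @param repsA,repsB lists of normalized single-replicate maps.
#' @param combinedA,combinedB `classified_map`s of the combined maps
#'   (nuclear compartments are merged internally).
#' @param alpha BH false-discovery level.
#' @return list with `table` (collated DL calls), `quantitative` (full
#'   [test_dl()] result) and `qualitative`.
#' @export
detect_dl <- function(repsA, repsB, combinedA, combinedB, alpha = 0.05) {
  combinedA <- merge_nuclear(combinedA)
  combinedB <- merge_nuclear(combinedB)
  qual <- qualitative_dl(combinedA, combinedB)
  dpA <- dl_distance_profiles(repsA, combinedA)
  dpB <- dl_distance_profiles(repsB, combinedB)
  quant <- test_dl(dpA, dpB, alpha = alpha)
  list(table = collate_dl(qual, quant), quantitative = quant,
       qualitative = qual)
}
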