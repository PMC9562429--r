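# Moderated two-group differential expression with a peptide-count-
# informed variance prior, Fisher-exact term enrichment, and profile
# colocalization ranking.

#' Moderated differential expression with peptide-count variance prior
#'
#' Fits a per-protein two-group comparison on imputed log2 intensities.
#' Residual variances are shrunk toward a trend over log peptide count by
#' empirical Bayes (proteins quantified by few peptides are noisier, so
#' they borrow a larger prior variance): the prior degrees of freedom and
#' the count-dependent prior variance are estimated with
#' [limma::squeezeVar()] (trended over `log(peptide count)`), and the
#' moderated t-statistic uses the posterior variance
#' `(d0 * s0^2 + d * s^2) / (d0 + d)` with `d0 + d` degrees of freedom.
#' As `d0 -> 0` the statistic reduces to the ordinary t-test; as
#' `d0 -> Inf` it collapses onto the trend.
#'
#' @param log2_mat imputed log2-intensity matrix (proteins x samples,
#'   rownames = accessions, no missing values).
#' @param groups two-level factor/character vector over the columns.
#' @param peptide_counts integer razor+unique peptide counts per protein.
#' @param alpha BH false-discovery level for the `significant` flag.
#' @param prior_df optional fixed prior degrees of freedom (overrides the
#'   empirical-Bayes estimate; mainly for method checks).
#' @return data frame: accession, log2fc (positive = higher in the first
#'   group level), t, df, p, q, peptides, prior_var, significant.
#' @export
moderated_de <- function(log2_mat, groups, peptide_counts, alpha = 0.05,
                         prior_df = NULL) {
  m <- as.matrix(log2_mat)
  if (anyNA(m)) stop("log2 matrix contains missing values; impute first")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 replicates")
  stopifnot(length(peptide_counts) == nrow(m))
  a <- m[, groups == levels(groups)[1], drop = FALSE]
  b <- m[, groups == levels(groups)[2], drop = FALSE]
  fc <- rowMeans(a) - rowMeans(b)
  df_res <- n1 + n2 - 2
  s2 <- ((n1 - 1) * apply(a, 1, stats::var) +
           (n2 - 1) * apply(b, 1, stats::var)) / df_res
  sq <- limma::squeezeVar(s2, df = df_res,
                          covariate = log(pmax(peptide_counts, 1)))
  d0 <- prior_df %||% sq$df.prior
  s02 <- sq$var.prior
  if (!is.finite(d0)) {
    post <- s02
    df_total <- Inf
  } else {
    post <- (d0 * s02 + df_res * s2) / (d0 + df_res)
    df_total <- d0 + df_res
  }
  t <- fc / sqrt(post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df = df_total)
  q <- bh_adjust(p)
  data.frame(accession = rownames(m) %||% sprintf("P%05d", seq_len(nrow(m))),
             log2fc = unname(fc), t = unname(t), df = df_total,
             p = unname(p), q = unname(q),
             peptides = as.integer(peptide_counts),
             prior_var = unname(s02),
             significant = unname(q <= alpha),
             stringsAsFactors = FALSE)
}

#' Fisher-exact term enrichment
#'
#' Per annotation term, a 2x2 table of foreground membership against
#' term annotation over the background is tested two-sided by Fisher's
#' exact test; p-values are BH-adjusted over terms.
#'
#' @param foreground character accessions (subset of background).
#' @param background character accession universe.
#' @param annotations data frame with columns `accession`, `term` (one
#'   row per annotation).
#' @param alpha BH false-discovery level.
#' @return data frame: term, fg_with, fg_without, bg_with, bg_without,
#'   enrichment (ratio of in-foreground annotation rates), p, q,
#'   significant.
#' @export
fisher_enrichment <- function(foreground, background, annotations,
                              alpha = 0.02) {
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  annotations <- as.data.frame(annotations)
  stopifnot(all(c("accession", "term") %in% names(annotations)))
  annotations <- annotations[annotations$accession %in% background, ,
                             drop = FALSE]
  if (!nrow(annotations)) stop("no annotations overlap the background")
  terms <- unique(annotations$term)
  n_fg <- length(unique(foreground))
  n_bg <- length(unique(background))
  rows <- lapply(terms, function(tm) {
    with_term <- unique(annotations$accession[annotations$term == tm])
    a <- sum(foreground %in% with_term)           # fg & term
    b <- n_fg - a                                 # fg & !term
    c_ <- length(with_term) - a                   # !fg & term
    d <- (n_bg - n_fg) - c_                       # !fg & !term
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "two.sided")$p.value
    rate_fg <- a / n_fg
    rate_bg <- length(with_term) / n_bg
    data.frame(term = tm, fg_with = a, fg_without = b,
               bg_with = length(with_term),
               bg_without = n_bg - length(with_term),
               enrichment = if (rate_bg > 0) rate_fg / rate_bg else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= alpha
  out[order(out$p), , drop = FALSE]
}

#' Rank cluster members by profile correlation with anchor proteins
#'
#' For every non-anchor protein classified to `cluster`, the mean
#' Pearson correlation of its combined-map profile with the anchors'
#' profiles is computed; the top k are returned (the colocalization
#' candidates of, e.g., the immunoglobulin chains within the ER
#' cluster).
#'
#' @param map a `classified_map` (combined map).
#' @param cluster compartment label.
#' @param anchors accessions classified to `cluster`.
#' @param k number of proteins to return.
#' @return data frame: accession, mean_r, ranked decreasingly.
#' @export
colocalization_ranking <- function(map, cluster, anchors, k = 20) {
  stopifnot(inherits(map, "classified_map"))
  a <- map$assignments
  members <- a$accession[a$compartment == cluster]
  if (!all(anchors %in% members))
    stop("anchor(s) not classified to ", cluster, ": ",
         paste(setdiff(anchors, members), collapse = ", "))
  others <- setdiff(members, anchors)
  if (!length(others)) stop("cluster has no non-anchor members")
  anc <- t(map$profiles[anchors, , drop = FALSE])
  oth <- t(map$profiles[others, , drop = FALSE])
  r <- stats::cor(oth, anc)  # others x anchors
  mean_r <- rowMeans(r)
  ord <- order(-mean_r)[seq_len(min(k, length(others)))]
  data.frame(accession = others[ord], mean_r = unname(mean_r[ord]),
             stringsAsFactors = FALSE)
}
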