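# Classification reproducibility between map pairs, stratified by
# SVM-score classes. Marker proteins are removed before comparison (their
# labels are fixed annotations, not predictions); "unknown" counts as a
# comparable label.

#' SVM-score strata boundaries
#'
#' Prediction-confidence classes: very_high (score >= 0.9), high
#' (0.7-0.9), medium (0.5-0.7), low (< 0.5). The strata partition [0,1].
#'
#' @param score numeric scores in `[0, 1]`.
#' @return ordered factor with levels very_high, high, medium, low.
#' @export
score_stratum <- function(score) {
  cut(score, breaks = c(-Inf, 0.5, 0.7, 0.9, Inf), right = FALSE,
      labels = c("low", "medium", "high", "very_high")) |>
    factor(levels = c("very_high", "high", "medium", "low"))
}

# overlap of non-marker proteins between two classified maps
.concordance_overlap <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "classified_map"),
            inherits(mapB, "classified_map"))
  a <- mapA$assignments[!mapA$assignments$marker, ]
  b <- mapB$assignments[!mapB$assignments$marker, ]
  common <- intersect(a$accession, b$accession)
  if (!length(common))
    stop("empty overlap between maps after marker removal")
  ia <- match(common, a$accession)
  ib <- match(common, b$accession)
  data.frame(accession = common,
             label_A = a$compartment[ia], label_B = b$compartment[ib],
             score_A = a$score[ia], score_B = b$score[ib],
             stringsAsFactors = FALSE)
}

#' Pairwise concordance of two classified maps
#'
#' Fraction of overlapping non-marker proteins with identical
#' classification ("unknown" counting as a label). Symmetric in its
#' arguments.
#'
#' @param mapA,mapB `classified_map` objects.
#' @return concordance fraction in `[0, 1]`.
#' @export
pairwise_concordance <- function(mapA, mapB) {
  ov <- .concordance_overlap(mapA, mapB)
  mean(ov$label_A == ov$label_B)
}

#' Concordance stratified by SVM-score class
#'
#' The overlap is partitioned by the stratum of `min(score_A, score_B)`
#' (the conservative, symmetric choice) and concordance is computed per
#' stratum; empty strata are reported as `NA`.
#'
#' @inheritParams pairwise_concordance
#' @return data frame with columns stratum, n, concordance.
#' @export
stratified_concordance <- function(mapA, mapB) {
  ov <- .concordance_overlap(mapA, mapB)
  st <- score_stratum(pmin(ov$score_A, ov$score_B))
  agree <- ov$label_A == ov$label_B
  out <- data.frame(stratum = levels(st),
                    n = as.integer(table(st)[levels(st)]),
                    concordance = NA_real_)
  for (k in seq_len(nrow(out))) {
    ix <- st == out$stratum[k]
    if (any(ix)) out$concordance[k] <- mean(agree[ix])
  }
  out
}

#' Compare a classified map against a reference annotation
#'
#' Reference entries annotating a protein with more than one location are
#' excluded; agreement is computed per predicted class over the overlap,
#' alongside the full predicted-by-reference contingency table.
#'
#' @param map a `classified_map`.
#' @param reference data frame with columns `accession`, `location`
#'   (one row per annotated location; multi-location accessions are
#'   dropped).
#' @return list with `agreement` (data frame: class, n, fraction) and
#'   `contingency` (predicted x reference table).
#' @export
compare_to_reference <- function(map, reference) {
  stopifnot(inherits(map, "classified_map"))
  reference <- as.data.frame(reference)
  stopifnot(all(c("accession", "location") %in% names(reference)))
  multi <- names(which(table(reference$accession) > 1))
  reference <- reference[!reference$accession %in% multi, , drop = FALSE]
  a <- map$assignments
  common <- intersect(a$accession, reference$accession)
  if (!length(common)) stop("empty overlap with reference annotation")
  pred <- a$compartment[match(common, a$accession)]
  ref <- reference$location[match(common, reference$accession)]
  tab <- table(predicted = pred, reference = ref)
  agr <- data.frame(class = rownames(tab),
                    n = as.integer(rowSums(tab)),
                    fraction = vapply(rownames(tab), function(cl) {
                      if (!cl %in% colnames(tab)) return(0)
                      tab[cl, cl] / sum(tab[cl, ])
                    }, 1.0), row.names = NULL)
  list(agreement = agr, contingency = tab)
}
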