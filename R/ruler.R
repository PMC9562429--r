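# Proteomic-ruler copy-number estimation: the summed MS signal of
# histones is anchored to the cell's DNA mass (genome size x ploidy), so
# protein copies per cell follow from intensity ratios without spike-in
# standards. Organelle protein masses combine copy numbers with the map
# classification, weighting each protein's mass by the share of its
# signal recovered in the nuclear / organellar / cytosolic fraction
# groups.

#' Ruler configuration
#'
#' @param genome_size_bp haploid genome size (bp).
#' @param ploidy cell ploidy; either given directly or derived via
#'   [derive_ploidy()] from `reference_genome_size_bp`.
#' @param reference_genome_size_bp reference (diploid-normalizing)
#'   genome size used when deriving ploidy.
#' @param bp_molar_mass mean molar mass of a DNA base pair
#'   (g/mol, default 615.8771).
#' @return a `ruler_config` list (with `dna_mass_mol`, the product
#'   genome_size x ploidy x bp_molar_mass, in g/mol units).
#' @export
ruler_config <- function(genome_size_bp, ploidy = NULL,
                         reference_genome_size_bp = NULL,
                         bp_molar_mass = 615.8771) {
  stopifnot(genome_size_bp > 0, bp_molar_mass > 0)
  if (is.null(ploidy)) {
    if (is.null(reference_genome_size_bp))
      stop("give either ploidy or reference_genome_size_bp")
    ploidy <- derive_ploidy(genome_size_bp, reference_genome_size_bp)
  }
  stopifnot(ploidy > 0)
  structure(list(genome_size_bp = genome_size_bp, ploidy = ploidy,
                 bp_molar_mass = bp_molar_mass,
                 dna_mass_mol = genome_size_bp * ploidy * bp_molar_mass),
            class = "ruler_config")
}

#' Derive ploidy from a genome-size ratio
#'
#' Twice the ratio of the cell line's genome size to the reference
#' species' genome size (i.e. the diploid-equivalent DNA content),
#' rounded to two decimals for configuration echo.
#'
#' @param genome_size_bp cell-line genome size (bp).
#' @param reference_genome_size_bp reference genome size (bp).
#' @return ploidy, rounded to 2 decimals.
#' @export
derive_ploidy <- function(genome_size_bp, reference_genome_size_bp) {
  if (genome_size_bp <= 0 || reference_genome_size_bp <= 0)
    stop("genome sizes must be positive")
  round(2 * genome_size_bp / reference_genome_size_bp, 2)
}

#' Normalize and yield-weight TMT fractions into per-protein totals
#'
#' Each TMT channel of a replicate map is normalized to the total channel
#' intensity and weighted by that fraction's protein yield, making the
#' weighted value an estimate of the protein's mass recovered in the
#' fraction. Weighted values are summed into one value per protein and
#' replicate, and also pooled into the three fraction groups nucleus
#' (fraction 1), organelle (fractions 2..9), cytosol (last fraction),
#' expressed as shares of their sum.
#'
#' @param replicate_maps list of raw proteins-by-fractions intensity
#'   matrices (one per replicate, identical rownames).
#' @param yields replicate-by-fraction matrix of protein yields
#'   (micrograms).
#' @return list with `summed` (proteins x replicates matrix of weighted
#'   totals) and `shares` (proteins x 3 matrix of mean nucleus /
#'   organelle / cytosol shares across replicates; per-replicate share
#'   arrays in `shares_by_replicate`).
#' @export
weight_tmt_fractions <- function(replicate_maps, yields) {
  yields <- as.matrix(yields)
  stopifnot(length(replicate_maps) == nrow(yields))
  nf <- ncol(replicate_maps[[1]])
  stopifnot(ncol(yields) == nf, nf >= 3)
  acc <- rownames(replicate_maps[[1]])
  summed <- matrix(NA_real_, length(acc), length(replicate_maps),
                   dimnames = list(acc, NULL))
  groups <- list(nucleus = 1L, organelle = 2:(nf - 1), cytosol = nf)
  shr <- array(NA_real_, c(length(acc), 3, length(replicate_maps)),
               dimnames = list(acc, names(groups), NULL))
  for (r in seq_along(replicate_maps)) {
    m <- as.matrix(replicate_maps[[r]])[acc, , drop = FALSE]
    tot <- colSums(m)
    if (any(tot <= 0)) stop("zero total channel intensity in replicate ", r)
    w <- sweep(m, 2, yields[r, ] / tot, "*")
    summed[, r] <- rowSums(w)
    g <- vapply(groups, function(j) rowSums(w[, j, drop = FALSE]),
                numeric(length(acc)))
    if (is.null(dim(g)))
      g <- matrix(g, nrow = 1, dimnames = list(acc, names(groups)))
    shr[, , r] <- g / rowSums(g)
  }
  list(summed = summed, shares = apply(shr, c(1, 2), mean),
       shares_by_replicate = shr)
}

#' Proteomic-ruler copy numbers per cell
#'
#' `copies_i = (I_i / sum of histone I) * (genome_size * ploidy *
#' bp_molar_mass) / MW_i`; the total histone mass per cell equals the
#' DNA mass by construction, and the estimate is invariant to rescaling
#' all intensities.
#'
#' @param intensities named nonnegative per-protein summed MS signal.
#' @param mol_weight molecular weights (g/mol), same order.
#' @param is_histone logical histone flags, same order.
#' @param config a [ruler_config()].
#' @return data frame: accession, intensity, mol_weight,
#'   copies_per_cell, mass_per_cell (grams).
#' @export
copies_per_cell <- function(intensities, mol_weight, is_histone, config) {
  stopifnot(inherits(config, "ruler_config"),
            length(intensities) == length(mol_weight),
            length(intensities) == length(is_histone))
  hist_total <- sum(intensities[is_histone])
  if (!any(is_histone) || hist_total <= 0)
    stop("no histone protein with positive intensity")
  avogadro <- 6.02214076e23
  copies <- intensities / hist_total * config$dna_mass_mol / mol_weight
  data.frame(accession = names(intensities) %||%
               sprintf("P%05d", seq_along(intensities)),
             intensity = unname(intensities),
             mol_weight = mol_weight,
             copies_per_cell = unname(copies),
             mass_per_cell = unname(copies * mol_weight / avogadro),
             stringsAsFactors = FALSE)
}

# fraction-group weight applying to a compartment label
.group_of <- function(label) {
  nuclear <- c("nucleus", "nucleus_chromatin", "nucleus_nonchromatin")
  ifelse(label %in% nuclear, "nucleus",
         ifelse(label == "cytosol", "cytosol", "organelle"))
}

#' Relative organelle protein masses
#'
#' Each protein's mass per cell is weighted by its share of signal in the
#' fraction group matching its assigned compartment (nuclear classes by
#' the nucleus share, the cytosol class by the cytosol share, every other
#' organelle class — including ribosome and proteasome, which pellet
#' across the organellar fractions — by the organelle share). Weighted
#' masses are summed per compartment and expressed as fractions of the
#' total protein mass; mass not captured by a compartment (unclassified
#' proteins and the out-of-group remainder) is pooled as `unassigned`,
#' so the fractions close to 1.
#'
#' @param copies data frame from [copies_per_cell()].
#' @param labels named compartment labels (accession -> label,
#'   "unknown" allowed).
#' @param shares proteins x 3 share matrix from
#'   [weight_tmt_fractions()] (rownames = accessions).
#' @return data frame: compartment, mass_fraction (including the
#'   `unassigned` pool).
#' @export
organelle_masses <- function(copies, labels, shares) {
  acc <- copies$accession
  if (!all(acc %in% names(labels))) stop("missing label for some proteins")
  if (!all(acc %in% rownames(shares)))
    stop("missing share vector for some proteins")
  lab <- labels[acc]
  shr <- shares[acc, , drop = FALSE]
  mass <- copies$mass_per_cell
  total <- sum(mass)
  w <- ifelse(lab == "unknown", 0,
              shr[cbind(seq_along(acc), match(.group_of(lab),
                                              colnames(shr)))])
  comps <- sort(unique(lab[lab != "unknown"]))
  frac <- vapply(comps, function(cmp)
    sum(mass[lab == cmp] * w[lab == cmp]) / total, 1.0)
  data.frame(compartment = c(comps, "unassigned"),
             mass_fraction = c(frac, 1 - sum(frac)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top mass-contributing proteins of one organelle
#'
#' @param copies data frame from [copies_per_cell()].
#' @param labels named compartment labels.
#' @param organelle compartment to rank within.
#' @param k number of proteins to return (all, with a warning, when the
#'   organelle has fewer members).
#' @return data frame: accession, mass_per_cell, mass_share (of the
#'   organelle's summed mass), ranked decreasingly.
#' @export
top_contributors <- function(copies, labels, organelle, k = 10) {
  acc <- copies$accession
  lab <- labels[acc]
  ix <- which(lab == organelle)
  if (!length(ix)) stop("organelle ", organelle, " has no member proteins")
  if (length(ix) < k) {
    warning("organelle ", organelle, " has only ", length(ix),
            " proteins; returning all")
    k <- length(ix)
  }
  m <- copies$mass_per_cell[ix]
  ord <- order(-m)[seq_len(k)]
  data.frame(accession = acc[ix][ord],
             mass_per_cell = m[ord],
             mass_share = m[ord] / sum(m),
             stringsAsFactors = FALSE)
}

#' Agreement of lysate- and fraction-derived copy numbers
#'
#' Pearson correlation and least-squares slope of log10 fraction-derived
#' copies against log10 lysate-derived copies over the overlapping
#' proteins.
#'
#' @param lysate_copies,fraction_copies named copies-per-cell vectors.
#' @return list with `r`, `slope`, `n`.
#' @export
cross_method_agreement <- function(lysate_copies, fraction_copies) {
  common <- intersect(names(lysate_copies), names(fraction_copies))
  common <- common[lysate_copies[common] > 0 &
                     fraction_copies[common] > 0]
  if (length(common) < 3) stop("fewer than 3 overlapping proteins")
  x <- log10(lysate_copies[common])
  y <- log10(fraction_copies[common])
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(stats::lm(y ~ x))[2]),
       n = length(common))
}
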