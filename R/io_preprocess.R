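# Ingestion and Perseus-equivalent preprocessing of proteinGroups-like
# tables: identification filtering, complete-reporter-series retention,
# per-replicate profile normalization, replicate merging, and left-shifted
# imputation of lysate LFQ values.

#' Read a proteinGroups-like TSV file
#'
#' Parses the minimal MaxQuant dialect written by
#' [write_protein_groups()]. Flag columns use the `"+"` convention; an
#' absent `Only identified by site` column is treated as all-false with a
#' warning (tolerant ingestion of minimal dialects). Zero intensities are
#' kept as written (they are treated as missing only by
#' [require_complete_reporters()]).
#'
#' @param path file path.
#' @param dialect `"tmt"` or `"lfq"`.
#' @return a [protein_groups()] object.
#' @export
read_protein_groups <- function(path, dialect = c("tmt", "lfq")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"Protein IDs" %in% names(df))
    stop("required column missing: Protein IDs")
  pref <- .intensity_prefix(dialect)
  icols <- grep(paste0("^", pref), names(df), value = TRUE)
  if (!length(icols))
    stop("required columns missing: no '", trimws(pref), "' columns ",
         "found under the ", dialect, " dialect")
  if (!"Razor + unique peptides" %in% names(df))
    stop("required column missing: Razor + unique peptides")
  ints <- as.matrix(df[icols])
  storage.mode(ints) <- "double"
  colnames(ints) <- sub(paste0("^", pref), "", icols)
  parse_flag <- function(col) {
    if (!col %in% names(df)) return(NULL)
    !is.na(df[[col]]) & trimws(as.character(df[[col]])) == "+"
  }
  site <- parse_flag(.flag_cols["site_only"])
  if (is.null(site)) {
    warning("'Only identified by site' column absent; treating as unflagged")
    site <- rep(FALSE, nrow(df))
  }
  mw <- if ("Mol. weight [kDa]" %in% names(df))
    df[["Mol. weight [kDa]"]] * 1000 else rep(NA_real_, nrow(df))
  protein_groups(df[["Protein IDs"]], ints, dialect = dialect,
                 peptides = df[["Razor + unique peptides"]],
                 mol_weight = mw,
                 reverse = parse_flag(.flag_cols["reverse"]) %||%
                   rep(FALSE, nrow(df)),
                 contaminant = parse_flag(.flag_cols["contaminant"]) %||%
                   rep(FALSE, nrow(df)),
                 site_only = site)
}

.subset_pg <- function(pg, keep) {
  protein_groups(pg$accession[keep],
                 pg$intensities[keep, , drop = FALSE],
                 dialect = pg$dialect, peptides = pg$peptides[keep],
                 mol_weight = pg$mol_weight[keep],
                 reverse = pg$reverse[keep],
                 contaminant = pg$contaminant[keep],
                 site_only = pg$site_only[keep])
}

#' Remove decoy, contaminant and site-only identifications
#'
#' Drops rows flagged as reverse-database matches, potential
#' contaminants, or identified only by a modification site. Row order is
#' preserved.
#'
#' @param pg a [protein_groups()] object.
#' @return the filtered object.
#' @export
filter_identifications <- function(pg) {
  stopifnot(inherits(pg, "protein_groups"))
  .subset_pg(pg, !(pg$reverse | pg$contaminant | pg$site_only))
}

#' Retain only proteins with a complete reporter-ion series
#'
#' A reporter intensity of zero (or `NA`) counts as missing. Single
#' replicate maps require all 10 channels; combined maps require the
#' complete series across all replicates of a cell line (30 channels for
#' a 3 x 10-plex design), which is obtained by passing the column-bound
#' replicate matrices.
#'
#' @param x a [protein_groups()] object or an intensity matrix.
#' @param n_required_channels number of leading channels that must all
#'   be observed (default: all channels present).
#' @return the filtered object/matrix.
#' @export
require_complete_reporters <- function(x, n_required_channels = NULL) {
  ints <- if (inherits(x, "protein_groups")) x$intensities else as.matrix(x)
  n_required_channels <- n_required_channels %||% ncol(ints)
  if (n_required_channels > ncol(ints))
    stop("n_required_channels (", n_required_channels,
         ") exceeds available channels (", ncol(ints), ")")
  sub <- ints[, seq_len(n_required_channels), drop = FALSE]
  keep <- rowSums(is.na(sub) | sub <= 0) == 0
  if (inherits(x, "protein_groups")) .subset_pg(x, keep)
  else ints[keep, , drop = FALSE]
}

#' Profile matrix of relative reporter intensities
#'
#' Wraps a proteins-by-channels matrix whose rows, within each
#' replicate's block of channels, sum to one.
#'
#' @param intensities nonnegative matrix with unique rownames.
#' @param replicate integer replicate label per column.
#' @param fraction integer fraction index per column.
#' @param normalized logical flag.
#' @return a `profile_matrix`.
#' @export
profile_matrix <- function(intensities, replicate = rep(1L, ncol(intensities)),
                           fraction = seq_len(ncol(intensities)),
                           normalized = FALSE) {
  intensities <- as.matrix(intensities)
  stopifnot(!is.null(rownames(intensities)),
            !anyDuplicated(rownames(intensities)),
            length(replicate) == ncol(intensities),
            length(fraction) == ncol(intensities),
            all(intensities >= 0, na.rm = TRUE))
  structure(list(intensities = intensities,
                 replicate = as.integer(replicate),
                 fraction = as.integer(fraction),
                 normalized = isTRUE(normalized)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d proteins x %d channels (%d replicate%s)%s\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$replicate)),
              if (length(unique(x$replicate)) > 1) "s" else "",
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize profiles to relative intensities
#'
#' Each protein's intensities are divided by their sum within each
#' replicate's block of channels, so every row sums to one per replicate
#' block. Idempotent.
#'
#' @param x a [protein_groups()] object, matrix, or `profile_matrix`.
#' @param replicate integer replicate label per column (default: one
#'   block).
#' @return a normalized `profile_matrix`.
#' @export
normalize_profiles <- function(x, replicate = NULL) {
  if (inherits(x, "profile_matrix")) {
    ints <- x$intensities
    replicate <- replicate %||% x$replicate
  } else if (inherits(x, "protein_groups")) {
    ints <- x$intensities
  } else ints <- as.matrix(x)
  replicate <- replicate %||% rep(1L, ncol(ints))
  out <- ints
  for (r in unique(replicate)) {
    j <- which(replicate == r)
    s <- rowSums(ints[, j, drop = FALSE])
    if (any(s <= 0))
      stop("zero row sum in replicate block ", r,
           " (apply require_complete_reporters first)")
    out[, j] <- ints[, j, drop = FALSE] / s
  }
  profile_matrix(out, replicate = replicate,
                 fraction = stats::ave(seq_along(replicate), replicate,
                                       FUN = seq_along),
                 normalized = TRUE)
}

#' Merge replicate maps into a combined map
#'
#' Restricts to proteins present in every replicate map, averages their
#' normalized profiles and renormalizes rows to sum one. Combined rows
#' are convex combinations of the replicate rows.
#'
#' @param maps list of normalized single-replicate `profile_matrix`
#'   objects with equal fraction counts.
#' @return a combined `profile_matrix`.
#' @export
combine_replicates <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, TRUE, "profile_matrix")))
  if (!all(vapply(maps, function(m) m$normalized, TRUE)))
    stop("all replicate maps must be normalized")
  nf <- vapply(maps, function(m) ncol(m$intensities), 1L)
  if (length(unique(nf)) != 1) stop("replicate maps differ in fraction count")
  common <- Reduce(intersect, lapply(maps, function(m) rownames(m$intensities)))
  if (!length(common)) stop("empty intersection of replicate maps")
  acc <- Reduce(`+`, lapply(maps, function(m)
    m$intensities[common, , drop = FALSE])) / length(maps)
  acc <- acc / rowSums(acc)
  profile_matrix(acc, normalized = TRUE)
}

#' Impute missing lysate values from a left-shifted normal
#'
#' Per sample column, missing cells are replaced by draws from
#' `Normal(mean - downshift * sd, (width * sd)^2)` with mean and sd of the
#' observed values of that column — the Perseus convention for values
#' missing because the protein fell below the detection limit. Observed
#' cells are untouched.
#'
#' @param log2_mat log2-intensity matrix with `NA` for missing values.
#' @param downshift shift of the imputation distribution, in column SDs.
#' @param width SD of the imputation distribution, in column SDs.
#' @param seed integer seed.
#' @return the imputed matrix.
#' @export
impute_lysate <- function(log2_mat, downshift = 1.8, width = 0.3, seed = 1) {
  m <- as.matrix(log2_mat)
  with_seed(derive_seed(seed, "impute"), {
    for (j in seq_len(ncol(m))) {
      obs <- m[, j][!is.na(m[, j])]
      miss <- which(is.na(m[, j]))
      if (!length(miss)) next
      if (length(obs) < 2)
        stop("column ", j, " has fewer than 2 observed values")
      m[miss, j] <- stats::rnorm(length(miss),
                                 mean(obs) - downshift * stats::sd(obs),
                                 width * stats::sd(obs))
    }
    m
  })
}

#' Plan the orthogonal combination of high-pH fractions
#'
#' Collected high-pH reverse-phase fractions are pooled for MS analysis:
#' fractions 1-15 into one pool, fractions 16-49 orthogonally in pairs
#' (16 + 33, 17 + 34, ...), and the remaining fractions 50 onward into a
#' final pool. The pools partition `1..n_collected`.
#'
#' @param n_collected number of collected fractions (>= 50).
#' @return list of integer vectors (the pools).
#' @export
plan_highph_combination <- function(n_collected = 70) {
  if (n_collected < 50) stop("n_collected must be >= 50")
  pools <- c(list(1:15),
             lapply(16:32, function(i) c(i, i + 17L)),
             list(50:as.integer(n_collected)))
  pools
}
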