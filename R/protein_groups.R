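# Minimal MaxQuant "proteinGroups.txt" dialect: only the columns the
# pipeline reads are written/parsed, with the "+" marker convention for
# boolean flag columns.

.flag_cols <- c(reverse = "Reverse",
                contaminant = "Potential contaminant",
                site_only = "Only identified by site")

#' Construct a proteinGroups-like table
#'
#' @param accession character protein identifiers (unique).
#' @param intensities numeric matrix, proteins x channels. For the
#'   `"tmt"` dialect columns are reporter channels; for `"lfq"` they are
#'   LFQ samples (column names become sample names).
#' @param dialect `"tmt"` or `"lfq"`.
#' @param peptides razor + unique peptide counts.
#' @param mol_weight molecular weight in g/mol.
#' @param reverse,contaminant,site_only logical flag vectors.
#' @return a `protein_groups` list.
#' @export
protein_groups <- function(accession, intensities,
                           dialect = c("tmt", "lfq"),
                           peptides = rep(1L, length(accession)),
                           mol_weight = rep(NA_real_, length(accession)),
                           reverse = rep(FALSE, length(accession)),
                           contaminant = rep(FALSE, length(accession)),
                           site_only = rep(FALSE, length(accession))) {
  dialect <- match.arg(dialect)
  intensities <- as.matrix(intensities)
  stopifnot(length(accession) == nrow(intensities),
            !anyDuplicated(accession))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- if (dialect == "tmt")
      paste0("C", seq_len(ncol(intensities)))
    else paste0("S", seq_len(ncol(intensities)))
  rownames(intensities) <- accession
  structure(list(accession = accession, intensities = intensities,
                 dialect = dialect, peptides = as.integer(peptides),
                 mol_weight = mol_weight, reverse = reverse,
                 contaminant = contaminant, site_only = site_only),
            class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("protein_groups [%s]: %d proteins x %d channels\n",
              x$dialect, length(x$accession), ncol(x$intensities)))
  invisible(x)
}

.intensity_prefix <- function(dialect) {
  if (dialect == "tmt") "Reporter intensity corrected " else "LFQ intensity "
}

#' Write a proteinGroups-like TSV file
#'
#' Columns: `Protein IDs`, per-channel `Reporter intensity corrected <k>`
#' (tmt) or `LFQ intensity <sample>` (lfq), `Razor + unique peptides`,
#' `Mol. weight [kDa]`, and the `"+"`-marked flag columns `Reverse`,
#' `Potential contaminant`, `Only identified by site`. Missing
#' intensities are written as 0 (the MaxQuant convention).
#'
#' @param pg a [protein_groups()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(pg, path) {
  stopifnot(inherits(pg, "protein_groups"))
  if (!length(pg$accession)) stop("empty table")
  ints <- pg$intensities
  ints[is.na(ints)] <- 0
  df <- data.frame(`Protein IDs` = pg$accession, check.names = FALSE,
                   stringsAsFactors = FALSE)
  cn <- if (pg$dialect == "tmt") seq_len(ncol(ints)) else colnames(ints)
  for (j in seq_len(ncol(ints)))
    df[[paste0(.intensity_prefix(pg$dialect), cn[j])]] <- ints[, j]
  df[["Razor + unique peptides"]] <- pg$peptides
  df[["Mol. weight [kDa]"]] <- pg$mol_weight / 1000
  df[["Reverse"]] <- ifelse(pg$reverse, "+", "")
  df[["Potential contaminant"]] <- ifelse(pg$contaminant, "+", "")
  df[["Only identified by site"]] <- ifelse(pg$site_only, "+", "")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
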