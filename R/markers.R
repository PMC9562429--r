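# Organelle marker taxonomy management and the homology-transfer rule
# for porting a marker set between species.

#' Organelle marker set
#'
#' @param entries named character vector mapping accession to compartment
#'   label.
#' @param taxonomy ordered compartment taxonomy; every entry label must
#'   belong to it.
#' @return a `marker_set`.
#' @export
marker_set <- function(entries, taxonomy = default_taxonomy()) {
  stopifnot(is.character(entries), !is.null(names(entries)))
  if (anyDuplicated(names(entries)))
    stop("duplicate marker accession(s): ",
         paste(unique(names(entries)[duplicated(names(entries))]),
               collapse = ", "))
  bad <- setdiff(unique(entries), taxonomy)
  if (length(bad))
    stop("marker label(s) outside taxonomy: ", paste(bad, collapse = ", "))
  structure(list(entries = entries, taxonomy = taxonomy),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers over %d-class taxonomy\n",
              length(x$entries), length(x$taxonomy)))
  print(table(factor(x$entries, levels = x$taxonomy)))
  invisible(x)
}

#' @export
length.marker_set <- function(x) length(x$entries)

#' Load a marker set from a two-column TSV
#'
#' @param path TSV with columns accession, compartment (header optional:
#'   the first row is taken as a header when its second field is not a
#'   taxonomy label).
#' @param taxonomy compartment taxonomy to validate against.
#' @return a [marker_set()].
#' @examples
#' # a synthetic 720-marker set over the 11-class taxonomy ships with
#' # the package (generator-derived, not a curated biological set)
#' mk <- load_markers(system.file("extdata", "synthetic_markers.tsv",
#'                                package = "spatmap"))
#' print(mk)
#' @export
load_markers <- function(path, taxonomy = default_taxonomy()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.delim(path, header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) stop("empty marker file: ", path))
  if (!nrow(df)) stop("empty marker file: ", path)
  if (ncol(df) < 2) stop("marker file needs two columns")
  if (!df[1, 2] %in% taxonomy && nrow(df) > 1) df <- df[-1, , drop = FALSE]
  if (!nrow(df)) stop("empty marker file: ", path)
  marker_set(stats::setNames(as.character(df[[2]]), as.character(df[[1]])),
             taxonomy = taxonomy)
}

#' Write a marker set to TSV
#' @param markers a [marker_set()].
#' @param path output path.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(
    data.frame(accession = names(markers$entries),
               compartment = unname(markers$entries)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Transfer a marker set to another species via homology hits
#'
#' For each marker, hits with sequence identity at or above
#' `min_identity` are retained and the hit with the lowest e-value is
#' chosen as the homolog (ties broken by input order, with a warning).
#' Markers without a surviving hit are dropped from both outputs, so the
#' target-species set and the filtered source set always have equal
#' size.
#'
#' @param markers source-species [marker_set()].
#' @param hits data frame with columns `query`, `subject`, `identity`
#'   (in `[0,1]`), `e_value` (BLAST outfmt-6 style).
#' @param min_identity identity threshold (default 0.8).
#' @return list with `target` and `source` marker sets.
#' @export
transfer_markers <- function(markers, hits, min_identity = 0.8) {
  stopifnot(inherits(markers, "marker_set"))
  hits <- as.data.frame(hits)
  need <- c("query", "subject", "identity", "e_value")
  if (!all(need %in% names(hits)))
    stop("hits needs columns: ", paste(need, collapse = ", "))
  stopifnot(all(hits$identity >= 0 & hits$identity <= 1),
            all(hits$e_value >= 0))
  hits <- hits[hits$identity >= min_identity &
                 hits$query %in% names(markers$entries), , drop = FALSE]
  tgt <- src <- character(0)
  for (q in names(markers$entries)) {
    hq <- hits[hits$query == q, , drop = FALSE]
    if (!nrow(hq)) next
    best <- which(hq$e_value == min(hq$e_value))
    if (length(best) > 1)
      warning("e-value tie for marker ", q, "; keeping first hit by input order")
    src <- c(src, q)
    tgt <- c(tgt, hq$subject[best[1]])
  }
  if (!length(src)) {
    warning("no markers survived homology transfer")
    empty <- marker_set(stats::setNames(character(0), character(0)),
                        taxonomy = markers$taxonomy)
    return(list(target = empty, source = empty))
  }
  if (anyDuplicated(tgt)) {
    warning("multiple markers map to the same target accession; ",
            "keeping the first by input order")
    keep <- !duplicated(tgt)
    src <- src[keep]
    tgt <- tgt[keep]
  }
  lab <- unname(markers$entries[src])
  list(target = marker_set(stats::setNames(lab, tgt),
                           taxonomy = markers$taxonomy),
       source = marker_set(stats::setNames(lab, src),
                           taxonomy = markers$taxonomy))
}
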