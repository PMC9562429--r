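# Shared internal helpers.

#' Derive a stage-specific seed from a master seed
#'
#' A single pipeline seed is fanned out to independent per-stage seeds by
#' mixing the seed with a stage tag. Keeps all derived seeds in
#' `[1, 2^31 - 2]` so they are valid R integer seeds.
#'
#' @param seed master integer seed.
#' @param tag character tag naming the stage (and, e.g., condition or
#'   replicate) the derived seed is for.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483629  # prime < 2^31
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(paste(tag, collapse = "/"))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Benjamini-Hochberg step-up adjustment (single FDR family).
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
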