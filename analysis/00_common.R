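# Shared setup for the analysis scripts: one benchmark experiment,
# regenerated deterministically by every script.
#
# The benchmark emulates the study design: two cell lines ("A" and "B"),
# three replicate 10-fraction maps each, 3000 proteins with 720 organelle
# markers over the 11-class taxonomy, systematic between-line organelle
# profile shifts, and 12 proteins translocating ER -> PM in line B.

library(spatmap)

SEED <- 2026
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

benchmark_config <- function() {
  simulation_config(
    translocations = data.frame(from = rep("ER", 12), to = rep("PM", 12)),
    seed = SEED)
}

benchmark_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(benchmark_config())
    cache
  }
})

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
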