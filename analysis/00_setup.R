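# Shared setup for the analysis scripts: library, output directory, seed.
# Each numbered script can be run standalone from the repository root:
#   Rscript analysis/01_simulate.R [--seed N]

suppressPackageStartupMessages(library(bathycomp))

cli_seed <- function(default = 42L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- which(args == "--seed")
  if (length(i)) as.integer(args[i + 1]) else default
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}

# The simulated bathytype pair used by every downstream script: genome A
# plays the complete reference (deep bathytype analogue), genome B the
# fragmented draft (shallow bathytype analogue).
study_pair <- function(seed) {
  dir <- results_dir("sim")
  fa <- file.path(dir, sprintf("pair_seed%d_%s.fa", seed, c("A", "B")))
  gff <- file.path(dir, sprintf("pair_seed%d_%s.gff", seed, c("A", "B")))
  sim <- simulate_pair(sim_config(seed = seed))
  write_genome(sim$A, fa[1], gff[1])
  write_genome(sim$B, fa[2], gff[2])
  sim
}
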