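# Shared fixtures, memoised so expensive simulations run once per suite.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# Mid-sized simulated genome pair shared across modules.
sim60 <- function() {
  fixture("sim60", simulate_pair(sim_config(
    n_genes = 60, n_island_genes = 4, n_deletions_per_side = 5,
    n_scaffolds_draft = 5, seed = 42)))
}

# Reference study conditions: the generator defaults.
sim_default <- function() {
  fixture("sim_default", simulate_pair(sim_config(seed = 42)))
}

# Genome with a known mixture of two codon tables (host + island cluster).
usage_mix <- function() {
  fixture("usage_mix", {
    sim <- simulate_pair(sim_config(n_genes = 90, n_island_genes = 10,
                                    n_deletions_per_side = 0,
                                    n_scaffolds_draft = 1, seed = 19))
    list(genes = genome_usage(sim$A), truth = sim$truth)
  })
}

# Homogeneous unevolved genome: every gene drawn straight from the host
# codon table (Ks = 0), for null-behaviour checks.
usage_hom <- function() {
  fixture("usage_hom", {
    sim <- simulate_pair(sim_config(n_genes = 120, n_island_genes = 0,
                                    n_deletions_per_side = 0, target_ks = 0,
                                    n_scaffolds_draft = 1, seed = 23))
    genome_usage(sim$A)
  })
}

# Random CDS of n codons drawn from a codon table (deterministic given seed).
random_cds <- function(n_codons, table = default_host_table(), seed = 1) {
  set.seed(seed)
  body <- sample(names(table), n_codons - 2, replace = TRUE, prob = table)
  paste(c("ATG", body, "TAA"), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
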