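small_cfg <- function(seed = 42, ...) {
  sim_config(n_genes = 30, mean_gene_len = 120, n_island_genes = 3,
             n_deletions_per_side = 3, n_scaffolds_draft = 3, seed = seed, ...)
}

test_that("identical seeds give byte-identical emitted genomes and truth", {
  s1 <- simulate_pair(small_cfg())
  s2 <- simulate_pair(small_cfg())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome(s1$A, file.path(d1, "A.fa"), file.path(d1, "A.gff"))
  write_genome(s2$A, file.path(d2, "A.fa"), file.path(d2, "A.gff"))
  write_genome(s1$B, file.path(d1, "B.fa"), file.path(d1, "B.gff"))
  write_genome(s2$B, file.path(d2, "B.fa"), file.path(d2, "B.gff"))
  for (f in c("A.fa", "A.gff", "B.fa", "B.gff")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(s1$truth$ortholog_map, s2$truth$ortholog_map)

  s3 <- simulate_pair(small_cfg(seed = 43))
  expect_false(identical(as.character(s1$A$scaffolds), as.character(s3$A$scaffolds)))
})

test_that("zero target divergence leaves ortholog gene sequences identical", {
  sim <- simulate_pair(small_cfg(target_ks = 0))
  m <- sim$truth$ortholog_map
  expect_equal(as.character(sim$A$cds[m$gene_a]), unname(as.character(sim$B$cds[m$gene_b])),
               ignore_attr = TRUE)
  expect_equal(m$ks_real, rep(0, nrow(m)))
  expect_equal(sim$truth$ks_median, 0)
})

test_that("emitted coordinates re-extract the simulated CDS and logged events match", {
  sim <- sim60()
  # every annotated CDS translates cleanly (no internal stops, correct strand)
  expect_false(any(is.na(sim$A$protein)))
  expect_false(any(grepl("\\*", sim$A$protein)))
  expect_false(any(is.na(sim$B$protein)))

  # substitution events logged by the simulator equal the differences
  # countable from the emitted sequences on the true (gap-free) alignment,
  # up to multiple hits, which can only reduce visible differences
  m <- sim$truth$ortholog_map
  for (i in c(1, 10, 25)) {
    sa <- as.character(sim$A$cds[[m$gene_a[i]]])
    sb <- as.character(sim$B$cds[[m$gene_b[i]]])
    nt_diffs <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
    logged <- m$n_syn_events[i] + m$n_nonsyn_events[i]
    expect_lte(nt_diffs, logged)
    expect_gte(nt_diffs, 0.8 * logged) # few multiple hits at this divergence
  }
})

test_that("realized synonymous divergence is calibrated to the target", {
  sim <- sim_default()
  expect_equal(nrow(sim$truth$ortholog_map), 160) # 200 - 2*20 deletions
  expect_lt(abs(sim$truth$ks_median - 0.21) / 0.21, 0.15)
  # omega < 1 purifying default: nonsynonymous rate well below synonymous
  expect_lt(stats::median(sim$truth$ortholog_map$ka_real /
                            sim$truth$ortholog_map$ks_real), 0.5)
})

test_that("truth evaluation reports perfect metrics for perfect outputs", {
  sim <- simulate_pair(small_cfg())
  perfect <- list(shared = data.frame(gene_a = sim$truth$ortholog_map$gene_a,
                                      gene_b = sim$truth$ortholog_map$gene_b,
                                      stringsAsFactors = FALSE))
  ev <- truth_eval(sim$truth, orthologs = perfect)
  expect_equal(ev$value[ev$metric == "ortholog_recall"], 1)
  expect_equal(ev$value[ev$metric == "ortholog_precision"], 1)

  sel <- data.frame(gene_a = sim$truth$ortholog_map$gene_a,
                    gene_b = sim$truth$ortholog_map$gene_b,
                    Ks = sim$truth$ortholog_map$ks_real)
  ev2 <- truth_eval(sim$truth, selection = sel)
  expect_equal(ev2$value[ev2$metric == "ks_recovery_relerr"], 0)
  expect_equal(ev2$value[ev2$metric == "tau_ratio"], 1)

  bad <- list(shared = data.frame(gene_a = "Z_0001", gene_b = "B_0001"))
  expect_error(truth_eval(sim$truth, orthologs = bad), "universe")
})
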