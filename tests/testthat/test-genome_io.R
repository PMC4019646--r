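test_that("CDS extraction and translation respect strand and the bacterial code", {
  g <- genome_record("t", c(s1 = "ATGAAATAA"),
                     data.frame(gene_id = "g1", scaffold_id = "s1",
                                start = 1, end = 9, strand = "+"))
  expect_equal(unname(g$protein["g1"]), "MK")

  g2 <- genome_record("t", c(s1 = revcomp("ATGAAATAA")),
                      data.frame(gene_id = "g1", scaffold_id = "s1",
                                 start = 1, end = 9, strand = "-"))
  expect_equal(unname(g2$protein["g1"]), "MK")

  # out-of-bounds coordinates and non-multiple-of-3 CDSs
  expect_error(genome_record("t", c(s1 = "ATGAAATAA"),
                             data.frame(gene_id = "g1", scaffold_id = "s1",
                                        start = 5, end = 20, strand = "+")),
               "bounds")
  g3 <- genome_record("t", c(s1 = "ATGAAATAAC"),
                      data.frame(gene_id = "g1", scaffold_id = "s1",
                                 start = 1, end = 10, strand = "+"))
  expect_true(g3$features$partial[1])
  expect_true(is.na(g3$protein["g1"]))
})

test_that("simulated genomes round-trip through FASTA + GFF3", {
  sim <- sim60()
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "B.fa"); gff <- file.path(dir, "B.gff")
  write_genome(sim$B, fa, gff)
  back <- read_genome(fa, gff, name = "B")
  expect_equal(as.character(back$scaffolds), as.character(sim$B$scaffolds))
  ord <- match(sim$B$features$gene_id, back$features$gene_id)
  expect_false(anyNA(ord))
  expect_equal(back$features$start[ord], sim$B$features$start)
  expect_equal(back$features$end[ord], sim$B$features$end)
  expect_equal(back$features$strand[ord], sim$B$features$strand)
  expect_equal(back$features$category[ord], sim$B$features$category)
  expect_equal(as.character(back$cds)[sim$B$features$gene_id],
               as.character(sim$B$cds)[sim$B$features$gene_id])
})

test_that("genome statistics: GC, intergenic gaps, permutation invariance", {
  expect_equal(genome_stats(genome_record("x", c(a = "ATGC")))$gc_percent, 50)
  # ambiguity codes excluded from GC numerator and denominator
  expect_equal(genome_stats(genome_record("x", c(a = "ATGCNNNN")))$gc_percent, 50)

  g <- genome_record("x", c(s = paste(rep("ACGT", 20), collapse = "")),
                     data.frame(gene_id = c("g1", "g2"), scaffold_id = "s",
                                start = c(1, 21), end = c(10, 30),
                                strand = c("+", "+")))
  expect_equal(genome_stats(g)$mean_intergenic, 10)

  # overlapping genes contribute no gap in skip mode, zero in clip mode
  g2 <- genome_record("x", c(s = paste(rep("ACGT", 20), collapse = "")),
                      data.frame(gene_id = c("g1", "g2", "g3"), scaffold_id = "s",
                                 start = c(1, 8, 21), end = c(10, 12, 30),
                                 strand = "+"))
  expect_equal(genome_stats(g2, intergenic = "skip")$mean_intergenic, 8)
  expect_equal(genome_stats(g2, intergenic = "clip")$mean_intergenic, 4)

  sim <- sim60()
  st <- genome_stats(sim$B)
  perm <- genome_record("B", rev(sim$B$scaffolds), sim$B$features)
  stp <- genome_stats(perm)
  expect_equal(stp$gc_percent, st$gc_percent)
  expect_equal(stp$total_length, st$total_length)
  expect_equal(stp$mean_intergenic, st$mean_intergenic)

  expect_error(genome_stats(genome_record("e", Biostrings::DNAStringSet())), "empty")
})

test_that("global pairwise identity counts gap columns and is symmetric", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  set.seed(7)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  # N never counts as a match
  expect_equal(pairwise_identity("AANA", "AANA"), 75)
})

test_that("pseudomolecule assembly: lengths, spacer joins, unplaced scaffolds", {
  sim <- sim60()
  one <- genome_record("d", sim$B$scaffolds[1])
  ps1 <- build_pseudomolecule(one, sim$A)
  expect_equal(as.character(ps1$sequence), as.character(sim$B$scaffolds[[1]]))

  ps <- build_pseudomolecule(sim$B, sim$A)
  expect_equal(length(ps$sequence),
               sum(Biostrings::width(sim$B$scaffolds)) +
                 34L * (length(sim$B$scaffolds) - 1L))
  expect_equal(sort(ps$offsets$scaffold_id), sort(names(sim$B$scaffolds)))

  # placement matches simulator truth (order and orientation)
  ev <- truth_eval(sim$truth, offsets = ps$offsets)
  expect_equal(ev$value[ev$metric == "scaffold_placement_accuracy"], 1)

  # a scaffold with no homology to the reference is appended unplaced
  set.seed(11)
  junk <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  draft2 <- genome_record("d2", c(sim$B$scaffolds,
                                  Biostrings::DNAStringSet(c(junk = junk))))
  ps2 <- build_pseudomolecule(draft2, sim$A)
  expect_false(ps2$offsets$placed[ps2$offsets$scaffold_id == "junk"])
  expect_equal(ps2$offsets$scaffold_id[nrow(ps2$offsets)], "junk")
})

test_that("every reading frame crossing a spacer junction hits a stop codon", {
  # two 100-bp scaffolds -> 234-bp pseudomolecule
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  s1 <- substr(ref, 1, 100); s2 <- substr(ref, 301, 400)
  draft <- genome_record("d", c(a = s1, b = s2))
  ps <- build_pseudomolecule(draft, genome_record("r", c(chr = ref)),
                             min_anchor_score = 50)
  expect_equal(length(ps$sequence), 234L)

  spacer_start <- 101L
  win <- as.character(Biostrings::DNAString(ps$sequence))
  code <- Biostrings::getGeneticCode("11")
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") win else revcomp(win)
    sp_lo <- if (strand == "+") spacer_start else length(ps$sequence) - (spacer_start + 33L) + 1L
    for (frame in 0:2) {
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(seqs, 1 + frame, nchar(seqs))),
        genetic.code = code, if.fuzzy.codon = "X")))
      stops <- which(strsplit(aa, "")[[1]] == "*")
      codon_starts <- 1 + frame + 3 * (stops - 1)
      in_spacer <- codon_starts >= sp_lo - 2 & codon_starts <= sp_lo + 33
      expect_true(any(in_spacer),
                  info = sprintf("strand %s frame %d", strand, frame))
    }
  }
})
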