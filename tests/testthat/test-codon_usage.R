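test_that("gene usage is family-normalized and scale-invariant", {
  cds <- paste(c("ATG", rep("GGT", 50), "TAA"), collapse = "")
  u <- gene_usage(cds)
  gly <- names(u$families)[u$families == "G"]
  expect_equal(unname(u$freq[gly]),
               as.numeric(gly == "GGT"))
  expect_equal(u$n_codons, 50)

  # concatenation leaves family frequencies unchanged
  cds2 <- random_cds(100, seed = 21)
  u1 <- gene_usage(cds2)
  body <- substr(cds2, 4, nchar(cds2) - 3)
  u2 <- gene_usage(paste0("ATG", body, body, "TAA"))
  expect_equal(u2$freq[!is.na(u1$freq)], u1$freq[!is.na(u1$freq)])

  # initiator and terminal stop excluded; internal stop errors
  expect_error(gene_usage(paste(c("ATG", "TAA", "GGT", "TAA"), collapse = "")),
               "stop")

  # family frequencies sum to 1 for every present family
  for (u in list(u1, u2)) {
    fam_sums <- tapply(u$freq, u$families, sum)
    present <- !is.na(fam_sums)
    expect_true(all(abs(fam_sums[present] - 1) < 1e-9))
  }

  # unevolved simulator genes reproduce the generating table's family
  # frequencies within multinomial error
  tab <- default_host_table()
  fam <- u1$families
  pooled <- usage_from_counts(Reduce(`+`, lapply(usage_hom(), `[[`, "counts")))
  tab_ic <- tab[names(fam)]
  tab_fam <- tab_ic / as.numeric(tapply(tab_ic, fam, sum)[fam])
  ok <- !is.na(pooled$freq)
  expect_lt(max(abs(pooled$freq[ok] - tab_fam[ok])), 0.05)
})

test_that("atypicality: proportional genes score chi2 = 0; calls respect the threshold", {
  mode <- usage_from_counts(stats::setNames(rep(10, 59),
                                            names(gene_usage(random_cds(80))$counts)))
  gene <- usage_from_counts(mode$counts * 3)
  a <- atypicality_test(gene, mode)
  expect_equal(a$chi2, 0)
  expect_equal(a$p, 1)
  expect_false(a$atypical)
  # df: sum over families of (size - 1) when all cells are expected >= 1
  fam_sizes <- table(gene$families)
  expect_equal(a$df, sum(fam_sizes - 1))
})

test_that("modal usage converges on the dominant table and flags the alien genes", {
  mix <- usage_mix()
  scr <- hgt_screen(mix$genes)
  calls <- scr$calls[scr$calls$tested, ]
  island <- calls$gene_id %in% mix$truth$island_genes
  expect_gte(mean(calls$atypical[island]), 0.8)
  expect_lte(mean(calls$atypical[!island]), 0.25)

  # mode is order-invariant
  m1 <- modal_usage(mix$genes)
  m2 <- modal_usage(rev(mix$genes))
  expect_equal(m1$mode$freq, m2$mode$freq)
  expect_equal(m1$n_matching, m2$n_matching)

  # homogeneous genome: all genes drawn from one table, mode ~ pooled usage,
  # false-positive fraction within the chi-square approximation band
  scr2 <- hgt_screen(usage_hom())
  fp <- mean(scr2$calls$atypical[scr2$calls$tested])
  expect_gte(fp, 0.0)
  expect_lte(fp, 0.20)
})

test_that("correspondence analysis: inertia oracle, clustering, row-order invariance", {
  mix <- usage_mix()
  m <- do.call(rbind, lapply(mix$genes, `[[`, "counts"))
  rownames(m) <- names(mix$genes)
  ca <- correspondence_analysis(m)

  # total inertia equals chi-square statistic of the table divided by n
  mm <- m[, colSums(m) > 0]
  n <- sum(mm)
  exp_tab <- outer(rowSums(mm), colSums(mm)) / n
  chi2 <- sum((mm - exp_tab)^2 / exp_tab)
  expect_equal(ca$total_inertia, chi2 / n, tolerance = 1e-8)

  # two codon tables separate on the leading axes
  lab <- as.integer(rownames(m) %in% mix$truth$island_genes) + 1L
  sil <- cluster::silhouette(lab, stats::dist(ca$coords[, 1]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # row coordinates invariant (up to sign) to row order
  perm <- sample(nrow(m))
  ca2 <- correspondence_analysis(m[perm, ])
  for (ax in 1:2) {
    v1 <- ca$coords[rownames(m)[perm], ax]
    v2 <- ca2$coords[, ax]
    expect_true(max(abs(v1 - v2)) < 1e-8 || max(abs(v1 + v2)) < 1e-8)
  }

  # identical rows collapse to the origin
  flat <- matrix(rep(c(3, 5, 2, 7), each = 4), nrow = 4)
  ca3 <- correspondence_analysis(flat)
  expect_lt(max(abs(ca3$coords)), 1e-10)
})
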