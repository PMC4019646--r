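# Test-local oracles, independent of the package internals: synonymous-site
# counting by direct enumeration of the nine single-nucleotide neighbours of
# each codon, and minimal-pathway difference counting.

oracle_code <- function() {
  code <- Biostrings::getGeneticCode("11")
  stats::setNames(as.character(code), names(code))
}

oracle_syn_sites <- function(codons) {
  code <- oracle_code()
  nt <- c("A", "C", "G", "T")
  stops <- names(code)[code == "*"]
  sum(vapply(codons, function(cd) {
    b <- strsplit(cd, "")[[1]]
    s <- 0
    for (p in 1:3) {
      neigh <- vapply(setdiff(nt, b[p]), function(x) {
        nb <- b; nb[p] <- x; paste(nb, collapse = "")
      }, character(1))
      neigh <- neigh[!neigh %in% stops]
      if (length(neigh)) s <- s + mean(code[neigh] == code[cd])
    }
    s
  }, numeric(1)))
}

# average sd/nd over minimal stop-free pathways between two codons
oracle_path_counts <- function(c1, c2) {
  code <- oracle_code()
  stops <- names(code)[code == "*"]
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  if (!length(dpos)) return(c(sd = 0, nd = 0))
  perms <- if (length(dpos) == 1) list(dpos) else
    unlist(lapply(combinat_perms(dpos), list), recursive = FALSE)
  paths <- list()
  for (ord in perms) {
    cur <- b1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- b2[p]
      now <- paste(cur, collapse = "")
      if (now %in% stops && now != c2) { ok <- FALSE; break }
      if (code[prev] == code[now]) sd <- sd + 1 else nd <- nd + 1
    }
    if (ok) paths[[length(paths) + 1]] <- c(sd = sd, nd = nd)
  }
  if (!length(paths)) { # every path blocked: fall back to unfiltered paths
    for (ord in perms) {
      cur <- b1; sd <- 0; nd <- 0
      for (p in ord) {
        prev <- paste(cur, collapse = "")
        cur[p] <- b2[p]
        if (code[prev] == code[paste(cur, collapse = "")]) sd <- sd + 1 else nd <- nd + 1
      }
      paths[[length(paths) + 1]] <- c(sd = sd, nd = nd)
    }
  }
  colMeans(do.call(rbind, paths))
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

make_aln <- function(cds_a, cds_b) codon_align(cds_a, cds_b)

test_that("codon alignment maps the protein alignment back to intact codon pairs", {
  cds <- random_cds(40, seed = 2)
  aln <- make_aln(cds, cds)
  expect_equal(aln$n_codons, 39) # terminal stop dropped
  expect_equal(aln$codons_a, aln$codons_b)

  # a 3-bp deletion removes exactly one codon column
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  del <- paste(codons[-20], collapse = "")
  aln2 <- make_aln(cds, del)
  expect_equal(aln2$n_codons, 38)
  expect_equal(sum(aln2$codons_a != aln2$codons_b), 0)

  # ambiguous codons are dropped
  amb <- cds
  substr(amb, 10, 10) <- "N"
  aln3 <- make_aln(cds, amb)
  expect_equal(aln3$n_codons, 38)
})

test_that("NG86 matches enumeration and pathway oracles", {
  cds <- random_cds(40, seed = 5)
  aln <- make_aln(cds, cds)
  r0 <- kaks_ng86(aln)
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_equal(r0$S + r0$N, 3 * aln$n_codons)

  # 30 codons with exactly two synonymous third-position changes
  codons <- rep("GGC", 32) # Gly, fourfold degenerate
  codons[1] <- "ATG"; codons[32] <- "TAA"
  mut <- codons
  mut[5] <- "GGT"; mut[20] <- "GGA"
  a <- paste(codons, collapse = ""); b <- paste(mut, collapse = "")
  aln2 <- make_aln(a, b)
  r <- kaks_ng86(aln2)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$Sd, 2)
  S_oracle <- (oracle_syn_sites(aln2$codons_a) + oracle_syn_sites(aln2$codons_b)) / 2
  expect_equal(r$S, S_oracle)
  expect_equal(r$Ks, -0.75 * log(1 - 4 * (2 / S_oracle) / 3))

  # pathway counts: Sd + Nd equals the average minimal-path difference count
  set.seed(8)
  for (rep in 1:5) {
    ca <- random_cds(20, seed = 100 + rep)
    sim <- simulate_pair(sim_config(n_genes = 1, mean_gene_len = 60,
                                    target_ks = 0.4, n_island_genes = 0,
                                    n_deletions_per_side = 0,
                                    n_scaffolds_draft = 1, seed = 200 + rep))
    aln3 <- make_aln(sim$A$cds[[1]], sim$B$cds[[1]])
    r3 <- kaks_ng86(aln3)
    oracle <- colSums(do.call(rbind, Map(function(x, y) {
      if (x == y) c(sd = 0, nd = 0) else oracle_path_counts(x, y)
    }, aln3$codons_a, aln3$codons_b)))
    expect_equal(r3$Sd + r3$Nd, sum(oracle))
    expect_equal(r3$Sd, oracle[["sd"]], tolerance = 1e-9)
  }
})

test_that("YN00 reduces to NG86 under uniform usage and kappa 1, and recovers omega", {
  uni <- stats::setNames(rep(1 / 61, 61), setdiff(names(oracle_code()),
                                                  c("TAA", "TAG", "TGA")))
  sim <- simulate_pair(sim_config(n_genes = 10, mean_gene_len = 500,
                                  target_ks = 0.2, kappa = 1,
                                  host_codon_table = uni,
                                  omega_per_gene = 0.3,
                                  n_island_genes = 0, n_deletions_per_side = 0,
                                  n_scaffolds_draft = 1, seed = 31))
  for (i in c(1, 5, 10)) {
    aln <- make_aln(sim$A$cds[[sprintf("A_%04d", i)]],
                    sim$B$cds[[sprintf("B_%04d", i)]])
    ng <- kaks_ng86(aln)
    yn_fixed <- kaks_yn00(aln, kappa = 1)
    expect_lt(abs(yn_fixed$S - ng$S) / ng$S, 0.02)
    expect_lt(abs(yn_fixed$N - ng$N) / ng$N, 0.02)
    # with estimated kappa, rates still agree within 20% at this divergence
    yn <- kaks_yn00(aln)
    expect_lt(abs(yn$Ka - ng$Ka) / max(ng$Ka, 1e-6), 0.2)
    expect_lt(abs(yn$Ks - ng$Ks) / ng$Ks, 0.2)
  }

  # identical sequences
  cds <- random_cds(60, seed = 3)
  r <- kaks_yn00(make_aln(cds, cds))
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)

  # omega recovery: true omega 0.2, Ks ~ 0.2, 500 codons
  sim2 <- fixture("omega02", simulate_pair(sim_config(
    n_genes = 100, mean_gene_len = 500, target_ks = 0.2,
    omega_per_gene = 0.2, n_island_genes = 0, n_deletions_per_side = 0,
    n_scaffolds_draft = 1, seed = 13)))
  om <- vapply(seq_len(100), function(i) {
    aln <- make_aln(sim2$A$cds[[sprintf("A_%04d", i)]],
                    sim2$B$cds[[sprintf("B_%04d", i)]])
    kaks_yn00(aln)$omega
  }, numeric(1))
  expect_gt(stats::median(om, na.rm = TRUE), 0.15)
  expect_lt(stats::median(om, na.rm = TRUE), 0.25)
})

test_that("Fisher screen matches direct hypergeometric enumeration", {
  # equal proportions -> no association
  expect_equal(omega_significance(list(S = 100, Sd = 10, N = 900, Nd = 90)), 1,
               tolerance = 0.05)

  # oracle: two-sided exact probability by summing the hypergeometric tail
  tab <- c(Sd = 10, Srest = 90, Nd = 1, Nrest = 899)
  p_pkg <- omega_significance(list(S = 100, Sd = 10, N = 900, Nd = 1))
  m <- tab["Sd"] + tab["Srest"]; nn <- tab["Nd"] + tab["Nrest"]
  k <- tab["Sd"] + tab["Nd"]
  probs <- stats::dhyper(0:k, m, nn, k)
  p_oracle <- sum(probs[probs <= stats::dhyper(tab[["Sd"]], m, nn, k) * (1 + 1e-7)])
  expect_equal(p_pkg, p_oracle, tolerance = 1e-8)

  expect_error(omega_significance(list(S = 10, Sd = 12, N = 10, Nd = 0)), "negative")
})

test_that("divergence dating inverts the clock formula and ignores saturated pairs", {
  expect_equal(divergence_time(0)$tau, 0)

  est <- divergence_time(0.210543, lambda = 8.3e-7)
  expect_equal(round(est$tau), 126833)

  expect_equal(divergence_time(c(0.1, 0.2, 0.3), lambda = 2 * 8.3e-7)$tau,
               divergence_time(c(0.1, 0.2, 0.3), lambda = 8.3e-7)$tau / 2)

  ks <- c(0.2, 0.1, 0.3, NA, Inf)
  expect_equal(divergence_time(ks)$tau, divergence_time(c(0.3, 0.2, 0.1))$tau)
  expect_equal(divergence_time(ks)$n_pairs, 3)
  expect_error(divergence_time(c(NA_real_)), "no finite")
  expect_error(divergence_time(0.1, lambda = 0), "positive")
})
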