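# Synthetic genome-pair generator with ground truth.  An ancestor genome of
# protein-coding genes is drawn from a host codon-usage table; two
# descendants evolve independently under a selection-filtered HKY codon
# process (synonymous changes always accepted, nonsynonymous accepted with
# probability omega, stops rejected) calibrated so the expected pairwise Ks
# matches a target; one genome receives a contiguous cluster of
# alien-codon-usage genes (HGT island), both lose random genes, and the
# second genome is fragmented into randomly oriented draft scaffolds.

#' Default host codon-usage table (GC-rich third positions)
#'
#' Named weights over the 61 sense codons with a moderate preference for G/C
#' in the wobble position, emulating a genome with a distinct translational
#' signature.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_host_table <- function() .biased_codon_table(gc3 = 0.72)

#' Default HGT-island codon-usage table (AT-rich third positions)
#'
#' Strongly AT-biased wobble positions, divergent from
#' [default_host_table()], emulating genes acquired from a donor with a
#' different compositional signature.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_island_table <- function() .biased_codon_table(gc3 = 0.14)

#' @noRd
.biased_codon_table <- function(gc3) {
  sense <- .sense_codons()
  w3 <- ifelse(substr(sense, 3, 3) %in% c("G", "C"), gc3 / 2, (1 - gc3) / 2)
  w <- w3
  names(w) <- sense
  w / sum(w)
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 200 genes of ~300 codons, intergenic spacers averaging 167 bp
#' (matching the intergenic scale of the shallow bathytype), pairwise median
#' Ks targeted at 0.21 (the divergence regime of the bathytype pair),
#' per-gene omega log-normally distributed around 0.1 (typical purifying
#' selection within a species), transition/transversion ratio kappa = 2, a
#' 10-gene HGT island, 20 gene deletions per side, and an 11-scaffold draft
#' fragmentation (the draft genome in the study has 11 scaffolds).
#'
#' @param n_genes Ancestral gene count.
#' @param mean_gene_len Mean gene length in codons (Poisson, floor 60).
#' @param intergenic_mean Mean intergenic spacer length in bp (geometric).
#' @param target_ks Expected pairwise synonymous divergence.
#' @param omega_per_gene Per-gene omega: numeric vector (recycled), a
#'   function of n, or `NULL` for the default log-normal.
#' @param kappa Transition/transversion rate ratio of the mutation process.
#' @param host_codon_table,island_codon_table Named codon weights over the
#'   61 sense codons.
#' @param n_island_genes Genes in the implanted island cluster (genome A).
#' @param n_deletions_per_side Genes deleted from each descendant.
#' @param n_scaffolds_draft Scaffolds to fragment genome B into.
#' @param seed Random seed (mandatory).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 200, mean_gene_len = 300, intergenic_mean = 167,
                       target_ks = 0.21, omega_per_gene = NULL, kappa = 2,
                       host_codon_table = default_host_table(),
                       island_codon_table = default_island_table(),
                       n_island_genes = 10, n_deletions_per_side = 20,
                       n_scaffolds_draft = 11, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(target_ks >= 0, n_genes > 0, mean_gene_len >= 60, kappa > 0,
            n_scaffolds_draft >= 1,
            n_deletions_per_side * 2 + n_island_genes < n_genes)
  structure(list(n_genes = n_genes, mean_gene_len = mean_gene_len,
                 intergenic_mean = intergenic_mean, target_ks = target_ks,
                 omega_per_gene = omega_per_gene, kappa = kappa,
                 host_codon_table = host_codon_table,
                 island_codon_table = island_codon_table,
                 n_island_genes = n_island_genes,
                 n_deletions_per_side = n_deletions_per_side,
                 n_scaffolds_draft = n_scaffolds_draft, seed = seed),
            class = "SimConfig")
}

#' @noRd
.draw_gene <- function(n_codons, table) {
  body <- sample(names(table), n_codons - 2L, replace = TRUE, prob = table)
  stop <- sample(c("TAA", "TGA", "TAG"), 1, prob = c(0.6, 0.3, 0.1))
  c("ATG", body, stop)
}

# One branch of selection-filtered HKY evolution over the internal codons
# (start and stop are held fixed).  `lambda` is the expected number of
# proposal events per nucleotide position.
#' @noRd
.evolve_codons <- function(codons, omega, kappa, lambda) {
  code <- .genetic_code()
  stops <- .stop_codons()
  inner <- codons[-c(1L, length(codons))]
  L3 <- 3L * length(inner)
  n_ev <- stats::rpois(1, L3 * lambda)
  n_syn <- 0L; n_non <- 0L
  if (n_ev > 0) {
    pos <- sample.int(L3, n_ev, replace = TRUE)
    for (e in seq_len(n_ev)) {
      ci <- (pos[e] - 1L) %/% 3L + 1L
      off <- (pos[e] - 1L) %% 3L + 1L
      cod <- inner[ci]
      cur <- substr(cod, off, off)
      alts <- .NT[.NT != cur]
      to <- sample(alts, 1, prob = ifelse(.is_transition(cur, alts), kappa, 1))
      newcod <- cod
      substr(newcod, off, off) <- to
      if (newcod %in% stops) next
      if (code[[newcod]] == code[[cod]]) {
        inner[ci] <- newcod; n_syn <- n_syn + 1L
      } else if (stats::runif(1) < omega) {
        inner[ci] <- newcod; n_non <- n_non + 1L
      }
    }
  }
  list(codons = c(codons[1L], inner, codons[length(codons)]),
       n_syn = n_syn, n_non = n_non)
}

# Calibrate the per-position proposal intensity so that the expected
# NG86-measured synonymous divergence per branch equals `ks_branch`.
# With f_s the expected accepted-synonymous fraction per proposal under the
# ancestral codon distribution and s_pos the mean synonymous sites per
# nucleotide position (NG86 counting), lambda = ks_branch * s_pos / f_s.
#' @noRd
.calibrate_rate <- function(codon_freq, kappa, ks_branch) {
  code <- .genetic_code()
  stops <- .stop_codons()
  sites <- .codon_syn_sites(kappa = 1)
  f_s <- 0; s_pos <- 0
  for (cd in names(codon_freq)) {
    nb <- .codon_neighbors(cd)
    w <- ifelse(nb$ts, kappa, 1)
    syn <- code[nb$codon] == code[[cd]] & !(nb$codon %in% stops)
    f_s <- f_s + codon_freq[[cd]] * sum(w[syn]) / (kappa + 2) / 3
    s_pos <- s_pos + codon_freq[[cd]] * sites[[cd]] / 3
  }
  ks_branch * s_pos / f_s
}

# NG86 counting on the true (gap-free) codon alignment of a gene pair.
#' @noRd
.ng86_truth <- function(ca, cb) {
  sites <- .codon_syn_sites(kappa = 1)
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  tabs <- .pair_diff_tables()
  idx <- cbind(ca, cb)
  c(ks = .jc_correct(sum(tabs$sd[idx]) / S),
    ka = .jc_correct(sum(tabs$nd[idx]) / N))
}

.COG_LETTERS <- c("C", "E", "G", "J", "K", "L", "M", "N", "O", "P", "T")

#' Simulate an annotated genome pair with ground truth
#'
#' See [sim_config()] for the model.  Genome A is a single complete
#' "reference" molecule carrying the HGT island; genome B is a draft
#' fragmented into randomly oriented scaffolds.  Genes sit on random strands
#' separated by geometric intergenic spacers; scaffold breakpoints fall in
#' intergenic regions.
#'
#' @param cfg A [sim_config()].
#' @return A list: `A`, `B` ([genome_record()]s) and `truth`, a list with
#'   `ortholog_map` (`gene_a`, `gene_b`, `omega_true`, `ks_real`, `ka_real`,
#'   `n_syn_events`, `n_nonsyn_events`), `island_genes`, `deleted_from_a`,
#'   `deleted_from_b`, `scaffolds` (draft fragmentation: id, rank, flipped),
#'   and the realized `ks_median`.
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  lens <- pmax(60L, stats::rpois(n, cfg$mean_gene_len))
  anc <- lapply(lens, .draw_gene, table = cfg$host_codon_table)
  omega <- cfg$omega_per_gene
  if (is.null(omega)) omega <- stats::rlnorm(n, log(0.1), 0.5)
  if (is.function(omega)) omega <- omega(n)
  omega <- rep_len(omega, n)
  freq <- table(unlist(lapply(anc, function(cd) cd[-c(1, length(cd))])))
  freq <- freq / sum(freq)
  lambda <- if (cfg$target_ks > 0) {
    .calibrate_rate(freq, cfg$kappa, cfg$target_ks / 2)
  } else 0
  ga <- gb <- vector("list", n)
  ev <- matrix(0L, nrow = n, ncol = 4,
               dimnames = list(NULL, c("syn_a", "non_a", "syn_b", "non_b")))
  for (i in seq_len(n)) {
    ra <- .evolve_codons(anc[[i]], omega[i], cfg$kappa, lambda)
    rb <- .evolve_codons(anc[[i]], omega[i], cfg$kappa, lambda)
    ga[[i]] <- ra$codons
    gb[[i]] <- rb$codons
    ev[i, ] <- c(ra$n_syn, ra$n_non, rb$n_syn, rb$n_non)
  }
  del_pool <- sample.int(n, 2 * cfg$n_deletions_per_side)
  del_a <- sort(del_pool[seq_len(cfg$n_deletions_per_side)])
  del_b <- sort(del_pool[-seq_len(cfg$n_deletions_per_side)])
  categories <- sample(.COG_LETTERS, n, replace = TRUE)
  ids_a <- sprintf("A_%04d", seq_len(n))
  ids_b <- sprintf("B_%04d", seq_len(n))

  # truth for surviving ortholog pairs
  both <- setdiff(seq_len(n), c(del_a, del_b))
  kk <- t(vapply(both, function(i) {
    .ng86_truth(ga[[i]][-c(1, lens[i])], gb[[i]][-c(1, lens[i])])
  }, numeric(2)))
  ortholog_map <- data.frame(
    gene_a = ids_a[both], gene_b = ids_b[both], omega_true = omega[both],
    ks_real = kk[, "ks"], ka_real = kk[, "ka"],
    n_syn_events = ev[both, "syn_a"] + ev[both, "syn_b"],
    n_nonsyn_events = ev[both, "non_a"] + ev[both, "non_b"],
    stringsAsFactors = FALSE)

  # ancestral layout, inherited by both descendants: strand per gene and
  # the intergenic spacer following each gene (spacers diverge neutrally)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  rand_seq <- function(len) paste(sample(.NT, len, replace = TRUE), collapse = "")
  spacer_len <- stats::rgeom(n + 1, 1 / cfg$intergenic_mean) + 5L
  anc_lead <- rand_seq(spacer_len[1])
  anc_spacers <- vapply(spacer_len[-1], rand_seq, character(1))
  tdiv <- cfg$target_ks / 2
  lead_a <- .mutate_seq(anc_lead, tdiv)
  lead_b <- .mutate_seq(anc_lead, tdiv)
  spac_a <- vapply(anc_spacers, .mutate_seq, character(1), t = tdiv)
  spac_b <- vapply(anc_spacers, .mutate_seq, character(1), t = tdiv)

  # island genes implanted into A as one contiguous cluster
  isl <- list()
  if (cfg$n_island_genes > 0) {
    il <- pmax(60L, stats::rpois(cfg$n_island_genes, cfg$mean_gene_len))
    isl <- lapply(il, .draw_gene, table = cfg$island_codon_table)
  }
  island_ids <- if (length(isl)) sprintf("A_hgt%02d", seq_along(isl)) else character(0)
  isl_strands <- sample(c("+", "-"), length(isl), replace = TRUE)
  isl_spacers <- vapply(stats::rgeom(length(isl), 1 / cfg$intergenic_mean) + 5L,
                        rand_seq, character(1))

  keep_a <- setdiff(seq_len(n), del_a)
  keep_b <- setdiff(seq_len(n), del_b)
  slot <- if (length(isl)) sample.int(length(keep_a) - 1, 1) else length(keep_a)
  idx1 <- keep_a[seq_len(slot)]
  idx2 <- if (slot < length(keep_a)) keep_a[(slot + 1):length(keep_a)] else integer(0)
  A <- .layout_genome("A", "A_chr",
                      c(ids_a[idx1], island_ids, ids_a[idx2]),
                      c(lapply(idx1, function(i) ga[[i]]), isl,
                        lapply(idx2, function(i) ga[[i]])),
                      c(categories[idx1],
                        sample(.COG_LETTERS, length(isl), replace = TRUE),
                        categories[idx2]),
                      c(strands[idx1], isl_strands, strands[idx2]),
                      lead_a,
                      c(spac_a[idx1], isl_spacers, spac_a[idx2]))

  # draft genome B: fragment gene list into scaffolds, flip some
  nb <- length(keep_b)
  ns <- min(cfg$n_scaffolds_draft, nb)
  cuts <- if (ns > 1) sort(sample(seq_len(nb - 1), ns - 1)) else integer(0)
  bounds <- cbind(c(1, cuts + 1), c(cuts, nb))
  scaf_order <- sample.int(ns) # emitted order is shuffled
  flipped <- stats::runif(ns) < 0.5
  b_scafs <- list(); b_feats <- list()
  for (k in seq_len(ns)) {
    r <- scaf_order[k]
    idx <- keep_b[bounds[r, 1]:bounds[r, 2]]
    sid <- sprintf("B_s%02d", k)
    gr <- .layout_genome("tmp", sid, ids_b[idx],
                         lapply(idx, function(i) gb[[i]]), categories[idx],
                         strands[idx],
                         if (bounds[r, 1] == 1) lead_b else "",
                         spac_b[idx])
    if (flipped[r]) gr <- .flip_scaffold(gr, sid)
    b_scafs[[sid]] <- gr$scaffolds[[sid]]
    b_feats[[sid]] <- gr$features
  }
  B <- genome_record("B", Biostrings::DNAStringSet(b_scafs), do.call(rbind, b_feats))
  truth <- list(
    ortholog_map = ortholog_map,
    island_genes = island_ids,
    deleted_from_a = ids_b[del_a],  # still present in B, unique to B
    deleted_from_b = ids_a[del_b],  # still present in A, unique to A
    scaffolds = data.frame(scaffold_id = sprintf("B_s%02d", seq_len(ns)),
                           first_gene = bounds[scaf_order, 1],
                           flipped = flipped[scaf_order],
                           stringsAsFactors = FALSE),
    ks_median = stats::median(ortholog_map$ks_real),
    lambda_events_per_site = lambda,
    config = cfg)
  truth$scaffolds$rank <- rank(truth$scaffolds$first_gene)
  list(A = A, B = B, truth = truth)
}

# Lay genes (codon lists) onto one scaffold.  `strands` and `spacers` are
# inherited from the ancestor: spacers[[i]] is the intergenic sequence
# following gene i, with a leading spacer prepended.
#' @noRd
.layout_genome <- function(name, scaffold_id, ids, codon_lists, cats,
                           strands, lead_spacer, spacers) {
  pieces <- character(2 * length(ids) + 1)
  pieces[1] <- lead_spacer
  feats <- vector("list", length(ids))
  pos <- nchar(pieces[1]) + 1L
  for (i in seq_along(ids)) {
    s <- paste(codon_lists[[i]], collapse = "")
    if (strands[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    pieces[2 * i] <- s
    feats[[i]] <- data.frame(gene_id = ids[i], scaffold_id = scaffold_id,
                             start = pos, end = pos + nchar(s) - 1L,
                             strand = strands[i], category = cats[i],
                             stringsAsFactors = FALSE)
    pieces[2 * i + 1] <- spacers[[i]]
    pos <- pos + nchar(s) + nchar(spacers[[i]])
  }
  seqs <- Biostrings::DNAStringSet(stats::setNames(paste(pieces, collapse = ""),
                                                   scaffold_id))
  genome_record(name, seqs, do.call(rbind, feats))
}

# Neutral per-site substitutions on a plain nucleotide string: expected
# t substitutions/site, multiple hits allowed (Jukes-Cantor-like).
#' @noRd
.mutate_seq <- function(seq, t) {
  if (t <= 0 || nchar(seq) == 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  x <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(x)) < p)
  for (i in hit) x[i] <- sample(.NT[.NT != x[i]], 1)
  paste(x, collapse = "")
}

# Reverse-complement a one-scaffold genome, remapping feature coordinates.
#' @noRd
.flip_scaffold <- function(g, sid) {
  len <- Biostrings::width(g$scaffolds)[1]
  seqs <- Biostrings::DNAStringSet(stats::setNames(
    as.character(Biostrings::reverseComplement(g$scaffolds[[1]])), sid))
  f <- g$features
  new_start <- len - f$end + 1L
  new_end <- len - f$start + 1L
  f$start <- new_start
  f$end <- new_end
  f$strand <- ifelse(f$strand == "+", "-", "+")
  genome_record(g$name, seqs, f)
}

#' Simulate a nucleotide-divergent genome pair (no indels)
#'
#' A random genome and a copy with a fixed fraction of sites substituted
#' uniformly at random (each mutated site changed to one of the three other
#' bases), giving a pair with known per-column identity; used to validate
#' the ANI engine.
#'
#' @param genome_length Length in bp.
#' @param divergence Per-site substitution fraction.
#' @param seed Random seed.
#' @param gc GC content of the ancestor.
#' @return A list: `A`, `B` ([genome_record()]s), `n_substituted`.
#' @export
simulate_nucleotide_pair <- function(genome_length, divergence, seed, gc = 0.45) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  a <- sample(.NT, genome_length, replace = TRUE, prob = p[.NT])
  b <- a
  k <- round(divergence * genome_length)
  idx <- sample.int(genome_length, k)
  for (i in idx) b[i] <- sample(.NT[.NT != b[i]], 1)
  list(A = genome_record("simA", stats::setNames(paste(a, collapse = ""), "chr")),
       B = genome_record("simB", stats::setNames(paste(b, collapse = ""), "chr")),
       n_substituted = k)
}

#' Evaluate pipeline outputs against simulator truth
#'
#' Compares any subset of pipeline outputs with the ground truth of
#' [simulate_pair()] and returns a metrics table.
#'
#' @param truth The `truth` element of a [simulate_pair()] result.
#' @param orthologs Optional [reciprocal_orthologs()] result.
#' @param selection Optional [selection_screen()] table (adds Ks/tau
#'   recovery metrics).
#' @param hgt_calls Optional [hgt_screen()] `calls` table for genome A
#'   (adds island sensitivity/specificity over tested genes).
#' @param offsets Optional [build_pseudomolecule()] `offsets` table for the
#'   draft genome (adds scaffold placement accuracy).
#' @param lambda Clock rate for tau recovery.
#' @return A data.frame with columns `metric` and `value`.
#' @export
truth_eval <- function(truth, orthologs = NULL, selection = NULL,
                       hgt_calls = NULL, offsets = NULL,
                       lambda = DEFAULT_CLOCK_RATE) {
  out <- list()
  add <- function(metric, value) {
    out[[length(out) + 1L]] <<- data.frame(metric = metric, value = value,
                                           stringsAsFactors = FALSE)
  }
  if (!is.null(orthologs)) {
    true_pairs <- paste(truth$ortholog_map$gene_a, truth$ortholog_map$gene_b)
    got <- paste(orthologs$shared$gene_a, orthologs$shared$gene_b)
    if (!all(orthologs$shared$gene_a %in% c(truth$ortholog_map$gene_a,
                                            truth$island_genes,
                                            truth$deleted_from_b))) {
      stop("ortholog table references genes outside the simulated universe")
    }
    add("ortholog_recall", mean(true_pairs %in% got))
    add("ortholog_precision", if (length(got)) mean(got %in% true_pairs) else NA_real_)
  }
  if (!is.null(selection)) {
    m <- merge(selection, truth$ortholog_map,
               by = c("gene_a", "gene_b"))
    est <- stats::median(m$Ks[is.finite(m$Ks)])
    add("ks_median_estimated", est)
    add("ks_median_true", truth$ks_median)
    add("ks_recovery_relerr", abs(est - truth$ks_median) / truth$ks_median)
    add("tau_ratio", divergence_time(m$Ks, lambda)$tau /
          divergence_time(truth$ortholog_map$ks_real, lambda)$tau)
  }
  if (!is.null(hgt_calls)) {
    calls <- hgt_calls[hgt_calls$tested, , drop = FALSE]
    is_island <- calls$gene_id %in% truth$island_genes
    if (any(is_island)) add("island_sensitivity", mean(calls$atypical[is_island]))
    add("island_specificity", mean(!calls$atypical[!is_island]))
  }
  if (!is.null(offsets)) {
    placed <- offsets[offsets$placed, , drop = FALSE]
    tr <- truth$scaffolds
    m <- merge(placed, tr, by = "scaffold_id")
    ok_orient <- m$orientation == ifelse(m$flipped, "-", "+")
    placed_rank <- rank(match(m$scaffold_id, offsets$scaffold_id))
    ok_order <- placed_rank == rank(m$rank)
    add("scaffold_placement_accuracy",
        sum(ok_orient & ok_order) / nrow(tr))
  }
  do.call(rbind, out)
}
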