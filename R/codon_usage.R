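# Per-gene codon-usage signatures, genome-wide modal codon usage, chi-square
# atypicality calls for horizontal-transfer detection, and correspondence
# analysis of the gene x codon usage matrix.

# The 59 informative codons: 61 sense codons minus the single-codon families
# ATG (Met) and TGG (Trp).
#' @noRd
.informative_codons <- function() {
  setdiff(.sense_codons(), c("ATG", "TGG"))
}

# amino-acid family of each informative codon
#' @noRd
.codon_families <- function() {
  code <- .genetic_code()
  ic <- .informative_codons()
  stats::setNames(unname(code[ic]), ic)
}

#' Codon-usage vector of one gene
#'
#' Counts codons over the CDS excluding the initiator codon and the terminal
#' stop, restricted to the 59 informative codons (sense codons minus ATG and
#' TGG), and normalizes the counts within each synonymous (amino-acid)
#' family.
#'
#' @param cds Nucleotide CDS (length divisible by 3).
#' @param gene_id Optional label carried through to calls.
#' @return A list of class `CodonUsageVector`: `counts` (named over the 59
#'   codons), `freq` (family-normalized, `NA` for absent families),
#'   `n_codons` (informative codons counted), `gene_id`.
#' @export
gene_usage <- function(cds, gene_id = NA_character_) {
  codons <- .split_codons(cds)
  codons <- .strip_stop(codons)
  if (any(codons %in% .stop_codons())) stop("internal stop codon")
  if (length(codons) > 1) codons <- codons[-1] # drop initiator
  ic <- .informative_codons()
  counts <- table(factor(codons[codons %in% ic], levels = ic))
  counts <- stats::setNames(as.numeric(counts), ic)
  usage_from_counts(counts, gene_id = gene_id)
}

#' Build a codon-usage vector from raw counts
#'
#' @param counts Named numeric vector of counts over the 59 informative
#'   codons (missing codons treated as 0).
#' @param gene_id Optional label.
#' @return A `CodonUsageVector`.
#' @export
usage_from_counts <- function(counts, gene_id = NA_character_) {
  ic <- .informative_codons()
  full <- stats::setNames(numeric(length(ic)), ic)
  full[names(counts)] <- counts
  fam <- .codon_families()
  fam_tot <- tapply(full, fam, sum)
  freq <- full / as.numeric(fam_tot[fam])
  freq[!is.finite(freq)] <- NA_real_
  structure(list(counts = full, freq = freq, n_codons = sum(full),
                 gene_id = gene_id, families = fam),
            class = "CodonUsageVector")
}

#' Chi-square atypicality of a gene against a reference usage
#'
#' Expected codon counts are the gene's per-family totals spread according
#' to the reference (modal) family frequencies.  The chi-square statistic is
#' summed over codons with positive expectation; within each family, cells
#' with expected count < 1 are pooled into the family's largest cell
#' (disable with `pool_small = FALSE`).  Degrees of freedom are the number
#' of retained cells minus the number of contributing families.  A gene is
#' atypical when p < `p_threshold`.
#'
#' @param gene,mode `CodonUsageVector`s (gene and genome-wide mode).
#' @param p_threshold Atypicality p-value threshold (default 0.1).
#' @param pool_small Pool expected cells < 1 into the family's largest cell.
#' @return A list of class `AtypicalityCall`: `gene_id`, `chi2`, `df`, `p`,
#'   `atypical`, `tested` (FALSE for genes under 60 informative codons,
#'   which are computed but flagged untested).
#' @export
atypicality_test <- function(gene, mode, p_threshold = 0.1, pool_small = TRUE) {
  fam <- gene$families
  chi2 <- 0
  df <- 0L
  for (f in unique(fam)) {
    idx <- names(fam)[fam == f]
    tot <- sum(gene$counts[idx])
    if (tot == 0) next
    mfreq <- mode$freq[idx]
    if (all(is.na(mfreq))) next # mode family absent: skipped, df unchanged
    mfreq[is.na(mfreq)] <- 0
    exp <- tot * mfreq
    obs <- gene$counts[idx]
    if (pool_small && any(exp < 1) && any(exp >= 1)) {
      big <- which.max(exp)
      small <- which(exp < 1)
      small <- setdiff(small, big)
      if (length(small)) {
        exp[big] <- exp[big] + sum(exp[small])
        obs[big] <- obs[big] + sum(obs[small])
        exp <- exp[-small]
        obs <- obs[-small]
      }
    }
    keep <- exp > 0
    exp <- exp[keep]; obs <- obs[keep]
    if (length(exp) < 2) next
    chi2 <- chi2 + sum((obs - exp)^2 / exp)
    df <- df + length(exp) - 1L
  }
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else 1
  structure(list(gene_id = gene$gene_id, chi2 = chi2, df = df, p = p,
                 atypical = p < p_threshold, tested = gene$n_codons >= 60),
            class = "AtypicalityCall")
}

#' Genome-wide modal codon usage
#'
#' Deterministic fixed-point search for the codon usage matched by the
#' largest number of genes: start from the pooled-count usage of all genes,
#' then repeatedly recompute the pooled usage over only the genes that match
#' the current mode (chi-square p >= `p_threshold`), until the matching set
#' is stable, revisits an earlier state, or `max_iter` is reached.  The
#' usage maximizing the number of matching genes seen during the iteration
#' is returned.
#'
#' @param genes List of `CodonUsageVector`s (genes under 60 informative
#'   codons are excluded from the fit).
#' @param p_threshold Match threshold (default 0.1).
#' @param max_iter Iteration cap.
#' @return A list of class `ModalUsage`: `mode` (a `CodonUsageVector`),
#'   `n_matching`, `converged`, `iterations`.
#' @export
modal_usage <- function(genes, p_threshold = 0.1, max_iter = 100) {
  eligible <- Filter(function(g) g$n_codons >= 60, genes)
  if (length(eligible) < 20) stop("need at least 20 eligible genes (>= 60 codons)")
  pooled <- function(gs) {
    usage_from_counts(Reduce(`+`, lapply(gs, `[[`, "counts")), gene_id = "mode")
  }
  match_set <- function(mode) {
    which(vapply(eligible, function(g) {
      atypicality_test(g, mode, p_threshold)$p >= p_threshold
    }, logical(1)))
  }
  mode <- pooled(eligible)
  seen <- character(0)
  best <- list(mode = mode, n = -1L)
  prev <- integer(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ms <- match_set(mode)
    if (length(ms) > best$n) best <- list(mode = mode, n = length(ms))
    key <- paste(ms, collapse = ",")
    if (identical(ms, prev)) { converged <- TRUE; break }
    if (key %in% seen) break # cycle: keep best-so-far
    seen <- c(seen, key)
    prev <- ms
    if (length(ms) == 0) break
    mode <- pooled(eligible[ms])
  }
  structure(list(mode = best$mode, n_matching = best$n, converged = converged,
                 iterations = it, n_eligible = length(eligible)),
            class = "ModalUsage")
}

#' Atypicality screen of a gene set against its modal usage
#'
#' Computes the modal usage and tests every gene against it.
#'
#' @param genes List of `CodonUsageVector`s.
#' @param p_threshold Atypicality threshold (default 0.1).
#' @return A list: `mode` (the `ModalUsage`), `calls` (data.frame with
#'   `gene_id`, `chi2`, `df`, `p`, `atypical`, `tested`).
#' @export
hgt_screen <- function(genes, p_threshold = 0.1) {
  m <- modal_usage(genes, p_threshold)
  calls <- do.call(rbind, lapply(genes, function(g) {
    a <- atypicality_test(g, m$mode, p_threshold)
    data.frame(gene_id = a$gene_id, chi2 = a$chi2, df = a$df, p = a$p,
               atypical = a$atypical, tested = a$tested,
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  list(mode = m, calls = calls)
}

#' Correspondence analysis of a gene x codon count matrix
#'
#' Standard CA: correspondence matrix from the counts, standardized
#' residuals, singular value decomposition, principal coordinates for the
#' rows (genes).  Axes are ordered by decreasing inertia; total inertia
#' equals the chi-square statistic of the table divided by its grand total.
#'
#' @param usage_matrix Numeric matrix, genes in rows, codons in columns
#'   (all-zero rows are not allowed; all-zero columns are dropped).
#' @param n_axes Number of axes to return.
#' @return A list: `coords` (row principal coordinates, genes x axes),
#'   `inertia` (per-axis share of total inertia), `total_inertia`,
#'   `singular_values`.
#' @export
correspondence_analysis <- function(usage_matrix, n_axes = 2) {
  m <- as.matrix(usage_matrix)
  if (nrow(m) < 3) stop("need at least 3 genes")
  if (any(rowSums(m) == 0)) stop("all-zero rows not allowed")
  m <- m[, colSums(m) > 0, drop = FALSE]
  n <- sum(m)
  P <- m / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cm) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  pos <- sv$d > 1e-12
  if (!any(pos)) { # zero inertia: all rows share one profile
    coords <- matrix(0, nrow(m), n_axes,
                     dimnames = list(rownames(m), paste0("CA", seq_len(n_axes))))
    return(list(coords = coords, inertia = numeric(0), total_inertia = 0,
                singular_values = numeric(0)))
  }
  d <- sv$d[pos]
  k <- min(n_axes, length(d))
  coords <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(length(d)), drop = FALSE] %*% diag(d)
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("CA", seq_len(ncol(coords)))
  list(coords = coords[, seq_len(k), drop = FALSE],
       inertia = d^2 / sum(d^2),
       total_inertia = sum(d^2),
       singular_values = d)
}

#' Gene x codon count matrix for a genome
#'
#' @param g A [genome_record()]; partial CDSs are skipped.
#' @param min_codons Keep genes with at least this many informative codons.
#' @return Numeric matrix of codon counts (genes x 59 codons).
#' @export
usage_matrix <- function(g, min_codons = 60) {
  genes <- genome_usage(g)
  genes <- Filter(function(u) u$n_codons >= min_codons, genes)
  do.call(rbind, lapply(genes, function(u) {
    stats::setNames(u$counts, names(u$counts))
  })) -> m
  rownames(m) <- vapply(genes, `[[`, character(1), "gene_id")
  m
}

#' Per-gene codon-usage vectors for a genome
#'
#' @param g A [genome_record()]; partial CDSs and CDSs with internal stops
#'   are skipped.
#' @return Named list of `CodonUsageVector`s.
#' @export
genome_usage <- function(g) {
  ids <- g$features$gene_id[!g$features$partial]
  out <- list()
  for (id in ids) {
    u <- tryCatch(gene_usage(g$cds[[id]], gene_id = id), error = function(e) NULL)
    if (!is.null(u)) out[[id]] <- u
  }
  out
}
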