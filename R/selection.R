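# Codon-level selection analysis for ortholog pairs: protein-guided codon
# alignment, Ka/Ks by the Nei-Gojobori pathway method (NG86) and by a
# YN00-style estimator with transition/transversion and codon-usage
# weighting, Fisher exact screening of omega > 1, and molecular-clock
# divergence dating from the median synonymous rate.

# Substitution rate per site per year used for dating (SNP clock calibrated
# on closely related bacterial isolates).
DEFAULT_CLOCK_RATE <- 8.3e-7

#' Protein-guided codon alignment of two CDSs
#'
#' Translates both CDSs, aligns the proteins globally (BLOSUM62), and maps
#' the alignment back to codons.  Columns containing a gap or an ambiguous
#' base in either sequence are dropped, so every retained column is an
#' intact codon pair.
#'
#' @param cds_a,cds_b Nucleotide CDSs (length divisible by 3; a terminal
#'   stop, if present, is removed).
#' @return A list of class `CodonAlignment`: `codons_a`, `codons_b`
#'   (character vectors of equal length), `n_codons`.
#' @export
codon_align <- function(cds_a, cds_b) {
  ca <- .strip_stop(.split_codons(cds_a))
  cb <- .strip_stop(.split_codons(cds_b))
  code <- .genetic_code()
  if (any(ca %in% .stop_codons()) || any(cb %in% .stop_codons())) {
    stop("internal stop codon in CDS")
  }
  pa <- paste(code[ca], collapse = "")
  pb <- paste(code[cb], collapse = "")
  aln <- Biostrings::pairwiseAlignment(pa, pb, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 11, gapExtension = 1)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(sa != "-")
  ib <- cumsum(sb != "-")
  keep <- which(sa != "-" & sb != "-")
  codons_a <- ca[ia[keep]]
  codons_b <- cb[ib[keep]]
  clean <- !grepl("[^ACGT]", codons_a) & !grepl("[^ACGT]", codons_b)
  structure(list(codons_a = codons_a[clean], codons_b = codons_b[clean],
                 n_codons = sum(clean)),
            class = "CodonAlignment")
}

#' @noRd
.strip_stop <- function(codons) {
  if (length(codons) && codons[length(codons)] %in% .stop_codons()) {
    codons <- codons[-length(codons)]
  }
  codons
}

#' @noRd
.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_) # saturated
  -0.75 * log(1 - 4 * p / 3)
}

#' @noRd
.selection_result <- function(method, ka, ks, kappa, S, N, Sd, Nd, n_codons,
                              saturated = FALSE, fallback = FALSE) {
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  res <- list(method = method, Ka = ka, Ks = ks, omega = omega, kappa = kappa,
              S = S, N = N, Sd = Sd, Nd = Nd, n_codons = n_codons,
              saturated = saturated, fallback = fallback)
  res$fisher_p <- tryCatch(omega_significance(res), error = function(e) NA_real_)
  structure(res, class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("%s: Ka=%.4f Ks=%.4f omega=%s kappa=%s (S=%.1f N=%.1f Sd=%.2f Nd=%.2f)%s\n",
              x$method, x$Ka, x$Ks,
              if (is.na(x$omega)) "NA" else sprintf("%.3f", x$omega),
              if (is.na(x$kappa)) "-" else sprintf("%.2f", x$kappa),
              x$S, x$N, x$Sd, x$Nd,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Ka/Ks by the Nei-Gojobori (NG86) pathway method
#'
#' Synonymous and nonsynonymous sites are counted by enumerating, per codon
#' position, the non-stop single-nucleotide changes (averaged over the two
#' sequences, so S + N = 3 * n_codons).  Differences are counted by
#' averaging over all minimal mutational pathways between differing codons,
#' discarding pathways through stop codons.  Proportions are
#' Jukes-Cantor corrected; a proportion at or beyond 3/4 leaves that rate
#' undefined and flags the pair saturated.
#'
#' @param aln A [codon_align()] result.
#' @return A `SelectionResult`: `Ka`, `Ks`, `omega`, `S`, `N`, `Sd`, `Nd`,
#'   `fisher_p`, `saturated`.
#' @export
kaks_ng86 <- function(aln) {
  stopifnot(inherits(aln, "CodonAlignment"))
  if (aln$n_codons < 10) stop("need at least 10 aligned codons")
  sites <- .codon_syn_sites(kappa = 1)
  S <- (sum(sites[aln$codons_a]) + sum(sites[aln$codons_b])) / 2
  N <- 3 * aln$n_codons - S
  tabs <- .pair_diff_tables()
  idx <- cbind(aln$codons_a, aln$codons_b)
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  ps <- Sd / S
  pn <- Nd / N
  ks <- .jc_correct(ps)
  ka <- .jc_correct(pn)
  .selection_result("NG86", ka, ks, NA_real_, S, N, Sd, Nd, aln$n_codons,
                    saturated = is.na(ks) || is.na(ka))
}

# Position-specific nucleotide frequencies averaged over both sequences,
# turned into F3x4 codon frequencies (small pseudocount guards empty cells).
#' @noRd
.f3x4_freqs <- function(aln) {
  cods <- c(aln$codons_a, aln$codons_b)
  f <- matrix(0.1, nrow = 4, ncol = 3, dimnames = list(.NT, NULL))
  for (p in 1:3) {
    tb <- table(factor(substr(cods, p, p), levels = .NT))
    f[, p] <- f[, p] + as.numeric(tb)
  }
  f <- sweep(f, 2, colSums(f), "/")
  all64 <- .codons()
  pi <- vapply(all64, function(cd) {
    f[substr(cd, 1, 1), 1] * f[substr(cd, 2, 2), 2] * f[substr(cd, 3, 3), 3]
  }, numeric(1))
  pi[.stop_codons()] <- 0
  pi / sum(pi)
}

# K80 two-parameter correction from transition/transversion proportions.
# Returns c(distance, ts_distance, tv_distance) or NAs when saturated.
#' @noRd
.k80 <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(c(NA_real_, NA_real_, NA_real_))
  d_ts <- -0.5 * log(w1) + 0.25 * log(w2)
  d_tv <- -0.5 * log(w2)
  c(d_ts + d_tv, d_ts, d_tv)
}

# Kappa from fourfold-degenerate and nondegenerate positions shared between
# the two sequences (K80 estimate per class, site-count-weighted average).
#' @noRd
.estimate_kappa <- function(aln) {
  deg <- .codon_degeneracy()
  ests <- numeric(0)
  wts <- numeric(0)
  for (class in c(4L, 0L)) {
    ts <- 0; tv <- 0; n <- 0
    for (p in 1:3) {
      sel <- deg[aln$codons_a, p] == class & deg[aln$codons_b, p] == class
      sel[is.na(sel)] <- FALSE
      if (!any(sel)) next
      ba <- substr(aln$codons_a[sel], p, p)
      bb <- substr(aln$codons_b[sel], p, p)
      n <- n + sum(sel)
      diff <- ba != bb
      ts <- ts + sum(diff & .is_transition(ba, bb))
      tv <- tv + sum(diff & !.is_transition(ba, bb))
    }
    if (n < 10) next
    k <- .k80(ts / n, tv / n)
    if (!is.na(k[3]) && k[3] > 0 && is.finite(k[2] / k[3])) {
      # kappa = alpha/beta: transition distance over one-type transversion
      # distance (tv distance covers two transversion types)
      ests <- c(ests, (k[2]) / (k[3] / 2))
      wts <- c(wts, n)
    }
  }
  if (!length(ests)) return(2)
  min(max(sum(ests * wts) / sum(wts), 0.1), 99)
}

#' Ka/Ks by a YN00-style estimator
#'
#' Iterative approximate estimator in the spirit of Yang & Nielsen (2000):
#' codon frequencies are estimated from the data (F3x4), the
#' transition/transversion ratio kappa from fourfold-degenerate and
#' nondegenerate sites, synonymous/nonsynonymous sites are counted with
#' kappa- and codon-frequency-weighting, differences are classified into
#' synonymous/nonsynonymous transitions and transversions by pathway
#' averaging, and Ka and Ks are obtained by separate K80 corrections.
#' The site counts are iterated to convergence of (S, N, kappa); on
#' non-convergence or saturation the NG86 result is returned flagged as a
#' fallback.
#'
#' @param aln A [codon_align()] result (at least 30 codons).
#' @param kappa Fix kappa instead of estimating it (mainly for comparisons
#'   against the NG86 limit).
#' @param max_iter Iteration cap.
#' @return A `SelectionResult` with `method = "YN00"` (or the flagged NG86
#'   fallback).
#' @export
kaks_yn00 <- function(aln, kappa = NULL, max_iter = 100) {
  stopifnot(inherits(aln, "CodonAlignment"))
  if (aln$n_codons < 30) stop("need at least 30 aligned codons for YN00")
  pi <- .f3x4_freqs(aln)
  k <- if (is.null(kappa)) .estimate_kappa(aln) else kappa
  tabs <- .pair_diff_tables()
  idx <- cbind(aln$codons_a, aln$codons_b)
  sts <- sum(tabs$sts[idx]); stv <- sum(tabs$stv[idx])
  nts <- sum(tabs$nts[idx]); ntv <- sum(tabs$ntv[idx])
  Sd <- sts + stv
  Nd <- nts + ntv
  S <- N <- NA_real_
  prev <- c(Inf, Inf, Inf)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sites <- .codon_syn_sites(kappa = k, codon_freq = pi)
    S <- (sum(sites[aln$codons_a]) + sum(sites[aln$codons_b])) / 2
    N <- 3 * aln$n_codons - S
    cur <- c(S, N, k)
    if (max(abs(cur - prev)) < 1e-8) { converged <- TRUE; break }
    prev <- cur
  }
  ks <- .k80(sts / S, stv / S)[1]
  ka <- .k80(nts / N, ntv / N)[1]
  if (!converged || is.na(ks) || is.na(ka)) {
    ng <- kaks_ng86(aln)
    ng$fallback <- TRUE
    ng$kappa <- k
    return(ng)
  }
  .selection_result("YN00", ka, ks, k, S, N, Sd, Nd, aln$n_codons)
}

#' Fisher exact test for omega different from neutrality
#'
#' Two-sided Fisher exact probability on the 2x2 table of rounded site and
#' difference counts `[[Sd, S - Sd], [Nd, N - Nd]]`, the construction used
#' by the KaKs-calculator convention.  Screens pairs with omega > 1 for
#' statistical support (significance called at P < 0.01).
#'
#' @param res A `SelectionResult` (or any list with `S`, `N`, `Sd`, `Nd`).
#' @return The two-sided p-value.
#' @export
omega_significance <- function(res) {
  tab <- round(matrix(c(res$Sd, res$S - res$Sd, res$Nd, res$N - res$Nd),
                      nrow = 2, byrow = TRUE))
  if (any(!is.finite(tab))) stop("non-finite site counts")
  if (any(tab < 0)) stop("negative cell after rounding (saturated counts?)")
  stats::fisher.test(tab)$p.value
}

#' Molecular-clock divergence time from synonymous rates
#'
#' tau = median(Ks) / (2 * lambda), with lambda the per-site per-year
#' substitution rate (default 8.3e-7, a SNP clock for closely related
#' bacterial isolates).  Saturated/non-finite Ks values are excluded before
#' taking the median.
#'
#' @param ks_values Numeric vector of per-pair Ks estimates.
#' @param lambda Substitutions/site/year.
#' @return A list of class `DivergenceEstimate`: `tau` (years), `ks_median`,
#'   `lambda`, `n_pairs` (pairs entering the median).
#' @export
divergence_time <- function(ks_values, lambda = DEFAULT_CLOCK_RATE) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("lambda must be a positive scalar")
  }
  ks <- ks_values[is.finite(ks_values)]
  if (length(ks) == 0) stop("no finite Ks values")
  ks_median <- stats::median(ks)
  structure(list(tau = ks_median / (2 * lambda), ks_median = ks_median,
                 lambda = lambda, n_pairs = length(ks)),
            class = "DivergenceEstimate")
}

#' @export
print.DivergenceEstimate <- function(x, ...) {
  cat(sprintf("median Ks = %.6f over %d pairs; lambda = %g /site/year; tau = %s years\n",
              x$ks_median, x$n_pairs, x$lambda,
              format(round(x$tau), big.mark = ",")))
  invisible(x)
}

#' Selection screen over an ortholog set
#'
#' Convenience driver: codon-aligns every ortholog pair, runs the requested
#' Ka/Ks estimator, and tabulates the results.
#'
#' @param partition A [reciprocal_orthologs()] result.
#' @param A,B The two [genome_record()]s.
#' @param method `"yn00"` or `"ng86"`.
#' @param min_codons Minimum aligned codons to analyse a pair.
#' @return A data.frame with one row per analysed pair: gene ids, `Ka`,
#'   `Ks`, `omega`, `kappa`, `S`, `N`, `Sd`, `Nd`, `fisher_p`, `saturated`,
#'   `fallback`.
#' @export
selection_screen <- function(partition, A, B, method = c("yn00", "ng86"),
                             min_codons = 30) {
  method <- match.arg(method)
  fun <- if (method == "yn00") kaks_yn00 else kaks_ng86
  rows <- list()
  for (i in seq_len(nrow(partition$shared))) {
    ga <- partition$shared$gene_a[i]
    gb <- partition$shared$gene_b[i]
    aln <- tryCatch(codon_align(A$cds[[ga]], B$cds[[gb]]), error = function(e) NULL)
    if (is.null(aln) || aln$n_codons < min_codons) next
    r <- fun(aln)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ga, gene_b = gb, Ka = r$Ka, Ks = r$Ks, omega = r$omega,
      kappa = r$kappa, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
      fisher_p = r$fisher_p, saturated = r$saturated, fallback = r$fallback,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(), Ka = numeric(),
               Ks = numeric(), omega = numeric(), kappa = numeric(),
               S = numeric(), N = numeric(), Sd = numeric(), Nd = numeric(),
               fisher_p = numeric(), saturated = logical(), fallback = logical())
}
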