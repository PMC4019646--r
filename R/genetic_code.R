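# Internal codon machinery shared by the selection, codon-usage and simulator
# code: bacterial genetic code (translation table 11), codon neighbourhoods,
# synonymous-site counting and pathway-averaged difference counting.

.bc_cache <- new.env(parent = emptyenv())

.NT <- c("A", "C", "G", "T")

#' @noRd
.genetic_code <- function() {
  if (is.null(.bc_cache$code)) {
    code <- Biostrings::getGeneticCode("11")
    .bc_cache$code <- stats::setNames(as.character(code), names(code))
  }
  .bc_cache$code
}

#' @noRd
.codons <- function() names(.genetic_code())

#' @noRd
.stop_codons <- function() names(.genetic_code())[.genetic_code() == "*"]

#' @noRd
.sense_codons <- function() names(.genetic_code())[.genetic_code() != "*"]

#' @noRd
.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# All nine single-nucleotide neighbours of a codon, with the position changed
# and whether the change is a transition.
#' @noRd
.codon_neighbors <- function(codon) {
  if (!is.null(.bc_cache$neighbors[[codon]])) return(.bc_cache$neighbors[[codon]])
  base <- strsplit(codon, "")[[1]]
  out <- data.frame(pos = integer(9), to = character(9), codon = character(9),
                    ts = logical(9), stringsAsFactors = FALSE)
  k <- 0L
  for (p in 1:3) {
    for (b in setdiff(.NT, base[p])) {
      k <- k + 1L
      nb <- base
      nb[p] <- b
      out$pos[k] <- p
      out$to[k] <- b
      out$codon[k] <- paste(nb, collapse = "")
      out$ts[k] <- .is_transition(base[p], b)
    }
  }
  if (is.null(.bc_cache$neighbors)) .bc_cache$neighbors <- list()
  .bc_cache$neighbors[[codon]] <- out
  out
}

# Synonymous site count per codon (vector over all 64 codons; NA for stops).
# Each codon position contributes exactly one site, split between synonymous
# and nonsynonymous in proportion to the weighted fraction of its non-stop
# single-nucleotide changes that are synonymous.  Weights: kappa for
# transitions, 1 for transversions, optionally multiplied by the equilibrium
# frequency of the target codon (used by the YN00-style estimator).
#' @noRd
.codon_syn_sites <- function(kappa = 1, codon_freq = NULL) {
  code <- .genetic_code()
  stops <- .stop_codons()
  vapply(names(code), function(cd) {
    if (code[[cd]] == "*") return(NA_real_)
    nb <- .codon_neighbors(cd)
    s <- 0
    for (p in 1:3) {
      sel <- nb$pos == p & !(nb$codon %in% stops)
      if (!any(sel)) next
      w <- ifelse(nb$ts[sel], kappa, 1)
      if (!is.null(codon_freq)) w <- w * codon_freq[nb$codon[sel]]
      tot <- sum(w)
      if (tot <= 0) next
      syn <- code[nb$codon[sel]] == code[[cd]]
      s <- s + sum(w[syn]) / tot
    }
    s
  }, numeric(1))
}

# Degeneracy class of each codon position: 4 if every change is synonymous,
# 0 if every change (including to stops, counted nonsynonymous) is
# nonsynonymous, 2 otherwise.  64 x 3 matrix.
#' @noRd
.codon_degeneracy <- function() {
  if (!is.null(.bc_cache$degeneracy)) return(.bc_cache$degeneracy)
  code <- .genetic_code()
  deg <- matrix(NA_integer_, nrow = 64, ncol = 3, dimnames = list(names(code), NULL))
  for (cd in names(code)) {
    if (code[[cd]] == "*") next
    nb <- .codon_neighbors(cd)
    for (p in 1:3) {
      sel <- nb$pos == p
      syn <- code[nb$codon[sel]] == code[[cd]] # change to stop is nonsyn
      deg[cd, p] <- if (all(syn)) 4L else if (!any(syn)) 0L else 2L
    }
  }
  .bc_cache$degeneracy <- deg
  deg
}

# Pathway-averaged difference counts for every ordered codon pair:
# sd/nd (synonymous / nonsynonymous differences) and their breakdown into
# transitions and transversions (sts, stv, nts, ntv).  Minimal mutational
# pathways between the two codons are enumerated; paths passing through a
# stop codon are discarded and the remainder weighted equally (all paths are
# kept if every one is blocked).  Cached as 64 x 64 matrices.
#' @noRd
.pair_diff_tables <- function() {
  if (!is.null(.bc_cache$pair_tabs)) return(.bc_cache$pair_tabs)
  code <- .genetic_code()
  cods <- names(code)
  stops <- .stop_codons()
  nm <- list(cods, cods)
  tabs <- list(sd = matrix(0, 64, 64, dimnames = nm),
               nd = matrix(0, 64, 64, dimnames = nm),
               sts = matrix(0, 64, 64, dimnames = nm),
               stv = matrix(0, 64, 64, dimnames = nm),
               nts = matrix(0, 64, 64, dimnames = nm),
               ntv = matrix(0, 64, 64, dimnames = nm))
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (c1 in setdiff(cods, stops)) {
    b1 <- strsplit(c1, "")[[1]]
    for (c2 in setdiff(cods, stops)) {
      if (c1 == c2) next
      b2 <- strsplit(c2, "")[[1]]
      dpos <- which(b1 != b2)
      nd <- length(dpos)
      ords <- perms[[as.character(nd)]]
      acc <- matrix(0, nrow = nrow(ords), ncol = 6)
      valid <- logical(nrow(ords))
      for (r in seq_len(nrow(ords))) {
        cur <- b1
        ok <- TRUE
        cnt <- numeric(6) # sd, nd, sts, stv, nts, ntv
        for (step in dpos[ords[r, ]]) {
          from <- cur[step]
          prev <- paste(cur, collapse = "")
          cur[step] <- b2[step]
          now <- paste(cur, collapse = "")
          if (now %in% stops && now != c2) { ok <- FALSE; break }
          syn <- code[[prev]] == code[[now]]
          ts <- .is_transition(from, b2[step])
          if (syn) cnt[1] <- cnt[1] + 1 else cnt[2] <- cnt[2] + 1
          if (syn && ts) cnt[3] <- cnt[3] + 1
          if (syn && !ts) cnt[4] <- cnt[4] + 1
          if (!syn && ts) cnt[5] <- cnt[5] + 1
          if (!syn && !ts) cnt[6] <- cnt[6] + 1
        }
        acc[r, ] <- cnt
        valid[r] <- ok
      }
      use <- if (any(valid)) acc[valid, , drop = FALSE] else acc
      avg <- colMeans(use)
      tabs$sd[c1, c2] <- avg[1]; tabs$nd[c1, c2] <- avg[2]
      tabs$sts[c1, c2] <- avg[3]; tabs$stv[c1, c2] <- avg[4]
      tabs$nts[c1, c2] <- avg[5]; tabs$ntv[c1, c2] <- avg[6]
    }
  }
  .bc_cache$pair_tabs <- tabs
  tabs
}

#' @noRd
.split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a CDS with the bacterial genetic code
#'
#' Translates a nucleotide coding sequence with translation table 11,
#' dropping a terminal stop if present.  Ambiguous codons translate to `X`.
#'
#' @param cds A character scalar or [Biostrings::DNAString] whose length is a
#'   multiple of 3.
#' @return A character scalar amino-acid sequence (no terminal stop).
#' @export
translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(toupper(as.character(cds))),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}
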