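# Fragment-based average nucleotide identity (ANI) and percent conserved
# DNA between two genomes, computed as a reciprocal two-way average in the
# style of Goris et al.: the query genome is cut into consecutive fragments,
# each fragment is locally aligned to the whole subject genome, and fragments
# passing identity and alignable-length filters are averaged.

#' ANI parameters
#'
#' Defaults follow the fragment-based recipe used for genome-level species
#' comparisons: 1020-bp fragments, 30% minimum identity, 714-bp minimum
#' alignable region; fragments aligning at >= 90% identity count towards
#' percent conserved DNA.
#'
#' @param fragment_size Fragment length in bp.
#' @param min_identity Minimum percent identity of a fragment's best hit for
#'   it to enter the ANI average.
#' @param min_alignable Minimum alignment length (bp) of the best hit.
#' @param conserved_identity Identity threshold (%) above which a fragment's
#'   aligned bases count as conserved DNA.
#' @return A list of class `AniParams`.
#' @export
ani_params <- function(fragment_size = 1020, min_identity = 30,
                       min_alignable = 714, conserved_identity = 90) {
  stopifnot(fragment_size > 0, min_identity > 0, min_identity <= 100,
            min_alignable <= fragment_size)
  structure(list(fragment_size = fragment_size, min_identity = min_identity,
                 min_alignable = min_alignable,
                 conserved_identity = conserved_identity),
            class = "AniParams")
}

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping windows of `size` bp per scaffold; a trailing fragment
#' shorter than `size` is retained and labelled partial.
#'
#' @param g A [genome_record()].
#' @param size Fragment size in bp.
#' @return A [Biostrings::DNAStringSet] of fragments named
#'   `<scaffold>|<index>`, with metadata column `partial`.
#' @export
fragment_genome <- function(g, size = 1020) {
  stopifnot(size > 0)
  frags <- list()
  partial <- logical(0)
  for (sid in names(g$scaffolds)) {
    s <- g$scaffolds[[sid]]
    n <- length(s)
    starts <- seq(1L, n, by = size)
    ends <- pmin(starts + size - 1L, n)
    for (i in seq_along(starts)) {
      frags[[sprintf("%s|%d", sid, i)]] <- Biostrings::subseq(s, starts[i], ends[i])
    }
    partial <- c(partial, ends - starts + 1L < size)
  }
  out <- Biostrings::DNAStringSet(frags)
  S4Vectors::mcols(out)$partial <- partial
  out
}

#' One-way fragment ANI
#'
#' Cuts the query into fragments and aligns each to the full subject with
#' BLASTN (match +1 / mismatch -1 / gap open -5 / gap extend -2, both
#' strands, best hit per fragment).  Fragments whose best alignment reaches
#' `min_identity` and spans at least `min_alignable` columns enter the ANI
#' mean; aligned bases of fragments at or above `conserved_identity` count
#' towards percent conserved DNA (relative to the query genome length).
#'
#' @param query,subject [genome_record()]s.
#' @param params An [ani_params()] object.
#' @return A list: `ani` (mean % identity of retained fragments, `NA` when
#'   none is retained), `conserved` (% of query genome length), `n_used`,
#'   `n_fragments`, and the per-fragment best-hit table `hits`.
#' @export
one_way_ani <- function(query, subject, params = ani_params()) {
  frags <- fragment_genome(query, params$fragment_size)
  hits <- .best_hits(.blast_search(frags, subject$scaffolds, "blastn"))
  qlen <- sum(Biostrings::width(query$scaffolds))
  if (nrow(hits) == 0) {
    return(list(ani = NA_real_, conserved = 0, n_used = 0L,
                n_fragments = length(frags), hits = hits))
  }
  hits$aligned_span <- hits$qend - hits$qstart + 1L
  retained <- hits$pident >= params$min_identity & hits$length >= params$min_alignable
  conserved_frac <- sum(hits$aligned_span[hits$pident >= params$conserved_identity])
  list(ani = if (any(retained)) mean(hits$pident[retained]) else NA_real_,
       conserved = 100 * conserved_frac / qlen,
       n_used = sum(retained),
       n_fragments = length(frags),
       hits = hits)
}

#' Two-way (reciprocal) ANI and percent conserved DNA
#'
#' Runs [one_way_ani()] in both directions and averages.  Also reports the
#' genome-level species-boundary verdict (same species when ANI > 95% and
#' conserved DNA > 69%).
#'
#' @param a,b [genome_record()]s.
#' @param params An [ani_params()] object.
#' @return A list of class `AniResult` with directional and mean ANI and
#'   conserved-DNA percentages, fragment counts, the species verdict, and
#'   the engine label.
#' @export
two_way_ani <- function(a, b, params = ani_params()) {
  ab <- one_way_ani(a, b, params)
  ba <- one_way_ani(b, a, params)
  ani_mean <- mean(c(ab$ani, ba$ani))
  conserved_mean <- mean(c(ab$conserved, ba$conserved))
  structure(list(
    ani_ab = ab$ani, ani_ba = ba$ani, ani_mean = ani_mean,
    conserved_ab = ab$conserved, conserved_ba = ba$conserved,
    conserved_mean = conserved_mean,
    n_fragments_used = c(ab = ab$n_used, ba = ba$n_used),
    same_species = !is.na(ani_mean) && ani_mean > 95 && conserved_mean > 69,
    params = params, engine = "blastn"
  ), class = "AniResult")
}

#' @export
print.AniResult <- function(x, ...) {
  cat(sprintf("ANI %.2f%% (a->b %.2f, b->a %.2f); conserved DNA %.2f%%\n",
              x$ani_mean, x$ani_ab, x$ani_ba, x$conserved_mean))
  cat(sprintf("species-boundary verdict (ANI>95%%, conserved>69%%): %s\n",
              if (x$same_species) "same species" else "distinct"))
  invisible(x)
}
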