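# Ortholog detection between two annotated genomes by the reciprocal
# smallest distance (RSD) procedure: BLASTP candidate hits, global protein
# alignment of the top candidates, corrected protein distance, and mutual
# smallest-distance pairing.

# Saturation ceiling for the corrected protein distance.
.DIST_CEILING <- 10

#' Candidate subject proteins for one query
#'
#' Top-`k` subject proteins by BLASTP local alignment score (BLOSUM62,
#' gap open -11 / extend -1); hits below `min_score` (raw score) are
#' discarded.
#'
#' @param query_protein A single amino-acid sequence (character or
#'   [Biostrings::AAString]).
#' @param subject_proteome Named [Biostrings::AAStringSet] (or named
#'   character vector).
#' @param k Number of candidates to keep.
#' @param min_score Minimum raw alignment score.
#' @return Character vector of subject ids, best first (possibly empty).
#' @export
candidate_hits <- function(query_protein, subject_proteome, k = 3, min_score = 50) {
  q <- Biostrings::AAStringSet(stats::setNames(as.character(query_protein), "query"))
  if (!methods::is(subject_proteome, "AAStringSet")) {
    subject_proteome <- Biostrings::AAStringSet(subject_proteome)
  }
  hits <- .blastp_topk(q, subject_proteome, k, min_score)
  hits$sseqid[hits$qseqid == "query"]
}

#' @noRd
.blastp_topk <- function(queries, subjects, k, min_score) {
  hits <- .blast_search(queries, subjects, "blastp")
  if (nrow(hits) == 0) return(hits)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  # best HSP per query-subject pair, then top-k subjects per query
  hits <- hits[order(hits$qseqid, -hits$score), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("qseqid", "sseqid")]), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$qseqid),
                        function(i) i[seq_len(min(k, length(i)))]))
  hits[sort(keep), , drop = FALSE]
}

# Global protein alignment and corrected distance for a query against a set
# of candidate hits; returns the smallest-distance hit.
# Distance: Kimura-style correction d = -ln(1 - p - p^2/5) on the proportion
# p of differing non-gap columns; p at or beyond saturation maps to the
# ceiling (10) and is flagged.
#' @noRd
.protein_distance <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ng <- pa != "-" & sa != "-"
  p <- if (any(ng)) sum(pa[ng] != sa[ng]) / sum(ng) else 1
  arg <- 1 - p - p^2 / 5
  if (arg <= 0) {
    list(distance = .DIST_CEILING, saturated = TRUE, p = p,
         score = Biostrings::score(aln))
  } else {
    list(distance = -log(arg), saturated = FALSE, p = p,
         score = Biostrings::score(aln))
  }
}

#' Smallest-distance hit among candidates
#'
#' Globally aligns the query to each candidate and returns the hit with the
#' smallest corrected protein distance.  Ties are broken by higher alignment
#' score, then lexicographic id.
#'
#' @param query Amino-acid sequence.
#' @param hits Named [Biostrings::AAStringSet] (or named character vector) of
#'   candidate sequences.
#' @return A list: `best_hit` (id), `distance`, `saturated`, `p`
#'   (proportion of differing non-gap columns), `score`.
#' @export
smallest_distance_pair <- function(query, hits) {
  if (!methods::is(hits, "AAStringSet")) hits <- Biostrings::AAStringSet(hits)
  if (length(hits) == 0) stop("no candidate hits")
  res <- lapply(seq_along(hits), function(i) {
    .protein_distance(as.character(query), as.character(hits[[i]]))
  })
  d <- vapply(res, `[[`, numeric(1), "distance")
  sc <- vapply(res, `[[`, numeric(1), "score")
  ord <- order(d, -sc, names(hits))
  i <- ord[1]
  c(res[[i]], list(best_hit = names(hits)[i]))
}

#' Reciprocal smallest distance orthologs
#'
#' A pair (a, b) is called orthologous iff b is a's smallest-distance hit
#' among a's top-`k` BLASTP candidates in B, and reciprocally a is b's
#' smallest-distance hit in A.  Genes without a reciprocal partner are
#' reported as unique to their genome.  Partial CDSs (no protein) are
#' treated as unique.
#'
#' @param A,B [genome_record()]s with annotated proteins.
#' @param k Candidate hits per query.
#' @param min_score Minimum BLASTP raw score for a candidate.
#' @return A list of class `GeneSetPartition`: `shared` (data.frame
#'   `gene_a`, `gene_b`, `distance`, `p`, `saturated`), `unique_a`,
#'   `unique_b` (character vectors).
#' @export
reciprocal_orthologs <- function(A, B, k = 3, min_score = 50) {
  prot_a <- A$protein[!is.na(A$protein) & nzchar(A$protein)]
  prot_b <- B$protein[!is.na(B$protein) & nzchar(B$protein)]
  aa <- Biostrings::AAStringSet(prot_a)
  bb <- Biostrings::AAStringSet(prot_b)
  best_ab <- .best_distance_map(aa, bb, k, min_score)
  best_ba <- .best_distance_map(bb, aa, k, min_score)
  pairs <- list()
  for (ga in names(best_ab)) {
    gb <- best_ab[[ga]]$best_hit
    back <- best_ba[[gb]]
    if (!is.null(back) && identical(back$best_hit, ga)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb,
        distance = best_ab[[ga]]$distance, p = best_ab[[ga]]$p,
        saturated = best_ab[[ga]]$saturated, stringsAsFactors = FALSE)
    }
  }
  shared <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(), gene_b = character(), distance = numeric(),
               p = numeric(), saturated = logical(), stringsAsFactors = FALSE)
  structure(list(
    shared = shared,
    unique_a = setdiff(A$features$gene_id, shared$gene_a),
    unique_b = setdiff(B$features$gene_id, shared$gene_b)
  ), class = "GeneSetPartition")
}

#' @noRd
.best_distance_map <- function(queries, subjects, k, min_score) {
  hits <- .blastp_topk(queries, subjects, k, min_score)
  out <- list()
  if (nrow(hits) == 0) return(out)
  for (q in unique(hits$qseqid)) {
    cand <- hits$sseqid[hits$qseqid == q]
    out[[q]] <- smallest_distance_pair(queries[[q]], subjects[cand])
  }
  out
}

#' @export
print.GeneSetPartition <- function(x, ...) {
  cat(sprintf("%d orthologous pairs; %d genes unique to A, %d unique to B\n",
              nrow(x$shared), length(x$unique_a), length(x$unique_b)))
  invisible(x)
}
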