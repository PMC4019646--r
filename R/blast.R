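# Thin wrappers around the NCBI BLAST+ binaries used for local-alignment
# search steps (ANI fragment search, pseudomolecule anchoring, ortholog
# candidate search).  Alignment scoring for nucleotide searches is
# match +1 / mismatch -1 / gap open -5 / gap extend -2.

.blast_check <- function(prog) {
  if (Sys.which(prog) == "") {
    stop(sprintf("'%s' not found on PATH; BLAST+ is required for this step", prog))
  }
}

.blast_fields <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore", "score")

# Tabular BLAST search of `query` (named XStringSet) against `subject`
# (named XStringSet).  Returns a data.frame with .blast_fields columns.
#' @noRd
.blast_search <- function(query, subject, program = c("blastn", "blastp"),
                          extra = character()) {
  program <- match.arg(program)
  .blast_check(program)
  .blast_check("makeblastdb")
  dir <- tempfile("blast")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fa")
  sf <- file.path(dir, "subject.fa")
  Biostrings::writeXStringSet(query, qf)
  Biostrings::writeXStringSet(subject, sf)
  dbtype <- if (program == "blastn") "nucl" else "prot"
  db <- file.path(dir, "db")
  out <- system2("makeblastdb", c("-in", sf, "-dbtype", dbtype, "-out", db),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status"))) stop("makeblastdb failed: ", paste(out, collapse = "\n"))
  resf <- file.path(dir, "hits.tsv")
  args <- c("-query", qf, "-db", db, "-out", resf,
            "-outfmt", shQuote(paste("6", paste(.blast_fields, collapse = " "))),
            extra)
  if (program == "blastn") {
    args <- c(args, "-task", "blastn", "-reward", "1", "-penalty", "-1",
              "-gapopen", "5", "-gapextend", "2", "-dust", "no",
              "-xdrop_gap_final", "150", "-evalue", "1e-5")
  } else {
    args <- c(args, "-seg", "no", "-comp_based_stats", "0", "-evalue", "1e-3")
  }
  out <- system2(program, args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status"))) stop(program, " failed: ", paste(out, collapse = "\n"))
  if (file.size(resf) == 0) {
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(.blast_fields))), .blast_fields))
  }
  hits <- utils::read.delim(resf, header = FALSE, col.names = .blast_fields,
                            stringsAsFactors = FALSE)
  hits$qseqid <- as.character(hits$qseqid)
  hits$sseqid <- as.character(hits$sseqid)
  hits
}

# Best hit per query by raw score (ties: bitscore, then input order).
#' @noRd
.best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$qseqid, -hits$score, -hits$bitscore)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}
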