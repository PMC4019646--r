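# Genome containers, FASTA/GFF3 input and output, reference-guided
# pseudomolecule scaffolding and descriptive genome statistics.

#' Six-frame stop-codon scaffold-join spacer
#'
#' 34-nt spacer used to join scaffolds into a pseudomolecule.  The 26-nt
#' core is its own reverse complement and contains a stop codon in every
#' reading frame on both strands, so no ORF prediction can read through a
#' join.
#' @export
PSEUDOMOLECULE_SPACER <- "NNNNCACACACTTAATTAATTAAGTGTGTGNNNN"

#' Construct a genome record
#'
#' Bundles a named genome: its scaffolds, its gene features, and the CDS and
#' protein sequences extracted from them.  Coordinates are 1-based inclusive
#' (GFF convention); minus-strand CDSs are reverse-complemented before
#' translation with the bacterial genetic code (table 11).
#'
#' @param name Genome label.
#' @param scaffolds A named [Biostrings::DNAStringSet] (or named character
#'   vector) of scaffold sequences; names must be unique.
#' @param features A data.frame with columns `gene_id`, `scaffold_id`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`) and optionally `category`
#'   (single-letter functional category, `NA` when unannotated).
#' @return An object of class `GenomeRecord`: a list with elements `name`,
#'   `scaffolds`, `features` (with added logical column `partial` for CDSs
#'   whose length is not a multiple of 3), `cds` (named `DNAStringSet`) and
#'   `protein` (named character vector, `NA` for partial CDSs).
#' @export
genome_record <- function(name, scaffolds, features = NULL) {
  if (!methods::is(scaffolds, "DNAStringSet")) {
    scaffolds <- Biostrings::DNAStringSet(scaffolds)
  }
  if (length(scaffolds) > 0 &&
        (is.null(names(scaffolds)) || anyDuplicated(names(scaffolds)))) {
    stop("scaffolds must have unique names")
  }
  if (is.null(features)) {
    features <- data.frame(gene_id = character(), scaffold_id = character(),
                           start = integer(), end = integer(),
                           strand = character(), category = character(),
                           stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"category" %in% names(features)) features$category <- NA_character_
  if (nrow(features) > 0) {
    if (anyDuplicated(features$gene_id)) stop("gene ids must be unique")
    bad <- !features$scaffold_id %in% names(scaffolds)
    if (any(bad)) stop("features reference unknown scaffolds: ",
                       paste(unique(features$scaffold_id[bad]), collapse = ", "))
    slen <- stats::setNames(Biostrings::width(scaffolds), names(scaffolds))
    if (any(features$start < 1 | features$end > slen[features$scaffold_id] |
              features$start > features$end)) {
      stop("feature coordinates outside scaffold bounds")
    }
    if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  g <- structure(list(name = name, scaffolds = scaffolds, features = features),
                 class = "GenomeRecord")
  g <- .extract_cds(g)
  g
}

#' @noRd
.extract_cds <- function(g) {
  fts <- g$features
  if (nrow(fts) == 0) {
    g$features$partial <- logical(0)
    g$cds <- Biostrings::DNAStringSet()
    g$protein <- character(0)
    return(g)
  }
  cds <- vector("list", nrow(fts))
  for (i in seq_len(nrow(fts))) {
    s <- Biostrings::subseq(g$scaffolds[[fts$scaffold_id[i]]],
                            fts$start[i], fts$end[i])
    if (fts$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    cds[[i]] <- s
  }
  cds <- Biostrings::DNAStringSet(cds)
  names(cds) <- fts$gene_id
  partial <- Biostrings::width(cds) %% 3L != 0L
  prot <- rep(NA_character_, length(cds))
  ok <- which(!partial)
  prot[ok] <- vapply(ok, function(i) translate_cds(cds[[i]]), character(1))
  g$features$partial <- partial
  g$cds <- cds
  g$protein <- stats::setNames(prot, fts$gene_id)
  g
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d scaffold(s), %s bp, %d gene(s)\n",
              x$name, length(x$scaffolds),
              format(sum(Biostrings::width(x$scaffolds)), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

#' Read a genome from FASTA and GFF3
#'
#' Scaffolds are read from a (multi-)FASTA file, gene models from the `CDS`
#' features of a GFF3 annotation.  FASTA headers are truncated at the first
#' whitespace.  Gene identifiers are taken from the `ID` (else `locus_tag`)
#' attribute, functional categories from a `category` (else `COG`) attribute
#' when present.
#'
#' @param fasta_path Path to the scaffold FASTA file.
#' @param annotation_path Path to the GFF3 annotation, or `NULL` for an
#'   unannotated genome.
#' @param name Genome label; defaults to the FASTA file name.
#' @return A [genome_record()].
#' @export
read_genome <- function(fasta_path, annotation_path = NULL, name = NULL) {
  scaffolds <- Biostrings::readDNAStringSet(fasta_path)
  names(scaffolds) <- sub("\\s.*$", "", names(scaffolds))
  if (is.null(name)) name <- sub("\\.(fa|fasta|fna)$", "", basename(fasta_path))
  features <- NULL
  if (!is.null(annotation_path)) {
    gr <- rtracklayer::import(annotation_path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    meta <- S4Vectors::mcols(gr)
    ids <- if (!is.null(meta$ID)) as.character(meta$ID) else NULL
    if (is.null(ids) && !is.null(meta$locus_tag)) ids <- as.character(meta$locus_tag)
    if (is.null(ids)) ids <- sprintf("cds_%05d", seq_along(gr))
    cat_col <- if (!is.null(meta$category)) as.character(meta$category)
      else if (!is.null(meta$COG)) as.character(meta$COG)
      else NA_character_
    features <- data.frame(
      gene_id = ids,
      scaffold_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      category = cat_col,
      stringsAsFactors = FALSE)
  }
  genome_record(name, scaffolds, features)
}

#' Write a genome to FASTA and GFF3
#'
#' Inverse of [read_genome()]: emits the scaffolds as FASTA and the gene
#' features as GFF3 `CDS` records carrying `ID` and (when present)
#' `category` attributes.
#'
#' @param g A [genome_record()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, `g`.
#' @export
write_genome <- function(g, fasta_path, gff_path) {
  Biostrings::writeXStringSet(g$scaffolds, fasta_path)
  fts <- g$features
  con <- file(gff_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (sid in names(g$scaffolds)) {
    writeLines(sprintf("##sequence-region %s 1 %d", sid,
                       Biostrings::width(g$scaffolds)[names(g$scaffolds) == sid]), con)
  }
  if (nrow(fts) > 0) {
    attrs <- sprintf("ID=%s", fts$gene_id)
    has_cat <- !is.na(fts$category)
    attrs[has_cat] <- sprintf("%s;category=%s", attrs[has_cat], fts$category[has_cat])
    writeLines(sprintf("%s\tbathycomp\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                       fts$scaffold_id, fts$start, fts$end, fts$strand, attrs), con)
  }
  invisible(g)
}

#' Descriptive genome statistics
#'
#' Total length, GC content, scaffold and gene counts, and the mean
#' intergenic distance.  GC is computed over unambiguous bases only.
#' Intergenic gaps are measured between consecutive gene spans sorted by
#' start within each scaffold; with `intergenic = "skip"` (default) only
#' strictly positive gaps enter the mean (overlapping genes contribute
#' nothing), with `"clip"` overlaps are clipped to zero-length gaps and
#' included.
#'
#' @param g A [genome_record()].
#' @param intergenic Gap handling for overlapping genes: `"skip"` or `"clip"`.
#' @return A list of class `GenomeStats` with `total_length`, `gc_percent`,
#'   `n_scaffolds`, `n_genes`, `mean_intergenic`.
#' @export
genome_stats <- function(g, intergenic = c("skip", "clip")) {
  intergenic <- match.arg(intergenic)
  if (length(g$scaffolds) == 0 || sum(Biostrings::width(g$scaffolds)) == 0) {
    stop("empty genome")
  }
  af <- colSums(Biostrings::alphabetFrequency(g$scaffolds))
  acgt <- af[c("A", "C", "G", "T")]
  gc <- 100 * sum(acgt[c("C", "G")]) / sum(acgt)
  gaps <- numeric(0)
  fts <- g$features
  if (nrow(fts) >= 2) {
    for (sid in unique(fts$scaffold_id)) {
      f <- fts[fts$scaffold_id == sid, , drop = FALSE]
      if (nrow(f) < 2) next
      f <- f[order(f$start, f$end), , drop = FALSE]
      # gap between consecutive gene spans; running max handles nesting
      hi <- cummax(f$end)
      gp <- f$start[-1] - hi[-nrow(f)] - 1L
      if (intergenic == "skip") gp <- gp[gp > 0] else gp <- pmax(gp, 0L)
      gaps <- c(gaps, gp)
    }
  }
  structure(list(
    total_length = sum(Biostrings::width(g$scaffolds)),
    gc_percent = gc,
    n_scaffolds = length(g$scaffolds),
    n_genes = nrow(fts),
    mean_intergenic = if (length(gaps)) mean(gaps) else NA_real_
  ), class = "GenomeStats")
}

#' @export
print.GenomeStats <- function(x, ...) {
  cat(sprintf("%s bp in %d scaffold(s); GC %.1f%%; %d genes; mean intergenic %s bp\n",
              format(x$total_length, big.mark = ","), x$n_scaffolds, x$gc_percent,
              x$n_genes,
              if (is.na(x$mean_intergenic)) "NA" else sprintf("%.0f", x$mean_intergenic)))
  invisible(x)
}

#' Global pairwise percent identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open -5,
#' gap extend -2 by default); identity is matches over all alignment columns,
#' gap columns included in the denominator.  Ambiguous bases never count as
#' matches.
#'
#' @param a,b Nucleotide sequences (character or [Biostrings::DNAString]).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring parameters.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 5, gap_extend = 2) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pa == sa & pa %in% c("A", "C", "G", "T"))
  100 * matches / length(pa)
}

#' Order draft scaffolds into a reference-guided pseudomolecule
#'
#' Each draft scaffold is anchored to the reference by its best local
#' alignment (BLASTN best hit); scaffolds are ordered by the reference
#' position of that anchor, reverse-complemented when it lies on the minus
#' strand, and concatenated with a 34-nt six-frame stop-codon spacer between
#' consecutive scaffolds.  Scaffolds with no anchor of at least
#' `min_anchor_score` are appended at the end in input order and flagged
#' unplaced.
#'
#' @param draft,reference [genome_record()]s; `reference` supplies the
#'   ordering coordinates.
#' @param min_anchor_score Minimum BLASTN raw score for a placement anchor.
#' @param spacer Join spacer; the default contains stops in all six frames.
#' @return A list with `sequence` (a [Biostrings::DNAString] pseudomolecule)
#'   and `offsets` (data.frame: `scaffold_id`, `start`, `orientation`,
#'   `placed`), plus the `spacer` used.
#' @export
build_pseudomolecule <- function(draft, reference, min_anchor_score = 100,
                                 spacer = PSEUDOMOLECULE_SPACER) {
  if (length(draft$scaffolds) == 0) stop("draft has no scaffolds")
  if (length(reference$scaffolds) == 0 ||
        sum(Biostrings::width(reference$scaffolds)) == 0) stop("reference is empty")
  ids <- names(draft$scaffolds)
  if (length(ids) == 1) {
    anchors <- NULL
  } else {
    anchors <- .best_hits(.blast_search(draft$scaffolds, reference$scaffolds, "blastn"))
  }
  ref_order <- stats::setNames(seq_along(reference$scaffolds), names(reference$scaffolds))
  place <- data.frame(scaffold_id = ids, placed = FALSE,
                      orientation = "+", ref_idx = NA_real_, ref_pos = NA_real_,
                      stringsAsFactors = FALSE)
  if (!is.null(anchors) && nrow(anchors) > 0) {
    anchors <- anchors[anchors$score >= min_anchor_score, , drop = FALSE]
    for (i in seq_len(nrow(anchors))) {
      j <- match(anchors$qseqid[i], place$scaffold_id)
      place$placed[j] <- TRUE
      place$orientation[j] <- if (anchors$sstart[i] <= anchors$send[i]) "+" else "-"
      place$ref_idx[j] <- ref_order[[anchors$sseqid[i]]]
      place$ref_pos[j] <- min(anchors$sstart[i], anchors$send[i])
    }
  } else if (length(ids) == 1) {
    place$placed <- TRUE
  }
  ord <- c(which(place$placed)[order(place$ref_idx[place$placed],
                                     place$ref_pos[place$placed])],
           which(!place$placed))
  place <- place[ord, , drop = FALSE]
  pieces <- character(length(ids))
  starts <- integer(length(ids))
  pos <- 1L
  for (k in seq_along(ids)) {
    s <- draft$scaffolds[[place$scaffold_id[k]]]
    if (place$orientation[k] == "-") s <- Biostrings::reverseComplement(s)
    pieces[k] <- as.character(s)
    starts[k] <- pos
    pos <- pos + length(s) + nchar(spacer)
  }
  list(sequence = Biostrings::DNAString(paste(pieces, collapse = spacer)),
       offsets = data.frame(scaffold_id = place$scaffold_id, start = starts,
                            orientation = place$orientation, placed = place$placed,
                            stringsAsFactors = FALSE),
       spacer = spacer)
}
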