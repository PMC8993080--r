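#' Trim random nucleotides from both ends of footprint reads
#'
#' Library preparation adds four random nucleotides to each end of a
#' footprint read; they are removed before any length accounting. Reads too
#' short to contain at least one nucleotide after trimming are rejected.
#'
#' @param reads character vector of read sequences.
#' @param n_each_end nucleotides to remove from each end (default 4).
#' @return list with `seq` (trimmed sequences, `NA` for rejected reads) and
#'   `n_rejected`.
#' @examples
#' trim_random_nt(c("AAAACGTACGTACGTTTTT"))
#' @export
trim_random_nt <- function(reads, n_each_end = 4) {
  stopifnot(n_each_end >= 0)
  len <- nchar(reads)
  ok <- len >= 2 * n_each_end + 1
  out <- rep(NA_character_, length(reads))
  out[ok] <- substr(reads[ok], n_each_end + 1, len[ok] - n_each_end)
  list(seq = out, n_rejected = sum(!ok))
}

#' Retain footprint alignments within a read-length window
#'
#' Ribosome-protected fragments are expected between `min_len` and
#' `max_len` nucleotides (inclusive at both ends); anything outside is
#' discarded as nuclease artefact or contaminant.
#'
#' @param alignments data frame with at least a `length` column.
#' @param min_len,max_len inclusive window, default 25-35 nt.
#' @return list with `kept` (filtered data frame) and `n_dropped`.
#' @export
length_filter <- function(alignments, min_len = 25, max_len = 35) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  keep <- alignments$length >= min_len & alignments$length <= max_len
  list(kept = alignments[keep, , drop = FALSE], n_dropped = sum(!keep))
}

#' Flag alignments whose 5' end falls inside the ORF offset window
#'
#' A footprint is attributed to an ORF when its 5' end lies between
#' `orf_start - start_offset` and `orf_stop - stop_offset`, both bounds
#' inclusive: 12 nt upstream of the start codon and 15 nt upstream of the
#' stop codon are the distances from a read's 5' end to the decoded codon
#' (the P-site offset) at the ORF boundaries. Coordinates are 0-based in
#' transcript space; `orf_start`/`orf_stop` are the first nucleotide of the
#' start and stop codons.
#'
#' @param alignments data frame (transcript_id, five_prime_pos, ...).
#' @param orfs ORF annotation data frame (transcript_id, gene_id,
#'   orf_start, orf_stop).
#' @param start_offset,stop_offset 5'-end offsets in nt (defaults 12 and
#'   15).
#' @return logical vector, one element per alignment; `NA` (with a warning)
#'   where the transcript has no annotation.
#' @export
assign_to_orf <- function(alignments, orfs, start_offset = 12,
                          stop_offset = 15) {
  idx <- match(alignments$transcript_id, orfs$transcript_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " alignment(s) on unannotated transcripts skipped")
  lo <- orfs$orf_start[idx] - start_offset
  hi <- orfs$orf_stop[idx] - stop_offset
  alignments$five_prime_pos >= lo & alignments$five_prime_pos <= hi
}

#' Count footprints per gene from multi-mapped alignments
#'
#' Applies the length filter and the ORF offset window, then resolves
#' multi-mapping: a read contributes one count to a gene if and only if it
#' has at least one in-ORF alignment and all of its in-ORF alignments hit
#' ORFs of isoforms of that single gene; reads whose in-ORF alignments span
#' two or more genes are discarded.
#'
#' @param alignments data frame with read_id, transcript_id,
#'   five_prime_pos, length (all alignments of each read).
#' @param orfs ORF annotation data frame.
#' @param min_len,max_len retained read-length window.
#' @param start_offset,stop_offset ORF-window offsets.
#' @param genes optional character vector fixing the output gene universe
#'   (defaults to the genes in `orfs`).
#' @return named integer vector of per-gene counts; attributes
#'   `n_reads_in`, `n_dropped_length`, `n_multi_gene` carry the tally.
#' @examples
#' syn <- simulate_footprint_alignments(200, n_genes = 5, seed = 2)
#' counts <- count_per_gene(syn$alignments, syn$orfs)
#' sum(counts) <= length(unique(syn$alignments$read_id))
#' @export
count_per_gene <- function(alignments, orfs, min_len = 25, max_len = 35,
                           start_offset = 12, stop_offset = 15,
                           genes = NULL) {
  if (is.null(genes)) genes <- unique(orfs$gene_id)
  counts <- setNames(integer(length(genes)), genes)
  n_in <- length(unique(alignments$read_id))

  lf <- length_filter(alignments, min_len, max_len)
  aln <- lf$kept
  if (nrow(aln)) {
    in_orf <- assign_to_orf(aln, orfs, start_offset, stop_offset)
    aln <- aln[!is.na(in_orf) & in_orf, , drop = FALSE]
  }
  n_multi <- 0L
  if (nrow(aln)) {
    gene <- orfs$gene_id[match(aln$transcript_id, orfs$transcript_id)]
    per_read <- tapply(gene, aln$read_id, function(g) unique(g))
    uni <- lengths(per_read) == 1L
    n_multi <- sum(!uni)
    hits <- table(unlist(per_read[uni], use.names = FALSE))
    shared <- intersect(names(hits), genes)
    counts[shared] <- counts[shared] + as.integer(hits[shared])
  }
  structure(counts, n_reads_in = n_in, n_dropped_length = lf$n_dropped,
            n_multi_gene = n_multi)
}
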