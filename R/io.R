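#' Read and write count matrices and companion tables
#'
#' Count matrices travel as TSV with a `gene` column followed by one column
#' per sample; sample sheets as TSV with columns sample, genotype,
#' treatment, replicate.
#'
#' @param path file path.
#' @name count_io
NULL

#' @rdname count_io
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in ", path)
  m
}

#' @rdname count_io
#' @param m integer matrix, genes x samples.
#' @export
write_count_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname count_io
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample", "genotype", "treatment", "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing))
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  sheet
}

#' Read transcript-space footprint alignments from a BED-like TSV
#'
#' Expected columns: transcript_id, five_prime_pos (0-based), length,
#' read_id.
#'
#' @param path file path.
#' @return data frame of alignments.
#' @export
read_alignments <- function(path) {
  aln <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "five_prime_pos", "length", "read_id")
  missing <- setdiff(required, names(aln))
  if (length(missing))
    stop("alignment table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(aln$five_prime_pos < 0) || any(aln$length <= 0))
    stop("invalid alignment coordinates")
  aln
}

#' Read an ORF annotation table
#'
#' Expected columns: transcript_id, gene_id, orf_start, orf_stop (0-based
#' positions of the first nucleotide of the start and stop codons).
#'
#' @param path file path.
#' @return data frame of ORF annotations.
#' @export
read_orf_annotation <- function(path) {
  orfs <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("transcript_id", "gene_id", "orf_start", "orf_stop")
  missing <- setdiff(required, names(orfs))
  if (length(missing))
    stop("ORF table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(orfs$orf_start < 0) || any(orfs$orf_start >= orfs$orf_stop))
    stop("ORF coordinates must satisfy 0 <= orf_start < orf_stop")
  if (anyDuplicated(orfs$transcript_id))
    stop("each transcript must map to exactly one ORF record")
  orfs
}

#' Read a per-fraction qPCR Ct table
#'
#' Expected columns: fraction, ct, spike_ct; optional mrna, condition,
#' replicate, af, spike_af.
#'
#' @param path file path.
#' @return data frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("fraction", "ct", "spike_ct")
  missing <- setdiff(required, names(ct))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  ct
}

#' Read and write UV traces with their region annotations
#'
#' The trace is a two-column TSV (position, absorbance); region boundaries
#' live in a YAML sidecar mapping region name to `[lo, hi]`.
#'
#' @param trace_path,regions_path file paths.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
read_uv_trace <- function(trace_path, regions_path = NULL) {
  trace <- utils::read.delim(trace_path, stringsAsFactors = FALSE)
  if (!all(c("position", "absorbance") %in% names(trace)))
    stop("trace must have columns position, absorbance")
  if (is.unsorted(trace$position, strictly = TRUE))
    stop("trace positions must be strictly increasing")
  regions <- if (!is.null(regions_path)) {
    lapply(yaml::read_yaml(regions_path), as.numeric)
  }
  list(trace = trace, regions = regions)
}

#' @rdname trace_io
#' @param uv list with `trace` and `regions` as from [simulate_uv_trace()].
#' @export
write_uv_trace <- function(uv, trace_path, regions_path) {
  utils::write.table(uv$trace, trace_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(lapply(uv$regions, as.numeric), regions_path)
  invisible(c(trace_path, regions_path))
}
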