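#' Median-of-ratios library size factors
#'
#' For each gene with a positive geometric-mean count across samples
#' (the "reference"), compute the ratio of each sample's count to that
#' reference; the sample's size factor is the median of its ratios.
#' Dividing a column by its factor equalizes pseudo-library depth. This is
#' the standard median-ratio normalization for sequencing count matrices.
#'
#' @param m count matrix, genes x samples.
#' @return numeric vector of size factors, one per sample.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' median_ratio_size_factors(m)  # c(1, 2) / sqrt(2)
#' @export
median_ratio_size_factors <- function(m) {
  m <- as.matrix(m)
  if (!nrow(m) || !ncol(m)) stop("empty count matrix")
  log_ref <- rowMeans(log(m))               # -Inf where any count is 0
  use <- is.finite(log_ref)
  if (!any(use))
    stop("normalization impossible: no gene has positive counts in all samples")
  # median taken on the ratio scale; even counts average the two central
  # ratios arithmetically
  apply(m[use, , drop = FALSE], 2,
        function(col) stats::median(exp(log(col) - log_ref[use])))
}

#' Normalize a count matrix by its size factors
#'
#' @param m count matrix, genes x samples.
#' @param size_factors optional precomputed factors; defaults to
#'   [median_ratio_size_factors()] of `m`.
#' @return list with `normalized` (numeric matrix of counts / factor) and
#'   `size_factors`.
#' @export
normalize_counts <- function(m, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(m)
  stopifnot(length(size_factors) == ncol(m), all(size_factors > 0))
  list(normalized = sweep(as.matrix(m), 2, size_factors, "/"),
       size_factors = size_factors)
}

#' Filter genes by minimum counts in designated conditions
#'
#' A gene is removed when its per-condition summary (mean over replicates by
#' default) is below `threshold` in *any* designated condition — strictly
#' below, so a gene at exactly the threshold is retained. The canonical use
#' filters on RNA-Seq counts in the NCS-treated condition of both genotypes
#' with a threshold of 10 raw reads; a variant rule uses library-size
#' normalized counts with a threshold of 5, which is what the `m` argument
#' should then contain.
#'
#' @param m count (or normalized count) matrix, genes x samples.
#' @param samples sample sheet matching `colnames(m)`.
#' @param threshold minimum per-condition summary to retain a gene.
#' @param conditions data frame of genotype/treatment combinations to test;
#'   default NCS in both genotypes.
#' @param stat per-condition summary across replicates: "mean" or "sum".
#' @return list with `keep` (character vector of retained genes) and
#'   `removed` (data frame: gene, offending condition, value).
#' @export
low_count_filter <- function(m, samples,
                             threshold = 10,
                             conditions = data.frame(
                               genotype = c("WT", "KO"),
                               treatment = c("NCS", "NCS")),
                             stat = c("mean", "sum")) {
  stopifnot(threshold >= 0)
  stat <- match.arg(stat)
  agg <- if (stat == "mean") rowMeans else rowSums
  bad <- matrix(FALSE, nrow(m), nrow(conditions))
  vals <- matrix(NA_real_, nrow(m), nrow(conditions))
  for (k in seq_len(nrow(conditions))) {
    sel <- samples$sample[samples$genotype == conditions$genotype[k] &
                          samples$treatment == conditions$treatment[k]]
    if (!length(sel))
      stop("condition ", conditions$genotype[k], "/",
           conditions$treatment[k], " absent from sample sheet")
    vals[, k] <- agg(m[, sel, drop = FALSE])
    bad[, k] <- vals[, k] < threshold
  }
  drop <- rowSums(bad) > 0
  first_bad <- apply(bad, 1, function(b) if (any(b)) which(b)[1] else NA_integer_)
  removed <- data.frame(
    gene = rownames(m)[drop],
    condition = paste(conditions$genotype, conditions$treatment,
                      sep = "_")[first_bad[drop]],
    value = vals[cbind(which(drop), first_bad[drop])]
  )
  list(keep = rownames(m)[!drop], removed = removed)
}

#' Per-condition mean expression over replicates
#'
#' @param normalized numeric matrix of normalized counts, genes x samples.
#' @param samples sample sheet.
#' @return numeric matrix genes x conditions, condition columns named
#'   `genotype_treatment`.
#' @export
condition_means <- function(normalized, samples) {
  cond <- paste(samples$genotype, samples$treatment, sep = "_")
  groups <- split(samples$sample, cond)
  out <- vapply(groups,
                function(s) rowMeans(normalized[, s, drop = FALSE]),
                numeric(nrow(normalized)))
  rownames(out) <- rownames(normalized)
  out
}

#' Ribosome density per gene and condition
#'
#' RD is the normalized footprint level divided by the normalized mRNA
#' level of the same gene, computed here on per-condition means over
#' replicates. Genes whose mRNA mean is zero in a condition get `NA`
#' (undefined density) there.
#'
#' @param fp_norm,rna_norm normalized count matrices (genes x samples) for
#'   footprints and RNA; identical gene universes.
#' @param samples sample sheet covering both assays' samples (assay-specific
#'   sheets may be supplied via `fp_samples`/`rna_samples`).
#' @param fp_samples,rna_samples optional assay-specific sample sheets.
#' @return numeric matrix genes x conditions of RD values.
#' @export
ribosome_density <- function(fp_norm, rna_norm, samples,
                             fp_samples = samples, rna_samples = samples) {
  if (!identical(rownames(fp_norm), rownames(rna_norm)))
    stop("footprint and RNA matrices must share an identical gene universe")
  fp_mean <- condition_means(fp_norm, fp_samples)
  rna_mean <- condition_means(rna_norm, rna_samples)
  common <- intersect(colnames(fp_mean), colnames(rna_mean))
  rd <- fp_mean[, common, drop = FALSE] / rna_mean[, common, drop = FALSE]
  rd[!is.finite(rd)] <- NA_real_
  rd
}
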