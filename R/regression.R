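#' Log2 fold change between two condition means
#'
#' @param cond_a_mean,cond_b_mean normalized expression means; the result is
#'   `log2(cond_a_mean / cond_b_mean)`. Non-positive inputs yield `NA`
#'   (undefined, to be excluded from regression).
#' @return numeric vector of log2 ratios.
#' @export
delta_log2 <- function(cond_a_mean, cond_b_mean) {
  out <- log2(cond_a_mean) - log2(cond_b_mean)
  out[!is.finite(out) | cond_a_mean <= 0 | cond_b_mean <= 0] <- NA_real_
  out
}

#' Build the per-genotype (delta mRNA, delta RD) table
#'
#' For one genotype, computes the NCS-vs-control log2 fold change of the
#' normalized mRNA mean and of the ribosome density for every gene.
#'
#' @param rd RD matrix from [ribosome_density()] (columns
#'   `genotype_treatment`).
#' @param rna_mean condition-mean matrix of normalized RNA counts.
#' @param genotype `"WT"` or `"KO"`.
#' @param treatment_num,treatment_den numerator / denominator treatments of
#'   the contrast.
#' @return data frame: gene, delta_mrna, delta_rd (rows with undefined
#'   values kept, flagged `NA`).
#' @export
delta_table <- function(rd, rna_mean, genotype = "WT",
                        treatment_num = "NCS", treatment_den = "control") {
  num <- paste(genotype, treatment_num, sep = "_")
  den <- paste(genotype, treatment_den, sep = "_")
  stopifnot(num %in% colnames(rd), den %in% colnames(rd),
            num %in% colnames(rna_mean), den %in% colnames(rna_mean))
  data.frame(
    gene = rownames(rd),
    delta_mrna = delta_log2(rna_mean[, num], rna_mean[, den]),
    delta_rd = delta_log2(rd[, num], rd[, den]),
    stringsAsFactors = FALSE
  )
}

#' Ordinary least squares fit of the passive kinetic trend
#'
#' Fits `delta_rd = a + b * delta_mrna` by closed-form OLS and reports the
#' Pearson correlation of the two coordinates. The negative slope captures
#' the kinetic (passive) relation between RD change and mRNA change that
#' holds for the bulk of genes; actively regulated genes appear as outliers
#' from this line.
#'
#' @param pairs data frame with columns delta_mrna, delta_rd (rows with
#'   `NA` in either are dropped).
#' @return object of class `passive_regression`: list with intercept `a`,
#'   slope `b`, `pearson_r`, `n`, `residual_sd` (vertical units, `n - 2`
#'   denominator) and `residual_sd_orthogonal`.
#' @export
fit_passive_regression <- function(pairs) {
  x <- pairs$delta_mrna
  y <- pairs$delta_rd
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite (delta mRNA, delta RD) pairs")
  if (length(unique(x)) < 2) stop("degenerate regression: all delta_mrna equal")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  syy <- sum((y - ybar)^2)
  b <- sxy / sxx
  a <- ybar - b * xbar
  r <- if (syy > 0) sxy / sqrt(sxx * syy) else 0
  res <- y - a - b * x
  res_sd <- sqrt(sum(res^2) / (n - 2))
  structure(
    list(a = a, b = b, pearson_r = r, n = n,
         residual_sd = res_sd,
         residual_sd_orthogonal = res_sd / sqrt(1 + b^2)),
    class = "passive_regression"
  )
}

#' @export
print.passive_regression <- function(x, ...) {
  cat(sprintf(
    "Passive trend: delta_RD = %.4f %+.4f * delta_mRNA  (R_P = %.3f, n = %d)\n",
    x$a, x$b, x$pearson_r, x$n))
  cat(sprintf("  residual SD: %.4f vertical, %.4f orthogonal\n",
              x$residual_sd, x$residual_sd_orthogonal))
  invisible(x)
}

#' Signed distance of points from the fitted passive trend
#'
#' Vertical mode returns the residual `y - a - b x`; orthogonal mode the
#' Euclidean distance to the line, `residual / sqrt(1 + b^2)`. Both are
#' signed, positive above the line (RD higher than the passive expectation).
#'
#' @param pairs data frame with delta_mrna, delta_rd (or numeric x when `y`
#'   given).
#' @param fit a `passive_regression`.
#' @param mode `"orthogonal"` (default) or `"vertical"`.
#' @param y optional numeric y when `pairs` is a numeric x vector.
#' @return numeric vector of signed distances in log2 units.
#' @export
signed_distance <- function(pairs, fit, mode = c("orthogonal", "vertical"),
                            y = NULL) {
  mode <- match.arg(mode)
  if (is.null(y)) {
    x <- pairs$delta_mrna
    y <- pairs$delta_rd
  } else {
    x <- pairs
  }
  res <- y - fit$a - fit$b * x
  if (mode == "orthogonal") res / sqrt(1 + fit$b^2) else res
}

.class_levels <- c("up_wt_only", "up_ko_only", "up_both",
                   "down_wt_only", "down_ko_only", "down_both", "none")

#' Classify genes from their per-genotype distances to the passive trend
#'
#' A gene is translationally up-regulated in a genotype when its signed
#' distance from that genotype's regression line exceeds `threshold`
#' (strictly), down-regulated below `-threshold`, and unremarkable
#' otherwise; the two genotype calls combine into a seven-way class
#' (up/down in WT only, in KO only, or in both, else `"none"`). In the rare
#' case of opposite calls in the two genotypes the up call takes
#' precedence for the label; both directional calls remain visible in the
#' per-genotype distances.
#'
#' @param d_wt,d_ko signed distances in WT and KO; `NA` in one genotype
#'   classifies on the other alone (provenance flagged via the
#'   `single_genotype` attribute).
#' @param threshold positive classification threshold in log2 units
#'   (default 1).
#' @return character vector of classes, attribute `single_genotype` marking
#'   genes classified from one genotype only.
#' @examples
#' classify_gene(1.5, 0.2)   # "up_wt_only"
#' classify_gene(1.2, 1.3)   # "up_both"
#' classify_gene(1.0, 0.0)   # "none": strict inequality at the threshold
#' @export
classify_gene <- function(d_wt, d_ko, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0")
  n <- max(length(d_wt), length(d_ko))
  d_wt <- rep_len(as.numeric(d_wt), n)
  d_ko <- rep_len(as.numeric(d_ko), n)
  up_wt <- !is.na(d_wt) & d_wt > threshold
  up_ko <- !is.na(d_ko) & d_ko > threshold
  dn_wt <- !is.na(d_wt) & d_wt < -threshold
  dn_ko <- !is.na(d_ko) & d_ko < -threshold
  cls <- rep("none", n)
  cls[up_wt & !up_ko] <- "up_wt_only"
  cls[up_ko & !up_wt] <- "up_ko_only"
  cls[up_wt & up_ko] <- "up_both"
  cls[dn_wt & !dn_ko & !(up_wt | up_ko)] <- "down_wt_only"
  cls[dn_ko & !dn_wt & !(up_wt | up_ko)] <- "down_ko_only"
  cls[dn_wt & dn_ko] <- "down_both"
  structure(cls, single_genotype = is.na(d_wt) != is.na(d_ko))
}

#' Project external points onto a fitted passive trend
#'
#' Evaluates the vertical residual of external (x, y) points — e.g. nascent
#' protein log2 fold differences against mRNA log2 fold differences — with
#' respect to a regression fitted on a reference point set. Points above
#' the line have positive residuals.
#'
#' @param points data frame with columns x and y.
#' @param fit a `passive_regression`.
#' @return numeric vector of signed vertical residuals.
#' @export
project_external_points <- function(points, fit) {
  points$y - fit$a - fit$b * points$x
}

#' Overlap of a classified gene set with a reference list
#'
#' Counts the intersection and computes the upper hypergeometric tail
#' probability of observing at least that overlap when `length(classified)`
#' genes are drawn without replacement from a universe containing the
#' reference list.
#'
#' @param classified character vector of gene ids (e.g. the up-in-WT-only
#'   group).
#' @param reference character vector of reference gene ids (e.g. a curated
#'   target-gene list).
#' @param universe_size size of the gene universe both sets come from.
#' @return list with `overlap`, `n_classified`, `n_reference`,
#'   `universe_size`, `p_value`.
#' @export
overlap_with_gene_list <- function(classified, reference, universe_size) {
  classified <- unique(classified)
  reference <- unique(reference)
  if (!length(reference)) stop("reference list is empty")
  if (universe_size < max(length(classified), length(reference)))
    stop("universe smaller than one of the sets")
  k <- length(classified)
  m <- length(reference)
  ov <- length(intersect(classified, reference))
  p <- if (k == 0) 1 else
    stats::phyper(ov - 1, m, universe_size - m, k, lower.tail = FALSE)
  list(overlap = ov, n_classified = k, n_reference = m,
       universe_size = universe_size, p_value = p)
}
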