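# Independent brute-force oracles the tests compare the implementation to.
# These deliberately avoid the package's own code paths.

# Passive RD ratio by numerical integration over the transcript-age
# distribution: n(a, t) = k(t - a) exp(-d a), load(a) = min(a/T, 1).
oracle_passive_ratio <- function(fold_change, decay_rate, fill_time,
                                 sample_time) {
  d <- decay_rate; T <- fill_time; t <- sample_time
  load <- function(a) if (T > 0) pmin(a / T, 1) else rep(1, length(a))
  horizon <- t + 60 / d  # old-transcript tail is negligible beyond this
  piecewise <- function(f, breaks) {
    breaks <- sort(unique(pmin(pmax(breaks, 0), horizon)))
    sum(vapply(seq_len(length(breaks) - 1), function(i) {
      stats::integrate(f, breaks[i], breaks[i + 1], rel.tol = 1e-12,
                       abs.tol = 0)$value
    }, numeric(1)))
  }
  rate <- function(a) ifelse(a < t, fold_change, 1)  # synthesis at birth
  kinks <- c(0, T, t, horizon)
  num_t <- piecewise(function(a) rate(a) * load(a) * exp(-d * a), kinks)
  den_t <- piecewise(function(a) rate(a) * exp(-d * a), kinks)
  num_ss <- piecewise(function(a) load(a) * exp(-d * a), kinks)
  den_ss <- piecewise(function(a) exp(-d * a), kinks)
  (num_t / den_t) / (num_ss / den_ss)
}

# Per-read re-evaluation of the footprint counting rules.
oracle_count_reads <- function(alignments, orfs, min_len = 25, max_len = 35,
                               start_offset = 12, stop_offset = 15) {
  counts <- setNames(integer(length(unique(orfs$gene_id))),
                     unique(orfs$gene_id))
  for (rid in unique(alignments$read_id)) {
    rows <- alignments[alignments$read_id == rid, , drop = FALSE]
    genes <- character(0)
    for (i in seq_len(nrow(rows))) {
      if (rows$length[i] < min_len || rows$length[i] > max_len) next
      ann <- orfs[orfs$transcript_id == rows$transcript_id[i], ]
      if (!nrow(ann)) next
      lo <- ann$orf_start - start_offset
      hi <- ann$orf_stop - stop_offset
      if (rows$five_prime_pos[i] >= lo && rows$five_prime_pos[i] <= hi)
        genes <- c(genes, ann$gene_id)
    }
    genes <- unique(genes)
    if (length(genes) == 1) counts[genes] <- counts[genes] + 1L
  }
  counts
}

# Median-of-ratios size factors by explicit enumeration and a sort-based
# median.
oracle_size_factors <- function(m) {
  n_samp <- ncol(m)
  ref <- apply(m, 1, function(row) prod(row)^(1 / n_samp))
  vapply(seq_len(n_samp), function(j) {
    r <- sort(m[ref > 0, j] / ref[ref > 0])
    k <- length(r)
    if (k %% 2 == 1) r[(k + 1) / 2] else (r[k / 2] + r[k / 2 + 1]) / 2
  }, numeric(1))
}

# Upper hypergeometric tail by direct log-binomial summation.
oracle_hyper_tail <- function(observed, n_marked, universe, n_drawn) {
  i <- observed:min(n_marked, n_drawn)
  sum(exp(lchoose(n_marked, i) + lchoose(universe - n_marked, n_drawn - i) -
            lchoose(universe, n_drawn)))
}

# Small random count matrix with no all-zero row in at least one gene.
random_count_matrix <- function(n_genes, n_samples) {
  m <- matrix(rpois(n_genes * n_samples, lambda = 50), n_genes, n_samples)
  m[1, ] <- m[1, ] + 1L  # guarantee a usable reference gene
  rownames(m) <- paste0("g", seq_len(n_genes))
  colnames(m) <- paste0("s", seq_len(n_samples))
  m
}
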