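#' Configuration of the synthetic Ribo-Seq / RNA-Seq experiment
#'
#' Describes a simulated experiment of 4 conditions (WT/KO genotype crossed
#' with control/NCS treatment) with `n_replicates` biological replicates per
#' condition and paired RNA-Seq and footprint libraries. Control samples are
#' taken at the pre-induction steady state; NCS samples `sample_time` after a
#' per-gene step change in transcription rate, so induced genes carry the
#' passive kinetic depression of ribosome density computed by
#' [passive_rd_ratio_vec()].
#'
#' Transcriptional fold changes are log-normal: `log2 F ~ N(0,
#' fold_change_sd_log2)` and are shared between genotypes (the classifier
#' contrast is NCS vs control within a genotype). Active translational
#' regulation is planted on a fraction of genes as a log2 offset `delta`
#' multiplying the footprint expectation in the NCS condition of the
#' affected genotype(s).
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per condition (>= 2).
#' @param library_size expected sequenced reads per sample (single number or
#'   one per sample); applied to RNA and footprint libraries alike.
#' @param fold_change_sd_log2 SD of the per-gene log2 transcriptional fold
#'   change.
#' @param nb_dispersion negative-binomial dispersion shared across genes
#'   (`variance = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param decay_meanlog,decay_sdlog log-normal parameters (natural log) of
#'   the per-gene mRNA decay rate, per hour.
#' @param fill_time effective ribosome-loading timescale (hours), shared
#'   across genes.
#' @param sample_time measurement time after induction (hours); matches the
#'   4 h treatment the design emulates.
#' @param density_meanlog,density_sdlog log-normal parameters of the
#'   per-gene steady ribosome density (ribosomes/transcript).
#' @param abundance_sdlog SD (natural log) of baseline relative abundances.
#' @param planted_frac fraction of genes receiving an active translational
#'   offset (0 disables planting).
#' @param planted_delta magnitude (log2 units) of the planted offset.
#' @param planted_classes character vector of ground-truth classes to cycle
#'   through when planting; any of `"up_wt_only"`, `"up_ko_only"`,
#'   `"up_both"`, `"down_wt_only"`, `"down_ko_only"`, `"down_both"`.
#' @param seed integer seed; the same seed yields identical tables.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_replicates = 4,
                              library_size = 5e6,
                              fold_change_sd_log2 = 1.5,
                              nb_dispersion = 0.05,
                              decay_meanlog = log(0.25),
                              decay_sdlog = 0.4,
                              fill_time = 6,
                              sample_time = 4,
                              density_meanlog = log(5),
                              density_sdlog = 0.5,
                              abundance_sdlog = 1.2,
                              planted_frac = 0,
                              planted_delta = 2,
                              planted_classes = c("up_wt_only", "up_ko_only",
                                                  "up_both", "down_wt_only",
                                                  "down_ko_only", "down_both"),
                              seed = 1L) {
  stopifnot(
    n_genes >= 1, n_replicates >= 2,
    all(library_size > 0),
    fold_change_sd_log2 >= 0,
    nb_dispersion >= 0,
    fill_time >= 0, sample_time >= 0,
    planted_frac >= 0, planted_frac <= 1,
    planted_delta >= 0
  )
  planted_classes <- match.arg(planted_classes, several.ok = TRUE)
  structure(
    list(n_genes = as.integer(n_genes),
         n_replicates = as.integer(n_replicates),
         library_size = library_size,
         fold_change_sd_log2 = fold_change_sd_log2,
         nb_dispersion = nb_dispersion,
         decay_meanlog = decay_meanlog, decay_sdlog = decay_sdlog,
         fill_time = fill_time, sample_time = sample_time,
         density_meanlog = density_meanlog, density_sdlog = density_sdlog,
         abundance_sdlog = abundance_sdlog,
         planted_frac = planted_frac, planted_delta = planted_delta,
         planted_classes = planted_classes,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

.condition_grid <- function(n_replicates) {
  grid <- expand.grid(
    replicate = seq_len(n_replicates),
    treatment = c("control", "NCS"),
    genotype = c("WT", "KO"),
    stringsAsFactors = FALSE
  )[, c("genotype", "treatment", "replicate")]
  grid$sample <- with(grid, paste(genotype, treatment, replicate, sep = "_"))
  grid
}

.nb_draw <- function(mu, dispersion) {
  x <- if (dispersion <= 0) {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), size = 1 / dispersion, mu = mu)
  }
  as.integer(x)
}

#' Simulate paired RNA-Seq and footprint count tables with ground truth
#'
#' Draws per-gene kinetic parameters, computes expected mRNA levels and
#' ribosome densities in every condition under the loading-kinetics model,
#' plants active translational offsets on a configured subset of genes, and
#' samples negative-binomial counts scaled to the configured library sizes.
#'
#' Expected RNA counts are proportional to the simulated transcript level;
#' expected footprint counts to transcript level x ribosome density, where
#' the density in the NCS condition carries the passive kinetic factor and
#' `2^delta` for planted genes.
#'
#' @param cfg a [simulation_config()].
#' @return a list with elements `rna` and `fp` (integer matrices, genes x
#'   samples), `samples` (sample sheet: sample, genotype, treatment,
#'   replicate), and `truth` (per-gene data frame: gene, log2 fold change,
#'   decay rate, steady density, passive RD ratio in the NCS condition,
#'   planted `delta_wt`/`delta_ko`, and ground-truth `class`).
#' @examples
#' sim <- simulate_count_tables(simulation_config(n_genes = 50, seed = 7))
#' dim(sim$rna)
#' table(sim$truth$class)
#' @export
simulate_count_tables <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("gene%05d", seq_len(n))

  abundance <- rlnorm(n, meanlog = 0, sdlog = cfg$abundance_sdlog)
  lfc <- rnorm(n, 0, cfg$fold_change_sd_log2)      # log2 transcriptional FC
  fold <- 2^lfc
  decay <- rlnorm(n, cfg$decay_meanlog, cfg$decay_sdlog)
  density <- rlnorm(n, cfg$density_meanlog, cfg$density_sdlog)

  # planted active regulation: log2 offsets per genotype, NCS only
  delta_wt <- delta_ko <- numeric(n)
  class <- rep("none", n)
  n_planted <- round(cfg$planted_frac * n)
  if (n_planted > 0) {
    planted <- sample.int(n, n_planted)
    cls <- rep_len(cfg$planted_classes, n_planted)
    sgn <- ifelse(startsWith(cls, "up"), 1, -1)
    in_wt <- grepl("wt_only|both", cls)
    in_ko <- grepl("ko_only|both", cls)
    delta_wt[planted] <- ifelse(in_wt, sgn * cfg$planted_delta, 0)
    delta_ko[planted] <- ifelse(in_ko, sgn * cfg$planted_delta, 0)
    class[planted] <- cls
  }

  # transcript level: steady state before, kinetic level at sample_time after
  mrna_control <- abundance
  mrna_ncs <- abundance *
    (fold * (-expm1(-decay * cfg$sample_time)) + exp(-decay * cfg$sample_time))
  passive <- passive_rd_ratio_vec(fold, decay, cfg$fill_time, cfg$sample_time)

  samples <- .condition_grid(cfg$n_replicates)
  n_samp <- nrow(samples)
  libsize <- rep_len(cfg$library_size, n_samp)

  rna <- fp <- matrix(0L, n, n_samp, dimnames = list(genes, samples$sample))
  for (j in seq_len(n_samp)) {
    ncs <- samples$treatment[j] == "NCS"
    wt <- samples$genotype[j] == "WT"
    level <- if (ncs) mrna_ncs else mrna_control
    rd <- density * (if (ncs) passive * 2^(if (wt) delta_wt else delta_ko) else 1)
    mu_rna <- level / sum(level) * libsize[j]
    mu_fp <- level * rd / sum(level * rd) * libsize[j]
    rna[, j] <- .nb_draw(mu_rna, cfg$nb_dispersion)
    fp[, j] <- .nb_draw(mu_fp, cfg$nb_dispersion)
  }

  truth <- data.frame(
    gene = genes,
    abundance = abundance,
    log2_fold_change = lfc,
    decay_rate = decay,
    steady_density = density,
    passive_rd_ratio = passive,
    delta_wt = delta_wt,
    delta_ko = delta_ko,
    class = class,
    stringsAsFactors = FALSE
  )
  list(rna = rna, fp = fp, samples = samples, truth = truth, config = cfg)
}

#' Simulate a per-fraction RT-qPCR Ct table for one mRNA
#'
#' Inverts the spike-in normalization model: given target per-fraction
#' weights, the Ct of fraction i is set so that
#' `AF^(-Ct_i) / AF^(-spike_ct)` equals the normalized weight, plus Gaussian
#' cycle noise. Fractions with zero weight get `Ct = Inf` (no amplification).
#'
#' @param weights non-negative per-fraction quantities (length = number of
#'   fractions, conventionally 13); not all zero.
#' @param spike_ct Ct of the spike-in control in every fraction.
#' @param amplification_factor per-cycle gain of the assay, in (1, 2].
#' @param noise_sd SD of Gaussian noise added to each Ct, in cycles.
#' @param seed optional integer seed.
#' @return data frame with columns fraction, ct, spike_ct, af.
#' @export
simulate_fraction_cts <- function(weights, spike_ct = 20,
                                  amplification_factor = 2,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(length(weights) >= 1, all(weights >= 0),
            noise_sd >= 0, spike_ct >= 0)
  if (all(weights == 0)) stop("weights must not be all zero")
  if (amplification_factor <= 1 || amplification_factor > 2)
    stop("amplification_factor must be in (1, 2]")
  if (!is.null(seed)) set.seed(seed)
  w <- weights / sum(weights)
  ct <- spike_ct - log(w) / log(amplification_factor)  # Inf where w == 0
  noisy <- is.finite(ct)
  ct[noisy] <- ct[noisy] + rnorm(sum(noisy), 0, noise_sd)
  data.frame(fraction = seq_along(weights), ct = ct,
             spike_ct = spike_ct, af = amplification_factor)
}

#' Simulate a polysome-profile UV absorbance trace
#'
#' Builds a 254 nm absorbance trace with a raised-cosine peak in each
#' annotated region whose continuous area equals the requested target, a
#' constant baseline and optional Gaussian noise. Integrating the trace over
#' the regions (after baseline subtraction) recovers the target areas.
#'
#' @param monosome_area,polysome_area target areas (absorbance x position
#'   units); non-negative, not both zero.
#' @param baseline constant absorbance offset added to the whole trace.
#' @param noise_sd SD of Gaussian noise per point.
#' @param seed optional integer seed.
#' @param positions positions at which absorbance is evaluated.
#' @param regions named list with `monosome` and `polysome` `(lo, hi)`
#'   boundaries.
#' @return list with `trace` (data frame: position, absorbance), `regions`,
#'   and `baseline`.
#' @export
simulate_uv_trace <- function(monosome_area = 30, polysome_area = 70,
                              baseline = 0, noise_sd = 0, seed = NULL,
                              positions = seq(0, 80, by = 0.05),
                              regions = list(monosome = c(12, 28),
                                             polysome = c(32, 76))) {
  stopifnot(monosome_area >= 0, polysome_area >= 0, noise_sd >= 0)
  if (monosome_area == 0 && polysome_area == 0)
    stop("at least one region area must be positive")
  if (!is.null(seed)) set.seed(seed)
  hann_peak <- function(x, lo, hi, area) {
    inside <- x >= lo & x <= hi
    y <- numeric(length(x))
    # 0.5*(1 - cos) pulse integrates to width/2 over [lo, hi]
    y[inside] <- (2 * area / (hi - lo)) *
      0.5 * (1 - cos(2 * pi * (x[inside] - lo) / (hi - lo)))
    y
  }
  abs254 <- baseline +
    hann_peak(positions, regions$monosome[1], regions$monosome[2], monosome_area) +
    hann_peak(positions, regions$polysome[1], regions$polysome[2], polysome_area) +
    rnorm(length(positions), 0, noise_sd)
  list(trace = data.frame(position = positions, absorbance = abs254),
       regions = regions, baseline = baseline)
}

#' Simulate transcript-space footprint alignments with a known per-read truth
#'
#' Generates an ORF annotation (several isoforms per gene) and a set of
#' aligned footprint reads covering all the cases the counting rules must
#' handle: unique in-ORF reads, reads hitting several isoforms of one gene,
#' reads spanning two genes, out-of-window reads, and out-of-range lengths.
#'
#' @param n_reads number of reads.
#' @param n_genes number of genes (2 isoforms each).
#' @param seed integer seed.
#' @param min_len,max_len sampled read-length range (deliberately wider than
#'   the 25-35 nt retention window so the length filter is exercised).
#' @return list with `alignments` (read_id, transcript_id, five_prime_pos,
#'   length) and `orfs` (transcript_id, gene_id, orf_start, orf_stop).
#' @export
simulate_footprint_alignments <- function(n_reads = 1000, n_genes = 20,
                                          seed = 1L, min_len = 22,
                                          max_len = 38) {
  set.seed(seed)
  orfs <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    k <- 2
    data.frame(
      transcript_id = sprintf("g%03d_t%d", g, seq_len(k)),
      gene_id = sprintf("g%03d", g),
      orf_start = sample(30:80, k, replace = TRUE),
      orf_stop = NA_integer_
    )
  }))
  orfs$orf_stop <- orfs$orf_start + 3 * sample(100:400, nrow(orfs), TRUE)

  recs <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    read_id <- sprintf("read%05d", i)
    len <- sample(min_len:max_len, 1)
    kind <- sample(c("unique", "iso_multi", "two_genes", "outside"), 1,
                   prob = c(0.55, 0.2, 0.1, 0.15))
    pick <- function(tx) {
      ann <- orfs[orfs$transcript_id == tx, ]
      lo <- ann$orf_start - 12L
      hi <- ann$orf_stop - 15L
      pos <- if (kind == "outside") {
        sample(c(max(0L, lo - sample(1:20, 1)), hi + sample(1:20, 1)), 1)
      } else {
        sample(lo:hi, 1)
      }
      data.frame(read_id = read_id, transcript_id = tx,
                 five_prime_pos = pos, length = len)
    }
    recs[[i]] <- switch(kind,
      unique = pick(sample(orfs$transcript_id, 1)),
      iso_multi = {
        g <- sample(orfs$gene_id, 1)
        do.call(rbind, lapply(orfs$transcript_id[orfs$gene_id == g], pick))
      },
      two_genes = {
        gs <- sample(unique(orfs$gene_id), 2)
        do.call(rbind, lapply(
          vapply(gs, function(g) orfs$transcript_id[orfs$gene_id == g][1], ""),
          pick))
      },
      outside = pick(sample(orfs$transcript_id, 1))
    )
  }
  list(alignments = do.call(rbind, recs), orfs = orfs)
}

#' Write simulated count tables and ground truth to TSV
#'
#' @param sim result of [simulate_count_tables()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_count_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("rna_counts.tsv", "fp_counts.tsv",
                            "samples.tsv", "truth.tsv"))
  write_count_matrix(sim$rna, paths[1])
  write_count_matrix(sim$fp, paths[2])
  utils::write.table(sim$samples, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
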