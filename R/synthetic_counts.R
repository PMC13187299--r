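#' Generate per-gene decay truth for a synthetic shutoff timecourse
#'
#' Draws gene half-lives log-normally (median `half_life_log_median_h`,
#' log-scale sd `half_life_log_sd`), converts them to decay rates
#' kd = ln(2) / half-life, and draws initial abundances log-normally, scaled
#' so that expected total counts at t = 0 equal `depth`. The default design
#' mirrors a 6-h transcription-shutoff timecourse sampled at 0, 2, 4 and 6 h
#' with two biological replicates.
#'
#' @param n_genes Number of genes (>= 1).
#' @param half_life_log_median_h Median half-life in hours (> 0); the default
#'   5.6 h matches typical interphase measurements.
#' @param half_life_log_sd Log-scale standard deviation of half-lives.
#' @param frac_lncRNA Fraction of genes labelled `lncRNA` (rest `coding`).
#' @param seed Integer seed; the truth is deterministic given the seed.
#' @param times_h Strictly increasing timepoints starting at 0.
#' @param n_replicates Replicates per timepoint.
#' @param depth Expected total counts per sample at t = 0.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson noise.
#' @return An object of class `synthetic_truth`: list with `genes` (data
#'   frame: gene_id, gene_class, a0_true, kd_true, half_life_true_h) and the
#'   design fields.
#' @export
generate_decay_truth <- function(n_genes, half_life_log_median_h = 5.6,
                                 half_life_log_sd = 0.8, frac_lncRNA = 0.1,
                                 seed = 1L, times_h = c(0, 2, 4, 6),
                                 n_replicates = 2L, depth = 2e6,
                                 dispersion = 0.05) {
  if (half_life_log_median_h <= 0) stop("half_life_log_median_h must be > 0")
  stopifnot(n_genes >= 1, half_life_log_sd >= 0, depth > 0, dispersion >= 0,
            frac_lncRNA >= 0, frac_lncRNA <= 1)
  if (times_h[1] != 0 || is.unsorted(times_h, strictly = TRUE)) {
    stop("times_h must be strictly increasing and start at 0")
  }
  set.seed(seed)
  hl <- exp(rnorm(n_genes, mean = log(half_life_log_median_h),
                  sd = half_life_log_sd))
  kd <- log(2) / hl
  a0 <- rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  a0 <- a0 / sum(a0) * depth
  n_lnc <- round(frac_lncRNA * n_genes)
  cls <- c(rep("lncRNA", n_lnc), rep("coding", n_genes - n_lnc))
  genes <- data.frame(
    gene_id = sprintf("gene_%05d", seq_len(n_genes)),
    gene_class = cls,
    a0_true = a0, kd_true = kd, half_life_true_h = hl,
    stringsAsFactors = FALSE
  )
  structure(
    list(genes = genes, seed = as.integer(seed), times_h = times_h,
         n_replicates = as.integer(n_replicates), depth = depth,
         dispersion = dispersion),
    class = "synthetic_truth"
  )
}

#' Simulate a shutoff timecourse count matrix from known decay truth
#'
#' Expected count of gene g in sample (t, replicate) is
#' `depth_scale(sample) * a0_true(g) * exp(-kd_true(g) * t)`; spike-in genes
#' have constant expected abundance `spike_abundance`. Counts are drawn
#' negative-binomially with the truth's dispersion (Poisson when 0); the
#' per-sample depth scale is gamma-distributed with mean 1 and coefficient of
#' variation `depth_jitter_cv`. Deterministic given `seed`.
#'
#' @param truth A `synthetic_truth` object.
#' @param spike_config List/vector with `n_spikes` and `spike_abundance`
#'   (expected counts per spike gene; default 1% of depth split evenly).
#' @param depth_jitter_cv Coefficient of variation of per-sample depth (>= 0).
#' @param seed Integer seed for the sampling noise (defaults to
#'   `truth$seed + 1`).
#' @return List with `matrix` (a [timecourse_counts()] including spike rows)
#'   and `truth` (the input truth, spike rows appended).
#' @export
simulate_counts <- function(truth, spike_config = list(n_spikes = 10),
                            depth_jitter_cv = 0.05, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), depth_jitter_cv >= 0)
  n_spikes <- as.integer(spike_config$n_spikes)
  spike_ab <- spike_config$spike_abundance
  if (is.null(spike_ab)) spike_ab <- 0.01 * truth$depth / max(n_spikes, 1)
  set.seed(seed)

  samples <- expand.grid(replicate = seq_len(truth$n_replicates),
                         time_h = truth$times_h,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[order(samples$time_h, samples$replicate), ]
  samples <- data.frame(
    sample_id = sprintf("s_t%g_r%d", samples$time_h, samples$replicate),
    condition = "sim", time_h = samples$time_h,
    replicate = samples$replicate, stringsAsFactors = FALSE
  )
  n_samp <- nrow(samples)
  depth_scale <- if (depth_jitter_cv > 0) {
    rgamma(n_samp, shape = 1 / depth_jitter_cv^2, scale = depth_jitter_cv^2)
  } else rep(1, n_samp)

  g <- truth$genes
  if (n_spikes > 0) {
    spikes <- data.frame(
      gene_id = sprintf("spike_%03d", seq_len(n_spikes)),
      gene_class = "spike", a0_true = spike_ab, kd_true = 0,
      half_life_true_h = Inf, stringsAsFactors = FALSE
    )
    g <- rbind(g, spikes)
  }
  mu <- outer(seq_len(nrow(g)), seq_len(n_samp), function(i, j) {
    depth_scale[j] * g$a0_true[i] * exp(-g$kd_true[i] * samples$time_h[j])
  })
  counts <- matrix(0, nrow(g), n_samp)
  if (truth$dispersion > 0) {
    counts[] <- rnbinom(length(mu), mu = mu, size = 1 / truth$dispersion)
  } else {
    counts[] <- rpois(length(mu), lambda = mu)
  }
  genes <- g[, c("gene_id", "gene_class")]
  out_truth <- truth
  out_truth$genes <- g
  list(matrix = timecourse_counts(counts, genes, samples), truth = out_truth)
}
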