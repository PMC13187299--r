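# Shared in-code fixtures: everything is generated at test time.

toy_counts <- function(counts, classes = NULL, times = NULL, conds = NULL,
                       reps = NULL) {
  counts <- as.matrix(counts)
  n_g <- nrow(counts)
  n_s <- ncol(counts)
  if (is.null(classes)) classes <- rep("coding", n_g)
  if (is.null(times)) times <- seq_len(n_s) - 1
  if (is.null(conds)) conds <- rep("G2", n_s)
  if (is.null(reps)) reps <- rep(1L, n_s)
  timecourse_counts(
    counts,
    genes = data.frame(gene_id = sprintf("g%02d", seq_len(n_g)),
                       gene_class = classes),
    samples = data.frame(sample_id = sprintf("s%02d", seq_len(n_s)),
                         condition = conds, time_h = times, replicate = reps)
  )
}

# exact exponential abundance table (no noise) for decay-fit checks; a0
# large enough that integer rounding of the counts is negligible
exact_abundance <- function(a0, kd, times = c(0, 2, 4, 6),
                            condition = "G2", classes = NULL) {
  ab <- outer(seq_along(a0), seq_along(times),
              function(i, j) a0[i] * exp(-kd[i] * times[j]))
  counts <- round(ab * 1e5 / max(ab))
  toy_counts(counts, classes = classes, times = times,
             conds = rep(condition, length(times)))
}

unit_factors <- function(mat) {
  structure(
    list(factors = setNames(rep(1, nrow(mat$samples)), mat$samples$sample_id),
         method = "spike_in", reference_gene_ids = character()),
    class = "size_factors"
  )
}

# dense profile grid-search oracle for the exponential least-squares fit:
# for each kd on the grid, the optimal a0 has the closed form
# sum(y * e) / sum(e^2); refine the grid once around the best kd.
grid_fit_oracle <- function(t, y, kd_lo = -0.5, kd_hi = 3, step = 1e-3) {
  prof <- function(kds) {
    sses <- vapply(kds, function(kd) {
      e <- exp(-kd * t)
      a0 <- sum(y * e) / sum(e^2)
      sum((y - a0 * e)^2)
    }, numeric(1))
    list(kd = kds[which.min(sses)], sse = min(sses))
  }
  c1 <- prof(seq(kd_lo, kd_hi, by = step))
  c2 <- prof(seq(c1$kd - step, c1$kd + step, by = step / 100))
  e <- exp(-c2$kd * t)
  list(kd = c2$kd, a0 = sum(y * e) / sum(e^2), sse = c2$sse)
}

# a tail_sample from raw vectors
tails_of <- function(tail_nt, weight = rep(1, length(tail_nt)),
                     condition = "x", time_h = 0) {
  tail_sample(condition, time_h, data.frame(
    gene_id = sprintf("r%d", seq_along(tail_nt)),
    tail_nt = tail_nt, weight = weight
  ))
}

# synthetic periodic density: Gaussian bumps on a flat baseline
comb_density <- function(period, sigma = 3, max_nt = 250, amp = 1,
                         jitter = NULL, start = period) {
  x <- 0:max_nt
  centers <- seq(start, 200, by = period)
  d <- rep(0.2 / length(x), length(x))
  for (i in seq_along(centers)) {
    a <- if (is.null(jitter)) amp else amp * jitter[(i - 1) %% length(jitter) + 1]
    d <- d + a * exp(-0.5 * ((x - centers[i]) / sigma)^2)
  }
  new_tail_distribution(d, bandwidth_nt = 0)
}
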