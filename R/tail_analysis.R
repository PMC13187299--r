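# Row-normalized Gaussian smoothing operator on a 1-nt grid of n bins;
# edge rows renormalize over the in-window kernel mass so a flat input
# stays flat near the boundaries.
.smooth_operator <- function(n, bw) {
  d <- outer(seq_len(n), seq_len(n), "-")
  S <- exp(-0.5 * (d / bw)^2)
  S[abs(d) > ceiling(4 * bw)] <- 0
  S / rowSums(S)
}

gauss_smooth <- function(x, bw) {
  if (bw <= 0) return(x)
  as.numeric(.smooth_operator(length(x), bw) %*% x)
}

#' Build a binned, optionally smoothed tail-length distribution
#'
#' Weight-aware histogram on a 1-nt grid from 0 to `max_nt` (tails longer
#' than `max_nt` accumulate in the top bin), Gaussian-smoothed with the
#' given bandwidth and renormalized to sum to 1. Use bandwidth 0 for
#' quantitative window masses; the default 2 nt is a display-level choice.
#'
#' @param sample A non-empty [tail_sample()].
#' @param max_nt Top bin (default 250).
#' @param bandwidth_nt Gaussian smoothing bandwidth in nt (default 2; 0
#'   disables smoothing).
#' @return An object of class `tail_distribution`: list with `bin_centers`
#'   (0:max_nt), `density` (sums to 1), `smoothing_bandwidth_nt`, `n_tails`.
#' @export
tail_distribution <- function(sample, max_nt = 250, bandwidth_nt = 2) {
  stopifnot(inherits(sample, "tail_sample"))
  if (!nrow(sample$records)) stop("empty tail sample")
  tails <- pmin(sample$records$tail_nt, max_nt)
  w <- sample$records$weight
  counts <- vapply(0:max_nt, function(b) sum(w[tails == b]), numeric(1))
  dens <- gauss_smooth(counts, bandwidth_nt)
  dens <- dens / sum(dens)
  new_tail_distribution(dens, bandwidth_nt = bandwidth_nt,
                        n_tails = sum(w))
}

#' Construct a tail-length distribution from a density vector
#'
#' Low-level constructor used when a density is built directly (e.g. for
#' synthetic periodic signals); bin i of `density` corresponds to i - 1 nt.
#'
#' @param density Non-negative vector over bins 0..(length - 1) nt;
#'   renormalized to sum to 1.
#' @param bandwidth_nt Smoothing bandwidth recorded on the object.
#' @param n_tails Effective number of tails behind the density.
#' @return A `tail_distribution` object.
#' @export
new_tail_distribution <- function(density, bandwidth_nt = 0, n_tails = NA_real_) {
  density <- as.numeric(density)
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("density must be finite and >= 0")
  }
  s <- sum(density)
  if (s <= 0) stop("density must have positive mass")
  structure(
    list(bin_centers = seq_along(density) - 1, density = density / s,
         smoothing_bandwidth_nt = bandwidth_nt, n_tails = n_tails),
    class = "tail_distribution"
  )
}

#' @export
print.tail_distribution <- function(x, ...) {
  cat("tail_distribution: bins 0..", max(x$bin_centers), " nt, bandwidth ",
      x$smoothing_bandwidth_nt, " nt, n = ", x$n_tails, "\n", sep = "")
  invisible(x)
}

#' Weighted median tail length
#'
#' The smallest tail length at which the cumulative weight reaches half the
#' total. Unsmoothed by construction: medians must not depend on display
#' smoothing.
#'
#' @param sample A non-empty [tail_sample()].
#' @return Median tail length in nt.
#' @export
median_tail <- function(sample) {
  stopifnot(inherits(sample, "tail_sample"))
  r <- sample$records
  if (!nrow(r)) stop("empty tail sample")
  ord <- order(r$tail_nt)
  tails <- r$tail_nt[ord]
  cw <- cumsum(r$weight[ord])
  tails[which(cw >= sum(r$weight) / 2)[1]]
}

#' Fraction of tail-length mass in a half-open window
#'
#' Sum of the distribution's density over bins in \[lo_nt, hi_nt); half-open
#' windows compose exactly to total mass 1.
#'
#' @param dist A `tail_distribution`.
#' @param lo_nt,hi_nt Window bounds in nt, `0 <= lo < hi <= max + 1`.
#' @return Mass in \[0, 1\].
#' @export
range_fraction <- function(dist, lo_nt, hi_nt) {
  stopifnot(inherits(dist, "tail_distribution"))
  if (lo_nt < 0 || hi_nt <= lo_nt || hi_nt > max(dist$bin_centers) + 1) {
    stop("window must satisfy 0 <= lo < hi <= max + 1")
  }
  sum(dist$density[dist$bin_centers >= lo_nt & dist$bin_centers < hi_nt])
}

# centered linear autocorrelation at a band of lags
.acf_band <- function(z, lags) {
  n <- length(z)
  z <- z - mean(z)
  denom <- sum(z^2)
  vapply(lags, function(k) {
    sum(z[1:(n - k)] * z[(k + 1):n]) / denom
  }, numeric(1))
}

# highest interior local maximum of `vals` (computed on a band padded by one
# lag on each side); returns c(value, index into the unpadded band) or NULL.
# A genuinely periodic signal has an ACF *peak* at its period; a smooth
# aperiodic residual has a monotone ACF with no interior peak and must not
# be called periodic no matter how large its autocorrelation.
.best_acf_peak <- function(vals) {
  n <- length(vals)
  if (n < 3) return(NULL)
  i <- which(vals[2:(n - 1)] > vals[1:(n - 2)] &
               vals[2:(n - 1)] >= vals[3:n]) + 1
  if (!length(i)) return(NULL)
  top <- i[which.max(vals[i])]
  c(vals[top], top - 1)
}

#' Detect phased PABPC toeprints in a tail-length distribution
#'
#' Looks for periodic "bumps" (PABPC toeprints) in the density over the
#' search window: the density is detrended by subtracting a heavily smoothed
#' baseline (bandwidth = `max_period_nt`, wide enough to erase any
#' periodicity of interest), the autocorrelation of the residual is computed
#' over lags `min_period_nt..max_period_nt`, and the period is the lag of
#' the highest interior autocorrelation peak (local maximum) in the band —
#' a smooth aperiodic residual, whose autocorrelation decays monotonically,
#' yields no peak and is never called periodic. Significance is assessed
#' with the same peak statistic against a
#' permutation null: the residual is randomly permuted `n_perm` times, the
#' same statistic recomputed, and the observed peak must exceed the null at
#' level `alpha`. Permutations consume the current RNG stream; set a seed
#' beforehand for exact reproducibility.
#'
#' @param dist A `tail_distribution` covering the search window.
#' @param min_period_nt,max_period_nt Period search band in nt (default
#'   15-60).
#' @param search_lo_nt,search_hi_nt Half-open analysis window in nt (default
#'   \[20, 200)).
#' @param n_perm Number of permutations for the null (default 999).
#' @param alpha Significance level (default 0.01).
#' @return An object of class `toeprint_report`: list with `period_nt`
#'   (`NA` when not significant), `peak_positions_nt`, `amplitude`,
#'   `significant`, `p_value`, and `best_lag_nt` (the top lag regardless of
#'   significance).
#' @export
detect_toeprints <- function(dist, min_period_nt = 15, max_period_nt = 60,
                             search_lo_nt = 20, search_hi_nt = 200,
                             n_perm = 999, alpha = 0.01) {
  stopifnot(inherits(dist, "tail_distribution"))
  if (search_hi_nt - 1 > max(dist$bin_centers) || search_lo_nt < 0) {
    stop("search window outside distribution support")
  }
  idx <- dist$bin_centers >= search_lo_nt & dist$bin_centers < search_hi_nt
  d <- dist$density[idx]
  baseline <- gauss_smooth(d, max_period_nt)
  resid <- d - baseline
  # pad the lag band by one on each side so peaks at the band edges are seen
  lags_pad <- (min_period_nt - 1):(max_period_nt + 1)
  ac_obs <- .acf_band(resid, lags_pad)
  peak <- .best_acf_peak(ac_obs)
  if (is.null(peak)) {
    obs <- -Inf
    best_lag <- NA_real_
  } else {
    obs <- peak[1]
    best_lag <- min_period_nt + peak[2] - 1
  }

  # Null: permute the residual, then re-impose the distribution's recorded
  # smoothing so the null has the same short-range correlation the kernel
  # introduced; a white null would understate ACF fluctuations of smoothed
  # data and inflate the false-positive rate.
  n <- length(resid)
  bw <- dist$smoothing_bandwidth_nt
  perm <- matrix(0, nrow = n, ncol = n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- resid[sample.int(n)]
  if (bw > 0) perm <- .smooth_operator(n, bw) %*% perm
  permc <- sweep(perm, 2, colMeans(perm))
  denom <- colSums(permc^2)
  ac_null <- matrix(0, nrow = length(lags_pad), ncol = n_perm)
  for (j in seq_along(lags_pad)) {
    k <- lags_pad[j]
    ac_null[j, ] <- colSums(permc[1:(n - k), , drop = FALSE] *
                              permc[(k + 1):n, , drop = FALSE]) / denom
  }
  null_stat <- apply(ac_null, 2, function(v) {
    p <- .best_acf_peak(v)
    if (is.null(p)) -Inf else p[1]
  })
  p_value <- (1 + sum(null_stat >= obs)) / (n_perm + 1)
  significant <- is.finite(obs) && p_value <= alpha

  # local maxima of the residual, spaced >= min_period / 2, positive only
  cand <- which(diff(sign(diff(resid))) < 0) + 1
  cand <- cand[resid[cand] > 0]
  cand <- cand[order(resid[cand], decreasing = TRUE)]
  peaks <- integer(0)
  for (i in cand) {
    if (all(abs(i - peaks) >= min_period_nt / 2)) peaks <- c(peaks, i)
  }
  peaks <- sort(peaks)
  peak_positions <- peaks + search_lo_nt - 1
  amplitude <- if (length(peaks)) max(0, mean(resid[peaks])) else 0

  structure(
    list(period_nt = if (significant) best_lag else NA_real_,
         peak_positions_nt = peak_positions, amplitude = amplitude,
         significant = significant, p_value = p_value,
         best_lag_nt = best_lag),
    class = "toeprint_report"
  )
}

#' @export
print.toeprint_report <- function(x, ...) {
  if (x$significant) {
    cat("toeprint_report: period", x$period_nt, "nt (p =", x$p_value, ")\n")
  } else {
    cat("toeprint_report: no significant period (p =", x$p_value, ")\n")
  }
  if (length(x$peak_positions_nt)) {
    cat("  peaks at:", paste(x$peak_positions_nt, collapse = ", "), "nt\n")
  }
  invisible(x)
}
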