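#' Fit a single-exponential decay curve
#'
#' Least-squares fit of `a0 * exp(-kd * t)` to abundances on the linear
#' scale (not log-transformed, so residuals are not reweighted and the
#' reported r2 refers to the abundances actually plotted). Initialization
#' comes from a log-linear regression on the positive abundances; the fit is
#' refined by Levenberg-Marquardt nonlinear least squares with a Nelder-Mead
#' polish on (log a0, kd). `kd` is unconstrained: abundances may drift upward
#' under noise, and non-positive rates are handled downstream by the
#' half-life cap.
#'
#' r2 = 1 - SS_res / SS_tot with SS_tot about the mean abundance; it may be
#' negative for poor fits, and is defined as 1 when both sums are zero
#' (constant data fit exactly).
#'
#' @param times_h Timepoints in hours (>= 3 values).
#' @param abundances Matching non-negative abundances, at least one positive.
#' @return List with `a0` (> 0), `kd` (per hour), `r2` and `sse`.
#' @export
fit_exponential <- function(times_h, abundances) {
  t <- as.numeric(times_h)
  y <- as.numeric(abundances)
  if (length(t) != length(y)) stop("times and abundances must match")
  if (length(t) < 3) stop("need >= 3 timepoints")
  if (any(!is.finite(t)) || any(!is.finite(y))) stop("non-finite input")
  if (any(y < 0)) stop("abundances must be >= 0")
  if (all(y == 0)) stop("all-zero abundances cannot be fit")

  sse_of <- function(a0, kd) sum((y - a0 * exp(-kd * t))^2)

  # initialization: log-linear regression on positive values
  pos <- y > 0
  if (sum(pos) >= 2) {
    ll <- lm(log(y[pos]) ~ t[pos])
    kd0 <- -unname(coef(ll)[2])
    a00 <- exp(unname(coef(ll)[1]))
  } else {
    kd0 <- 1
    a00 <- max(y)
  }
  if (!is.finite(kd0)) kd0 <- 0
  if (!is.finite(a00) || a00 <= 0) a00 <- max(y)

  cands <- list(c(a00, kd0), c(mean(y), 0))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a0 * exp(-kd * t),
      start = list(a0 = a00, kd = kd0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- coef(fit)
    if (is.finite(cf["a0"]) && cf["a0"] > 0) {
      cands <- c(cands, list(unname(cf)))
    }
  }
  sses <- vapply(cands, function(p) sse_of(p[1], p[2]), numeric(1))
  best <- cands[[which.min(sses)]]
  # Nelder-Mead polish on (log a0, kd) keeps a0 positive
  pol <- optim(c(log(best[1]), best[2]),
               function(p) sse_of(exp(p[1]), p[2]),
               method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  if (pol$value < sse_of(best[1], best[2])) {
    best <- c(exp(pol$par[1]), pol$par[2])
  }
  a0 <- best[1]
  kd <- best[2]
  sse <- sse_of(a0, kd)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    if (sse <= .Machine$double.eps * sum(y^2)) 1 else 1 - sse / .Machine$double.eps
  } else 1 - sse / sst
  r2 <- min(r2, 1)
  list(a0 = a0, kd = kd, r2 = r2, sse = sse)
}

#' Convert a decay rate to a capped half-life
#'
#' t1/2 = ln(2) / kd, clamped to the interval used for visualization and
#' downstream ratios: values >= 200 h report 200 h and values <= 0.25 h
#' report 0.25 h, both flagged as capped. Non-positive rates (no apparent
#' decay) map to the 200-h cap.
#'
#' @param kd Decay rate(s) per hour; finite.
#' @return List with `half_life_h` in \[0.25, 200\] and logical `capped`
#'   (vectorized over `kd`).
#' @export
half_life_from_rate <- function(kd) {
  if (any(!is.finite(kd))) stop("kd must be finite")
  raw <- ifelse(kd > 0, log(2) / kd, Inf)
  hl <- pmin(pmax(raw, 0.25), 200)
  list(half_life_h = hl, capped = raw >= 200 | raw <= 0.25)
}

#' Fit exponential decay to every gene of one condition
#'
#' Applies [fit_exponential()] to the replicate-averaged abundances of each
#' gene across the condition's timepoints and attaches capped half-lives.
#' Genes whose abundance is zero at every timepoint cannot be fit; they are
#' excluded and logged, never silently dropped.
#'
#' @param table A `normalized_abundance` object.
#' @param condition Condition label with >= 3 timepoints in the table.
#' @return Data frame with columns gene_id, gene_class, a0, kd_per_h,
#'   half_life_h, capped, r2, n_timepoints. Excluded gene ids are attached
#'   as `attr(, "excluded")`.
#' @export
fit_table <- function(table, condition) {
  stopifnot(inherits(table, "normalized_abundance"))
  sel <- table$timepoints$condition == condition
  if (!any(sel)) stop("condition '", condition, "' not present")
  times <- table$timepoints$time_h[sel]
  if (length(unique(times)) < 3) {
    stop("condition '", condition, "' has fewer than 3 timepoints")
  }
  ord <- order(times)
  times <- times[ord]
  ab <- table$abundance[, which(sel)[ord], drop = FALSE]

  fitable <- rowSums(ab) > 0
  excluded <- table$genes$gene_id[!fitable]
  message("fit_table(", condition, "): fitting ", sum(fitable), "/",
          length(fitable), " genes (", length(excluded),
          " all-zero excluded)")
  rows <- lapply(which(fitable), function(i) {
    f <- fit_exponential(times, ab[i, ])
    h <- half_life_from_rate(f$kd)
    data.frame(
      gene_id = table$genes$gene_id[i],
      gene_class = table$genes$gene_class[i],
      a0 = f$a0, kd_per_h = f$kd, half_life_h = h$half_life_h,
      capped = h$capped, r2 = f$r2, n_timepoints = length(times),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_id = character(), gene_class = character(), a0 = numeric(),
    kd_per_h = numeric(), half_life_h = numeric(), capped = logical(),
    r2 = numeric(), n_timepoints = integer(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Join reference and alternative fits and apply the goodness-of-fit filter
#'
#' Inner-joins two per-gene fit tables on gene_id and keeps genes whose
#' reference-condition (interphase) fit has r2 >= `r2_min`. The filter is
#' deliberately one-sided: a lack of degradation in the alternative
#' condition is expected to produce poor fits there, so the alternative r2
#' is never tested. The stabilization ratio is computed from the capped
#' half-lives.
#'
#' @param ref_fits Fit table for the reference (interphase) condition.
#' @param alt_fits Fit table for the alternative (mitotic) condition.
#' @param r2_min Reference r2 cutoff (default 0.8; 0.4 for the THZ1-style
#'   variant).
#' @return Data frame of passing genes with columns gene_id,
#'   half_life_ref_h, half_life_alt_h, ratio, passed_filter, r2_ref, r2_alt,
#'   capped_ref, capped_alt.
#' @export
join_and_filter <- function(ref_fits, alt_fits, r2_min = 0.8) {
  if (anyDuplicated(ref_fits$gene_id)) stop("duplicate gene_id in ref_fits")
  if (anyDuplicated(alt_fits$gene_id)) stop("duplicate gene_id in alt_fits")
  common <- intersect(ref_fits$gene_id, alt_fits$gene_id)
  r <- ref_fits[match(common, ref_fits$gene_id), ]
  a <- alt_fits[match(common, alt_fits$gene_id), ]
  passed <- r$r2 >= r2_min
  message("join_and_filter: ", length(common), " genes joined, ",
          sum(passed), " pass reference r2 >= ", r2_min)
  out <- data.frame(
    gene_id = common,
    half_life_ref_h = r$half_life_h, half_life_alt_h = a$half_life_h,
    ratio = a$half_life_h / r$half_life_h,
    passed_filter = passed,
    r2_ref = r$r2, r2_alt = a$r2,
    capped_ref = r$capped, capped_alt = a$capped,
    stringsAsFactors = FALSE
  )[passed, , drop = FALSE]
  rownames(out) <- NULL
  out
}
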