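#' Parameterize the per-molecule deadenylation simulator
#'
#' Encodes the mechanistic picture of mitotic deadenylation: cytoplasmic
#' poly(A)-binding protein (PABPC) occupies ~27 nt of tail and packs with a
#' ~30 nt period; a deadenylase that cannot displace PABPC shortens free
#' 3' poly(A) quickly (`r_free`) but stalls when the 3' end reaches a
#' PABPC-protected boundary (`r_boundary`). Tails too short to hold a single
#' PABPC (< `min_protected_nt`) are unprotected and the molecule is exposed
#' to a degradation hazard. In the interphase regime PABPC is displaced
#' efficiently, so `r_boundary` is forced equal to `r_free`.
#'
#' @param regime `"interphase"` or `"mitotic"`.
#' @param footprint_nt PABPC occupancy, nt (default 27).
#' @param packing_period_nt Boundary spacing = footprint + inter-PABPC gap,
#'   nt (default 30, the observed toeprint period).
#' @param r_free Shortening rate on unprotected 3' poly(A), nt/h (> 0).
#' @param r_boundary Shortening rate at a protected boundary, nt/h (>= 0);
#'   default `r_free / 100` in the mitotic regime, `r_free` in interphase.
#' @param min_protected_nt Shortest tail a single PABPC protects (default 20).
#' @param deg_hazard_per_h Degradation hazard applied while tail <
#'   `min_protected_nt` (default 0.5 per h).
#' @param init_mode_nt Mode of the initial tail-length distribution (default
#'   45 nt, matching the steady-state bulk profile).
#' @param init_shape Gamma shape of the initial distribution (> 1; controls
#'   right skew, default 2.2).
#' @param phase_nt Integer offset added to all boundary positions (default 0).
#' @param n_molecules Number of molecules to simulate.
#' @param seed Integer seed.
#' @return An object of class `deadenylation_config`.
#' @export
deadenylation_config <- function(regime = c("mitotic", "interphase"),
                                 footprint_nt = 27L, packing_period_nt = 30L,
                                 r_free = 30, r_boundary = NULL,
                                 min_protected_nt = 20L,
                                 deg_hazard_per_h = 0.5,
                                 init_mode_nt = 45, init_shape = 2.2,
                                 phase_nt = 0L, n_molecules = 10000L,
                                 seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(r_boundary)) {
    r_boundary <- if (regime == "mitotic") r_free / 100 else r_free
  }
  if (regime == "interphase") r_boundary <- r_free
  stopifnot(footprint_nt > 0, footprint_nt <= packing_period_nt,
            r_free > 0, r_boundary >= 0, is.finite(r_free),
            is.finite(r_boundary), min_protected_nt >= 0,
            deg_hazard_per_h >= 0, init_mode_nt > 0, init_shape > 1,
            n_molecules >= 0)
  structure(
    list(regime = regime, footprint_nt = as.integer(footprint_nt),
         packing_period_nt = as.integer(packing_period_nt),
         r_free = r_free, r_boundary = r_boundary,
         min_protected_nt = as.integer(min_protected_nt),
         deg_hazard_per_h = deg_hazard_per_h,
         init_mode_nt = init_mode_nt, init_shape = init_shape,
         phase_nt = as.integer(phase_nt),
         n_molecules = as.integer(n_molecules), seed = as.integer(seed)),
    class = "deadenylation_config"
  )
}

#' Draw an initial poly(A) tail-length sample
#'
#' Integer tail lengths from a right-skewed, unimodal gamma distribution with
#' mode `init_mode_nt` and shape `init_shape` (scale = mode / (shape - 1)),
#' reproducing the steady-state bulk profile: a peak around 40-50 nt and a
#' heavy right tail extending past 200 nt.
#'
#' @param config A [deadenylation_config()].
#' @param n Number of molecules (>= 0).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [tail_sample()] with molecule ids `mol_...` as `gene_id`.
#' @export
initial_tail_sample <- function(config, n = config$n_molecules,
                                seed = config$seed) {
  stopifnot(inherits(config, "deadenylation_config"), n >= 0)
  set.seed(seed)
  scale <- config$init_mode_nt / (config$init_shape - 1)
  tails <- round(rgamma(n, shape = config$init_shape, scale = scale))
  tail_sample(
    condition = config$regime, time_h = 0,
    records = data.frame(
      gene_id = if (n) sprintf("mol_%06d", seq_len(n)) else character(),
      tail_nt = tails, weight = rep(1, n), stringsAsFactors = FALSE
    )
  )
}

# removal rate while the tail has length l (rate of losing the next nt)
.boundary_rate <- function(l, config) {
  at_boundary <- ((l - config$phase_nt) %% config$packing_period_nt == 0) &
    l >= config$footprint_nt
  ifelse(at_boundary, config$r_boundary, config$r_free)
}

#' Simulate per-molecule poly(A) tail shortening
#'
#' Exact event-based simulation of a pure-death chain on tail length: each
#' nucleotide removal waits an exponential time with rate `r_free` nt/h,
#' except when the 3' end sits at a PABPC-protected boundary (tail length a
#' positive multiple of `packing_period_nt`, at least `footprint_nt`), where
#' the rate is `r_boundary`. While the tail is shorter than
#' `min_protected_nt` the molecule is removed with constant hazard
#' `deg_hazard_per_h` (competing exponential clock). The state of every
#' molecule is recorded at each requested timepoint; molecule identity is
#' carried in `gene_id` so trajectories can be joined across timepoints.
#'
#' @param config A [deadenylation_config()].
#' @param timepoints_h Ascending timepoints (hours), first >= 0.
#' @param initial Optional [tail_sample()] of starting tails (defaults to
#'   [initial_tail_sample()] under the config seed).
#' @return An object of class `deadenylation_sim`: list with `timepoints_h`,
#'   `samples` (one [tail_sample()] of survivors per timepoint),
#'   `degraded_fraction` and `config`.
#' @export
simulate_tails <- function(config, timepoints_h, initial = NULL) {
  stopifnot(inherits(config, "deadenylation_config"))
  if (is.unsorted(timepoints_h, strictly = TRUE) || timepoints_h[1] < 0) {
    stop("timepoints_h must be strictly ascending, first >= 0")
  }
  if (is.null(initial)) {
    initial <- initial_tail_sample(config)
    set.seed(config$seed + 1L)
  } else {
    set.seed(config$seed)
  }
  L0 <- initial$records$tail_nt
  ids <- initial$records$gene_id
  n <- length(L0)
  n_t <- length(timepoints_h)
  lengths_at <- matrix(0L, nrow = n, ncol = n_t)
  t_deg <- rep(Inf, n)

  for (m in seq_len(n)) {
    l0 <- L0[m]
    if (l0 > 0) {
      lens <- l0:1                      # lengths occupied before each removal
      rates <- .boundary_rate(lens, config)
      u <- rexp(l0, rate = 1)
      waits <- ifelse(rates > 0, u / rates, Inf)
      etimes <- cumsum(waits)           # time at which length drops below lens[i]
      n_removed <- findInterval(timepoints_h, etimes)
      lengths_at[m, ] <- l0 - n_removed
    } else {
      etimes <- numeric(0)
    }
    if (config$deg_hazard_per_h > 0) {
      # time at which the tail first drops below min_protected_nt
      if (l0 < config$min_protected_nt) {
        t_enter <- 0
      } else {
        i <- l0 - config$min_protected_nt + 1L  # event taking length to min-1
        t_enter <- if (i <= length(etimes)) etimes[i] else Inf
      }
      if (is.finite(t_enter)) {
        t_deg[m] <- t_enter + rexp(1, rate = config$deg_hazard_per_h)
      }
    }
  }

  samples <- vector("list", n_t)
  degraded_fraction <- numeric(n_t)
  for (j in seq_len(n_t)) {
    alive <- t_deg > timepoints_h[j]
    degraded_fraction[j] <- if (n) mean(!alive) else 0
    samples[[j]] <- tail_sample(
      condition = config$regime, time_h = timepoints_h[j],
      records = data.frame(
        gene_id = ids[alive], tail_nt = lengths_at[alive, j],
        weight = rep(1, sum(alive)), stringsAsFactors = FALSE
      )
    )
  }
  structure(
    list(timepoints_h = timepoints_h, samples = samples,
         degraded_fraction = degraded_fraction, config = config),
    class = "deadenylation_sim"
  )
}

#' @export
print.deadenylation_sim <- function(x, ...) {
  cat("deadenylation_sim (", x$config$regime, "): ",
      x$config$n_molecules, " molecules\n", sep = "")
  for (j in seq_along(x$timepoints_h)) {
    s <- x$samples[[j]]
    cat(sprintf("  t=%g h: %d survivors (degraded %.1f%%), median tail %s nt\n",
                x$timepoints_h[j], nrow(s$records),
                100 * x$degraded_fraction[j],
                if (nrow(s$records)) median_tail(s) else "NA"))
  }
  invisible(x)
}
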