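test_that("exact exponential and constant inputs are fit exactly", {
  f <- fit_exponential(c(0, 2, 4), c(100, 50, 25))
  expect_equal(f$a0, 100, tolerance = 1e-8)
  expect_equal(f$kd, log(2) / 2, tolerance = 1e-8)
  expect_equal(f$r2, 1)

  f2 <- fit_exponential(c(0, 2, 4, 6), c(100, 100, 100, 100))
  expect_equal(f2$kd, 0, tolerance = 1e-10)
  expect_equal(f2$r2, 1)

  expect_error(fit_exponential(c(0, 2, 4), c(0, 0, 0)), "all-zero")
  expect_error(fit_exponential(c(0, 2, NA), c(1, 2, 3)), "non-finite")
  expect_error(fit_exponential(c(0, 2), c(1, 2)), ">= 3")
})

test_that("fitted parameters match a dense grid-search oracle", {
  t <- c(0, 2, 4, 6)
  y <- c(100, 62, 35, 22)
  f <- fit_exponential(t, y)
  o <- grid_fit_oracle(t, y)
  expect_equal(f$kd, o$kd, tolerance = 1e-3)
  expect_equal(f$a0, o$a0, tolerance = 1e-3)
  expect_lte(f$sse, o$sse + 1e-9)
})

test_that("the fitter never does worse than brute-force grid search on noisy data", {
  set.seed(17)
  for (i in 1:20) {
    t <- c(0, 2, 4, 6)
    kd <- runif(1, 0.02, 1.5)
    a0 <- runif(1, 50, 500)
    y <- pmax(a0 * exp(-kd * t) * exp(rnorm(4, sd = 0.2)), 0)
    f <- fit_exponential(t, y)
    o <- grid_fit_oracle(t, y)
    expect_lte(f$sse, o$sse + 1e-9)
  }
})

test_that("noiseless decay rates are recovered to 1e-6 relative across the cap range", {
  t <- c(0, 2, 4, 6)
  for (kd in exp(seq(log(log(2) / 200), log(log(2) / 0.25), length.out = 9))) {
    y <- 80 * exp(-kd * t)
    f <- fit_exponential(t, y)
    expect_equal(f$kd, kd, tolerance = 1e-6)
  }
})

test_that("half-life conversion applies ln(2)/kd with the 0.25/200 h caps", {
  h <- half_life_from_rate(log(2))
  expect_equal(h$half_life_h, 1)
  expect_false(h$capped)

  h2 <- half_life_from_rate(0.003)      # uncapped 231.05 h
  expect_equal(h2$half_life_h, 200)
  expect_true(h2$capped)

  h3 <- half_life_from_rate(0.124)
  expect_equal(round(h3$half_life_h, 1), 5.6)
  expect_false(h3$capped)

  h4 <- half_life_from_rate(c(0, -0.5, 5))   # ln(2)/5 = 0.139 h, below cap
  expect_equal(h4$half_life_h, c(200, 200, 0.25))
  expect_true(all(h4$capped))

  expect_error(half_life_from_rate(Inf), "finite")

  # monotone non-increasing in kd over kd > 0, always within caps
  kds <- sort(exp(seq(log(1e-4), log(50), length.out = 200)))
  hl <- half_life_from_rate(kds)$half_life_h
  expect_true(all(diff(hl) <= 1e-12))
  expect_true(all(hl >= 0.25 & hl <= 200))
})

test_that("fit_table matches per-gene fits and logs degenerate genes", {
  mat <- exact_abundance(a0 = c(100, 200), kd = log(2) / c(2, 8))
  norm <- normalize_and_average(mat, unit_factors(mat))
  fits <- suppressMessages(fit_table(norm, "G2"))
  expect_equal(fits$r2, c(1, 1), tolerance = 1e-6)
  expect_equal(fits$kd_per_h, log(2) / c(2, 8), tolerance = 1e-3)

  # all-zero gene: excluded and recorded
  m2 <- toy_counts(rbind(c(100, 50, 25), c(0, 0, 0)), times = c(0, 2, 4))
  n2 <- normalize_and_average(m2, unit_factors(m2))
  expect_message(f2 <- fit_table(n2, "G2"), "all-zero")
  expect_identical(f2$gene_id, "g01")
  expect_identical(attr(f2, "excluded"), "g02")

  expect_error(suppressMessages(fit_table(n2, "M")), "not present")

  # composition: fit_table equals fit_exponential applied by hand
  truth <- generate_decay_truth(15, seed = 9, depth = 1e5, dispersion = 0.05)
  sim <- simulate_counts(truth)
  fac <- suppressMessages(compute_size_factors(sim$matrix, "spike_in"))
  nt <- normalize_and_average(sim$matrix, fac)
  ft <- suppressMessages(fit_table(nt, "sim"))
  i <- match("gene_00007", nt$genes$gene_id)
  manual <- fit_exponential(nt$timepoints$time_h, nt$abundance[i, ])
  row <- ft[ft$gene_id == "gene_00007", ]
  expect_equal(row$kd_per_h, manual$kd)
  expect_equal(row$r2, manual$r2)
})

test_that("the goodness-of-fit filter tests only the reference condition", {
  mk <- function(ids, r2, hl) {
    data.frame(gene_id = ids, gene_class = "coding", a0 = 100,
               kd_per_h = log(2) / hl, half_life_h = hl, capped = FALSE,
               r2 = r2, n_timepoints = 4L, stringsAsFactors = FALSE)
  }
  ref <- mk(c("a", "b", "c"), r2 = c(0.85, 0.79, 0.50), hl = c(5, 5, 5))
  alt <- mk(c("a", "b", "c"), r2 = c(0.99, 0.10, 0.10), hl = c(20, 20, 10))

  cmp <- suppressMessages(join_and_filter(ref, alt))
  expect_identical(cmp$gene_id, "a")           # 0.85 in, 0.79 out
  expect_equal(cmp$ratio, 4)

  cmp4 <- suppressMessages(join_and_filter(ref, alt, r2_min = 0.4))
  expect_setequal(cmp4$gene_id, c("a", "b", "c"))  # 0.5 passes the 0.4 variant

  expect_error(join_and_filter(rbind(ref, ref[1, ]), alt), "duplicate")
})
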