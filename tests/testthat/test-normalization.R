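test_that("size factors are reference totals over their mean", {
  # equal spike totals -> unit factors
  m <- toy_counts(rbind(c(1000, 1000, 1000), c(50, 60, 70)),
                  classes = c("spike", "coding"))
  sf <- suppressMessages(compute_size_factors(m, "spike_in"))
  expect_equal(unname(sf$factors), c(1, 1, 1))
  expect_identical(sf$reference_gene_ids, "g01")

  m2 <- toy_counts(rbind(c(1000, 500), c(50, 60)),
                   classes = c("spike", "coding"))
  sf2 <- suppressMessages(compute_size_factors(m2, "spike_in"))
  expect_equal(unname(sf2$factors), c(4 / 3, 2 / 3))
  expect_equal(mean(sf2$factors), 1, tolerance = 1e-9)

  expect_error(suppressMessages(compute_size_factors(m2, "mito")),
               "no reference genes")
  m3 <- toy_counts(rbind(c(1000, 0), c(50, 60)),
                   classes = c("spike", "coding"))
  expect_error(suppressMessages(compute_size_factors(m3, "spike_in")),
               "zero reference counts")
})

test_that("top_k_stable picks the k genes with lowest count CV", {
  set.seed(8)
  counts <- rbind(
    c(100, 101, 99, 100),   # very stable
    c(200, 210, 190, 205),  # stable
    c(50, 500, 30, 300),    # unstable
    c(400, 100, 600, 50),   # unstable
    c(80, 90, 70, 85)       # middling
  ) * 1L
  m <- toy_counts(counts)
  sf <- suppressMessages(compute_size_factors(m, "top_k_stable", k = 2,
                                              min_reads = 25))
  # oracle: enumerate every gene's CV, take the two lowest
  cv <- apply(counts, 1, function(x) sd(x) / mean(x))
  oracle_ids <- m$genes$gene_id[order(cv)][1:2]
  expect_setequal(sf$reference_gene_ids, oracle_ids)
  tot <- colSums(counts[match(oracle_ids, m$genes$gene_id), ])
  expect_equal(unname(sf$factors), unname(tot / mean(tot)))
})

test_that("the >=25-reads-in-each-sample filter is exact and idempotent", {
  counts <- rbind(c(25, 30, 25),   # kept: >= 25 in every sample
                  c(100, 24, 100), # dropped: one sample below 25
                  c(25, 25, 25),
                  c(0, 1000, 1000))
  m <- toy_counts(counts)
  f <- suppressMessages(apply_expression_filter(m))
  expect_identical(f$genes$gene_id, c("g01", "g03"))
  f2 <- suppressMessages(apply_expression_filter(f))
  expect_identical(f2$counts, f$counts)

  empty <- suppressMessages(apply_expression_filter(
    toy_counts(matrix(0, 0, 3))
  ))
  expect_identical(nrow(empty$counts), 0L)
})

test_that("normalization divides by factors and averages replicates", {
  # single replicate, unit factors: abundance equals raw counts
  m <- toy_counts(matrix(c(10, 20, 30, 40), 2, 2), times = c(0, 2))
  n <- normalize_and_average(m, unit_factors(m))
  expect_equal(unname(n$abundance), matrix(c(10, 20, 30, 40), 2, 2))

  # two replicates, counts [120, 80], factors [1.2, 0.8] -> (100+100)/2
  m2 <- toy_counts(matrix(c(120, 80), 1, 2), times = c(0, 0),
                   reps = c(1L, 2L))
  fac <- unit_factors(m2)
  fac$factors[] <- c(1.2, 0.8)
  n2 <- normalize_and_average(m2, fac)
  expect_equal(unname(n2$abundance)[1, 1], 100)
  expect_identical(n2$timepoints$n_replicates, 2L)

  fac$factors <- fac$factors[1]
  expect_error(normalize_and_average(m2, fac), "no size factor")
})

test_that("reference genes have equal normalized abundance in every sample", {
  set.seed(31)
  counts <- matrix(rpois(60, 500), 6, 10)
  m <- toy_counts(counts, classes = c("spike", "spike", rep("coding", 4)),
                  times = seq(0, 9))
  sf <- suppressMessages(compute_size_factors(m, "spike_in"))
  norm <- sweep(m$counts, 2, sf$factors[m$samples$sample_id], "/")
  ref_tot <- colSums(norm[1:2, ])
  expect_lt(diff(range(ref_tot)) / mean(ref_tot), 1e-9)

  # scale invariance: scaling one sample (references included) by c scales
  # its factor by c up to the global mean renormalization, and reference
  # totals stay equalized after normalization
  m_sc <- m
  m_sc$counts[, 3] <- m_sc$counts[, 3] * 5
  sf_sc <- suppressMessages(compute_size_factors(m_sc, "spike_in"))
  mean_old <- mean(colSums(m$counts[1:2, ]))
  mean_new <- mean(colSums(m_sc$counts[1:2, ]))
  expect_equal(unname(sf_sc$factors[3] / sf$factors[3]),
               5 * mean_old / mean_new, tolerance = 1e-9)
  norm_sc <- sweep(m_sc$counts, 2, sf_sc$factors[m$samples$sample_id], "/")
  expect_lt(diff(range(colSums(norm_sc[1:2, ]))) /
              mean(colSums(norm_sc[1:2, ])), 1e-9)
})
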