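mk_cmp <- function(ids, ref, alt) {
  data.frame(gene_id = ids, half_life_ref_h = ref, half_life_alt_h = alt,
             ratio = alt / ref, passed_filter = TRUE, stringsAsFactors = FALSE)
}

test_that("stabilization ratios and class medians match hand arithmetic", {
  cmp <- mk_cmp("a", 5, 20)
  s <- stabilization_summary(cmp)
  expect_equal(s$per_gene$ratio, 4)

  # cap collision: flagged uninformative but retained
  cmp2 <- mk_cmp(c("a", "b"), c(200, 5), c(200, 10))
  s2 <- suppressMessages(stabilization_summary(cmp2))
  expect_identical(s2$per_gene$uninformative, c(TRUE, FALSE))
  expect_identical(nrow(s2$per_gene), 2L)

  # 5-gene toy set with classes, against hand-computed medians
  cmp5 <- mk_cmp(letters[1:5], rep(4, 5), c(8, 16, 24, 12, 6))
  cls <- setNames(c("coding", "coding", "coding", "lncRNA", "lncRNA"),
                  letters[1:5])
  s5 <- stabilization_summary(cmp5, cls)
  med <- s5$per_class
  expect_equal(med$median_ratio[med$gene_class == "coding"], 4)   # 2,4,6 -> 4
  expect_equal(med$median_ratio[med$gene_class == "lncRNA"], 2.25) # 3,1.5
  expect_equal(med$n, c(3L, 2L))

  # permutation invariance
  s5p <- stabilization_summary(cmp5[c(4, 2, 5, 1, 3), ], cls)
  expect_equal(s5p$per_class, s5$per_class)
})

test_that("rank correlation handles ties and ignores monotone transforms", {
  x <- setNames(1:4, letters[1:4])
  expect_equal(rank_correlation(x, x), 1)
  expect_equal(rank_correlation(x, setNames(4:1, letters[1:4])), -1)

  y <- setNames(c(2, 2, 3, 1), letters[1:4])
  # oracle: Pearson correlation of average ranks
  rx <- rank(1:4)
  ry <- rank(c(2, 2, 3, 1))
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(rank_correlation(x, y), oracle)

  # monotone-transform invariance, incl. the log10(y + 0.9) pseudo-count
  set.seed(33)
  for (i in 1:10) {
    n <- 30
    xv <- setNames(rnorm(n), sprintf("g%02d", 1:n))
    yv <- setNames(rpois(n, 3), sprintf("g%02d", 1:n))
    base <- rank_correlation(xv, yv)
    expect_equal(rank_correlation(xv, yv, log_transform = TRUE), base)
    mono <- sample(list(function(v) exp(v), function(v) v^3,
                        function(v) 5 * v + 2))[[1]]
    expect_equal(rank_correlation(mono(xv), yv), base)
  }

  expect_error(rank_correlation(x[1:2], x[1:2]), ">= 3")
})

test_that("P-body and ARE membership rules use the printed strict thresholds", {
  cov <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    pbody_fdr = c(0.005, 0.02, 0.005, 0.01),
    pbody_log2_enrichment = c(2.5, 5, 2, 3),
    are_count = c(0, 2, 1, 0)
  )
  m <- pbody_membership(cov)
  expect_identical(unname(m), c("enriched", "not_enriched", "not_enriched",
                                "not_enriched"))
  # b fails FDR despite huge enrichment; c fails the strict > 2; d fails
  # the strict < 0.01

  a <- are_membership(cov)
  expect_identical(unname(a), c("no_ARE", "ARE", "ARE", "no_ARE"))

  vals <- setNames(c(1, 3, 5, 2, 4), c("a", "b", "c", "d", "e"))
  grp <- setNames(c("g1", "g2", "g1", "g2", "g1"), names(vals))
  gc <- group_comparison(vals, grp)
  expect_equal(gc$median[gc$group == "g1"], 4)
  expect_equal(gc$median[gc$group == "g2"], 2.5)

  gc0 <- group_comparison(vals, grp, groups = c("g1", "g2", "empty"))
  expect_identical(gc0$n[gc0$group == "empty"], 0L)
  expect_true(is.na(gc0$median[gc0$group == "empty"]))
})

test_that("fold-change summaries behave under identity, scaling and depletion", {
  mk_table <- function(ab, cond, t) {
    m <- toy_counts(matrix(round(ab), length(ab), 1), times = t,
                    conds = cond)
    normalize_and_average(m, unit_factors(m))
  }
  ab <- c(100, 220, 80, 140, 60)
  t0 <- mk_table(ab, "control", 0)
  t1 <- mk_table(ab, "control", 4)
  fc <- foldchange_summary(t0, t1)
  expect_true(all(fc$per_gene$fold_change == 1))
  expect_equal(fc$per_condition$median_fold_change, 1)

  half <- mk_table(ab / 2, "control", 4)
  fc2 <- foldchange_summary(t0, half)
  expect_equal(fc2$per_condition$median_fold_change, 0.5)

  # rescaling both tables by the same constant changes nothing
  t0s <- mk_table(ab * 3, "control", 0)
  t1s <- mk_table(ab * 3 / 2, "control", 4)
  expect_equal(foldchange_summary(t0s, t1s)$per_condition,
               fc2$per_condition)

  # simulator-coupled directional check: a depletion condition with the
  # short-tail degradation hazard on loses more mRNA than the control
  cfg_on <- deadenylation_config(regime = "interphase", deg_hazard_per_h = 1,
                                 n_molecules = 4000, seed = 19)
  cfg_off <- deadenylation_config(regime = "mitotic", r_boundary = 0.3,
                                  deg_hazard_per_h = 1, n_molecules = 4000,
                                  seed = 19)
  surv <- function(cfg) {
    sim <- simulate_tails(cfg, 4)
    1 - sim$degraded_fraction
  }
  s_dep <- surv(cfg_on)    # PABPC protection lost: hazard fully felt
  s_ctl <- surv(cfg_off)   # protected: stalls above the hazard window
  ab0 <- c(1000, 1500, 800)
  dep0 <- mk_table(ab0, "depleted", 0)
  dep1 <- mk_table(ab0 * s_dep, "depleted", 4)
  ctl0 <- mk_table(ab0, "control", 0)
  ctl1 <- mk_table(ab0 * s_ctl, "control", 4)
  fc_dep <- foldchange_summary(dep0, dep1)$per_condition$median_fold_change
  fc_ctl <- foldchange_summary(ctl0, ctl1)$per_condition$median_fold_change
  expect_lt(fc_dep, fc_ctl)

  bad <- mk_table(ab[1:4], "control", 4)
  expect_error(foldchange_summary(t0, bad), "gene sets differ")
})
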