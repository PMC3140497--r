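# Ratio statistic, exact signed-rank test, and the resampling test with its
# analytic binomial tail.

test_that("pseudocount ratio is finite, positive, and matches hand values", {
  expect_equal(swimbladder_ratio(0, 0), 1.0)
  expect_equal(swimbladder_ratio(105, 29), 106 / 30)
  expect_equal(swimbladder_ratio(5, 0), 6.0)
  expect_equal(swimbladder_ratio(2.5, 0.5), 3.5 / 1.5)  # rationals post-averaging
  expect_error(swimbladder_ratio(-1, 2), "non-negative")
})

test_that("per-transect ratio pairs evaluate the pseudocount formula per mode", {
  u <- family_universe(c("Pinguipedidae", "Labridae"), c(FALSE, TRUE))
  tab <- abundance_frame(
    cell("Pinguipedidae", "sponging", "T1", 4),
    cell("Labridae", "sponging", "T1", 1),
    cell("Labridae", "non_sponging", "T1", 3))
  pr <- transect_ratio_pairs(tab, u)
  expect_equal(pr$values_a, 2.5)
  expect_equal(pr$values_b, 0.25)

  # identical counts in both modes give a tied pair; an empty transect the
  # degenerate (1, 1) pair
  tab2 <- abundance_frame(
    cell("Pinguipedidae", "sponging", "T1", 2),
    cell("Pinguipedidae", "non_sponging", "T1", 2))
  pr2 <- transect_ratio_pairs(tab2, u, transect_ids = c("T1", "T2"))
  expect_equal(pr2$values_a[1], pr2$values_b[1])
  expect_equal(pr2$values_a[2], 1.0)
  expect_equal(pr2$values_b[2], 1.0)

  tab3 <- abundance_frame(cell("Sparidae", "sponging", "T1", 1))
  expect_error(transect_ratio_pairs(tab3, u), "Sparidae")
})

test_that("abundance pairs use the sponging-extracted family set only", {
  tab <- abundance_frame(
    cell("Pinguipedidae", "sponging", "T1", 3),
    cell("Pinguipedidae", "non_sponging", "T1", 1),
    cell("Nemipteridae", "non_sponging", "T1", 29))  # never during sponging
  pr <- extracted_family_abundance_pairs(tab)
  expect_equal(pr$values_a, 3)
  expect_equal(pr$values_b, 1)  # Nemipteridae excluded from both sides

  tab2 <- abundance_frame(
    cell("Pinguipedidae", "sponging", "T1", 2),
    cell("Pinguipedidae", "sponging", "T2", 5))
  pr2 <- extracted_family_abundance_pairs(tab2)
  expect_equal(pr2$values_b, c(0, 0))
})

test_that("exact signed-rank test reproduces hand and oracle results", {
  # seven all-positive differences: the unique extreme outcome
  res <- wilcoxon_signed_rank_exact(11:17, rep(1, 7))
  expect_equal(res$w_statistic, 28)
  expect_equal(res$p_two_sided, 2 / 128)
  expect_equal(res$n_effective, 7)
  expect_equal(res$method, "exact-enumeration")

  # single pair: p is capped at 1
  res1 <- wilcoxon_signed_rank_exact(5, 0)
  expect_equal(res1$w_statistic, 1)
  expect_equal(res1$p_two_sided, 1.0)

  # mixed signs vs the literal sign-vector oracle
  oracle <- wilcoxon_brute(c(1, 2, -3, 4), rep(0, 4))
  res4 <- wilcoxon_signed_rank_exact(c(1, 2, -3, 4), rep(0, 4))
  expect_equal(res4$w_statistic, oracle$w)
  expect_equal(res4$p_two_sided, oracle$p)

  # zero differences are dropped before ranking
  resz <- wilcoxon_signed_rank_exact(c(2, 3, 5, 5), c(1, 1, 5, 5))
  expect_equal(resz$n_effective, 2)

  expect_error(wilcoxon_signed_rank_exact(c(1, 2), c(1, 2)), "degenerate")
  expect_error(wilcoxon_signed_rank_exact(1:25, rep(0, 25)), "cap")
})

test_that("enumeration matches the brute-force oracle across random samples", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    a <- sample(-4:6, n, replace = TRUE)  # integer values force ties
    b <- sample(-4:6, n, replace = TRUE)
    if (all(a == b)) next
    oracle <- wilcoxon_brute(a, b)
    res <- wilcoxon_signed_rank_exact(a, b)
    expect_equal(res$w_statistic, oracle$w)
    expect_equal(res$p_two_sided, oracle$p, tolerance = 1e-12)
    expect_equal(res$n_effective, oracle$n)
  }
})

test_that("negating all differences reflects W and preserves the p-value", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    d <- stats::rnorm(n)
    d <- d[d != 0]
    res <- wilcoxon_signed_rank_exact(d, rep(0, length(d)))
    neg <- wilcoxon_signed_rank_exact(-d, rep(0, length(d)))
    n_eff <- res$n_effective
    expect_equal(neg$w_statistic, n_eff * (n_eff + 1) / 2 - res$w_statistic)
    expect_equal(neg$p_two_sided, res$p_two_sided)
    expect_gte(res$p_two_sided, 2 / 2^n_eff)
  }
})

test_that("analytic binomial two-tail matches frozen and degenerate values", {
  # deviation rule: only the upper tail clears the observed deviation here;
  # frozen from the closed form sum(choose(8, 6:8) p^x (1-p)^(8-x)), p = 9/29
  expect_equal(exact_binomial_twotail(29, 9, 8, 6), 0.013514261743,
               tolerance = 1e-10)
  # observed equals the expectation: every outcome qualifies
  expect_equal(exact_binomial_twotail(2, 1, 2, 1), 1.0)
  # degenerate universe: X is deterministic
  expect_equal(exact_binomial_twotail(10, 10, 4, 4), 1.0)
  expect_error(exact_binomial_twotail(0, 0, 4, 2), "universe_size")

  # doubling rule agrees with the binomial CDF construction
  expect_equal(exact_binomial_twotail(29, 9, 8, 6, two_tail = "doubling"),
               min(1, 2 * min(pbinom(6, 8, 9 / 29),
                              1 - pbinom(5, 8, 9 / 29))))
})

test_that("Monte Carlo resampling tracks the analytic tail and is seeded", {
  u <- catalog_universe(make_default_catalog())  # 29 families, 9 without SB
  res <- family_resampling_test(u, n_draw = 8, observed_no_sb = 6,
                                reps = 10000, seed = 3)
  mcse <- sqrt(res$p_exact * (1 - res$p_exact) / res$reps)
  expect_lte(abs(res$p_mc - res$p_exact), 3 * mcse)
  expect_equal(res$p_exact, exact_binomial_twotail(29, 9, 8, 6))

  # bit-identical under the same seed
  res2 <- family_resampling_test(u, n_draw = 8, observed_no_sb = 6,
                                 reps = 10000, seed = 3)
  expect_identical(res$p_mc, res2$p_mc)

  # convergence at large rep count
  big <- family_resampling_test(u, n_draw = 8, observed_no_sb = 6,
                                reps = 1e6, seed = 4)
  expect_lt(abs(big$p_mc - big$p_exact), 0.005)

  # all-swimbladdered universe: deviation is identically zero
  u0 <- family_universe(paste0("F", 1:5), rep(TRUE, 5))
  res0 <- family_resampling_test(u0, n_draw = 4, observed_no_sb = 0,
                                 reps = 500, seed = 1)
  expect_equal(res0$p_mc, 1.0)
  expect_equal(res0$p_exact, 1.0)

  expect_error(family_resampling_test(u, n_draw = 8, observed_no_sb = 6,
                                      reps = 0, seed = 1), "reps")
})

test_that("resampling converges for assorted universe configurations", {
  set.seed(9)
  configs <- data.frame(n_u = c(29, 12, 40), k = c(9, 5, 2),
                        m = c(8, 6, 10), obs = c(6, 5, 3))
  for (i in seq_len(nrow(configs))) {
    u <- family_universe(paste0("F", seq_len(configs$n_u[i])),
                         seq_len(configs$n_u[i]) > configs$k[i])
    res <- family_resampling_test(u, n_draw = configs$m[i],
                                  observed_no_sb = configs$obs[i],
                                  reps = 1e5, seed = 100 + i)
    mcse <- sqrt(res$p_exact * (1 - res$p_exact) / res$reps)
    expect_lte(abs(res$p_mc - res$p_exact), 4 * mcse + 1e-12)
  }
})

test_that("the observed sponging family statistic is computed from data", {
  stat <- sponging_family_stat(pooled_long(study_pooled_counts()),
                               study_family_universe())
  expect_equal(stat$n_families, 8)
  expect_equal(stat$n_no_sb, 6)
})
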