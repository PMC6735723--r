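## Bootstrap machinery, trimming, summaries, trend/pairwise tests,
## FDR correction and variance partitioning.

make_unit_spectra <- function(n_units, seed = 1, Ls = 2e4, Ln = 6e4) {
  units <- data.frame(unit_id = sprintf("u%02d", seq_len(n_units)),
                      Ls = Ls, Ln = Ln)
  simulate_spectra(units, default_true_dfe(), n = 10, seed = seed)$spectra
}

test_that("identity-mode bootstrap replicates equal the point estimate", {
  sp <- make_unit_spectra(4)
  b <- bootstrap_categories(list(A = names(sp)), sp, B = 1, seed = 1,
                            family = "Gamma", resample = FALSE)
  expect_equal(b$replicates$A$omega_a, b$point["A", "omega_a"],
               tolerance = 1e-3)   # replicate refits use a looser optim tol
})

test_that("bootstrap results are reproducible given the seed", {
  sp <- make_unit_spectra(6)
  b1 <- bootstrap_categories(list(A = names(sp)[1:3], B = names(sp)[4:6]),
                             sp, B = 4, seed = 7, family = "Gamma")
  b2 <- bootstrap_categories(list(A = names(sp)[1:3], B = names(sp)[4:6]),
                             sp, B = 4, seed = 7, family = "Gamma")
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_categories(list(A = names(sp)[1:3]), sp, B = 4, seed = 8,
                             family = "Gamma")
  expect_false(identical(b1$replicates$A, b3$replicates$A))
})

test_that("trimming drops strict 1%/99% exceedances on mean and shape", {
  ## extremes of the two parameters on different replicates: 4 dropped
  b <- crafted_bootstrap(mean_del = 1:100, shape = c(51:100, 1:50))
  t1 <- trim_replicates(b)
  expect_equal(unname(t1$retained["A"]), 96L)
  expect_false(any(t1$replicates$A$mean_del %in% c(1, 100)))
  expect_false(any(t1$replicates$A$shape %in% c(1, 100)))

  ## extremes coincide on the same replicates: only 2 dropped
  b2 <- crafted_bootstrap(mean_del = 1:100, shape = 1:100)
  expect_equal(unname(trim_replicates(b2)$retained["A"]), 98L)

  ## identical replicates: nothing strictly exceeds the percentiles
  b3 <- crafted_bootstrap(mean_del = rep(5, 100), shape = rep(1, 100))
  expect_equal(unname(trim_replicates(b3)$retained["A"]), 100L)

  ## failed replicates always dropped
  b4 <- crafted_bootstrap(mean_del = 1:20, shape = 1:20)
  b4$replicates$A$ok[3] <- FALSE
  expect_lte(unname(trim_replicates(b4)$retained["A"]), 17L)
})

test_that("summaries use the mean and the percentile 95% interval", {
  b <- crafted_bootstrap(mean_del = 1:100, shape = 1:100)
  b$replicates$A$omega_a <- 1:100
  s <- summarize_bootstrap(b, stats = "omega_a")
  expect_equal(s$mean, 50.5)
  expect_equal(s$ci_low, 3.475)
  expect_equal(s$ci_high, 97.525)
  expect_lte(s$ci_low, s$ci_high)
  ## constant replicates collapse the interval
  b$replicates$A$omega_a <- rep(2, 100)
  s2 <- summarize_bootstrap(b, stats = "omega_a")
  expect_equal(c(s2$mean, s2$ci_low, s2$ci_high), c(2, 2, 2))
})

test_that("Kendall trend has known tau values and antisymmetry", {
  expect_equal(kendall_trend(c(1, 2, 3))$statistic, 1)
  expect_equal(kendall_trend(c(1, 3, 2))$statistic, 1 / 3)
  t1 <- kendall_trend(c(0.1, 0.4, 0.2, 0.8, 0.9))
  t2 <- kendall_trend(rev(c(0.1, 0.4, 0.2, 0.8, 0.9)))
  expect_equal(t1$statistic, -t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
  expect_true(is.na(kendall_trend(rep(1, 5))$statistic))
})

test_that("pairwise bootstrap test applies P = (2k+1)/(N+1)", {
  ## all 100 differences positive: k = 0
  r <- pairwise_bootstrap_test(101:200, 1:100, mode = "index")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 101)
  ## exactly 10 sign flips: k = 10
  a <- c(rep(0, 10), rep(2, 90)); b <- rep(1, 100)
  r2 <- pairwise_bootstrap_test(a, b, mode = "index")
  expect_equal(r2$statistic, 10)
  expect_equal(r2$p_value, 21 / 101)
  ## balanced differences: maximal P = 1
  r3 <- pairwise_bootstrap_test(c(rep(0, 50), rep(2, 50)), rep(1, 100),
                                mode = "index")
  expect_equal(r3$p_value, 1)
  ## zero differences split evenly keeps P at its maximum
  r4 <- pairwise_bootstrap_test(rep(1, 100), rep(1, 100), mode = "index")
  expect_equal(r4$p_value, 1)
  ## shorter list padded by resampling, deterministic given seed
  r5 <- pairwise_bootstrap_test(rnorm(50, 5), rnorm(100), seed = 3)
  r6 <- pairwise_bootstrap_test(rnorm(50, 5), rnorm(100), seed = 3)
  expect_equal(r5$p_value, r6$p_value)
})

test_that("BH adjustment matches hand application and preserves order", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(c(0.04, 0.5)), c(0.08, 0.5))
  expect_equal(fdr_adjust(0.2), 0.2)
  p <- c(0.04, 0.001, 0.3, 0.02)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  ## monotone nondecreasing in sorted order
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("variance partition attributes a pure-RSA response to RSA", {
  set.seed(1)
  rsa <- seq(0, 1, length.out = 20)
  disorder <- rnorm(20)
  y <- 2 + 3 * rsa + rnorm(20, sd = 1e-6)
  part <- ancova_partition(y, rsa, disorder)
  expect_equal(part$fraction[part$term == "rsa"], 1, tolerance = 1e-6)
  expect_equal(sum(part$fraction), 1, tolerance = 1e-10)
  ## noise response: fractions still sum to one, residual dominates
  y2 <- rnorm(20)
  part2 <- ancova_partition(y2, rsa, disorder)
  expect_equal(sum(part2$fraction), 1, tolerance = 1e-10)
  expect_gt(part2$fraction[part2$term == "residual"], 0.5)
  expect_error(ancova_partition(y, rsa, rsa * 2), "collinear")
})

test_that("null-noise variance fractions match their degrees of freedom", {
  ## under a pure-noise response the expected per-term fraction is
  ## df/(n-1); checked against simulation
  set.seed(42)
  n <- 24
  fr <- replicate(300, {
    p <- ancova_partition(rnorm(n), rnorm(n), rnorm(n))
    p$fraction[p$term == "rsa"]
  })
  expect_equal(mean(fr), 1 / (n - 1), tolerance = 0.25)
})
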