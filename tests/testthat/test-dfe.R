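## Sojourn/fixation kernels, quadrature accuracy, expected spectra,
## likelihood, fitting, nesting and model comparison.

test_that("sojourn density has the neutral limit and known values", {
  x <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  expect_equal(sojourn_weight(x, 0), 1 / x)
  expect_equal(sojourn_weight(0.5, 1), 2.489837, tolerance = 1e-6)
  ## strong purifying selection removes high-frequency sojourn time
  expect_lt(sojourn_weight(0.5, -1e4), 1e-300)
  ## stability at the extremes the optimizer can visit
  expect_true(is.finite(sojourn_weight(0.999, 1e4)))
  expect_true(is.finite(sojourn_weight(0.001, -1e4)))
  expect_error(sojourn_weight(0, 1), "inside")
})

test_that("relative fixation probability has known values and asymptotics", {
  expect_equal(fixation_ratio(0), 1)
  expect_equal(fixation_ratio(2), 2.313035, tolerance = 1e-6)
  expect_equal(fixation_ratio(1e4), 1e4)
  expect_equal(fixation_ratio(-1e4), 0)
  expect_equal(fixation_ratio(-1e6), 0)   # beyond expm1 overflow
})

test_that("neutral SFS weights equal 1/i exactly within quadrature tolerance", {
  expect_equal(sfs_weight(0, 1:9, 10), 1 / (1:9), tolerance = 1e-10)
})

test_that("SFS weights match a brute-force fine-grid oracle", {
  ## 10^5-interval midpoint rule, independent of the Gauss-Legendre path
  oracle <- function(S, i, n) {
    x <- (seq_len(1e5) - 0.5) / 1e5
    mean(choose(n, i) * x^i * (1 - x)^(n - i) * sojourn_weight(x, S))
  }
  n <- 10
  for (S in c(-100, -10, -1, 0, 1, 10, 100)) {
    got <- sfs_weight(S, 1:9, n)
    want <- vapply(1:9, function(i) oracle(S, i, n), numeric(1))
    expect_equal(got, want, tolerance = 1e-4)
  }
  ## deleterious mass shifts toward low frequencies
  expect_lt(sfs_weight(-50, 9, 10), sfs_weight(-50, 1, 10))
})

test_that("expected spectrum has the neutral closed form", {
  for (n in c(4, 10, 20)) {
    e <- expected_spectrum(dfe_params("Neutral", theta = 0.01), n,
                           Ls = 1000, Ln = 3000)
    i <- seq_len(n - 1)
    expect_equal(e$e_syn, 10 / i, tolerance = 1e-8)
    expect_equal(e$e_nonsyn, 30 / i, tolerance = 1e-8)
  }
})

test_that("GammaExpo with p_b = 0 reduces to the Gamma family", {
  g <- dfe_params("Gamma", theta = 0.01, shape = 0.4, mean_del = 500)
  ge <- dfe_params("GammaExpo", theta = 0.01, shape = 0.4, mean_del = 500,
                   p_b = 0, mean_ben = 10)
  e1 <- expected_spectrum(g, 10, 1000, 3000)
  e2 <- expected_spectrum(ge, 10, 1000, 3000)
  expect_equal(e1$e_nonsyn, e2$e_nonsyn)
})

test_that("purifying selection makes the nonsyn/syn ratio decrease with frequency", {
  p <- dfe_params("Gamma", theta = 0.01, shape = 0.3, mean_del = 1000)
  e <- expected_spectrum(p, 10, 1000, 1000)
  ratio <- e$e_nonsyn / e$e_syn
  expect_true(all(diff(ratio) < 0))
})

test_that("Poisson log-likelihood matches hand evaluation", {
  ## n = 2: single frequency class per mutation type; theta Ls = theta Ln = 2
  s <- spectrum_set(2, Ls = 200, Ln = 200, sfs_syn = 2, sfs_nonsyn = 2)
  ll <- poisson_loglik(dfe_params("Neutral", theta = 0.01), s)
  expect_equal(ll, 2 * (2 * log(2) - 2 - log(2)), tolerance = 1e-12)
  ## zero expectation with positive observation
  s0 <- spectrum_set(2, Ls = 0, Ln = 200, sfs_syn = 2, sfs_nonsyn = 0)
  expect_equal(poisson_loglik(dfe_params("Neutral", theta = 0.01), s0),
               -Inf)
})

test_that("likelihood is invariant to the scale decomposition of theta", {
  p1 <- dfe_params("Gamma", theta = 0.01, shape = 0.3, mean_del = 100)
  s <- spectrum_set(10, 1000, 3000, rpois(9, 10 / (1:9)),
                    rpois(9, 20 / (1:9)))
  ## doubling all observations and expectations shifts the loglik by a
  ## computable amount: recompute directly from the Poisson pmf
  e <- expected_spectrum(p1, 10, 1000, 3000)
  direct <- sum(dpois(s$sfs_syn, e$e_syn, log = TRUE)) +
    sum(dpois(s$sfs_nonsyn, e$e_nonsyn, log = TRUE))
  expect_equal(poisson_loglik(p1, s), direct, tolerance = 1e-10)
})

test_that("theta is recovered from Neutral simulations", {
  p <- dfe_params("Neutral", theta = 0.01)
  units <- data.frame(unit_id = "u", Ls = 1e6, Ln = 3e6)
  err <- replicate(5, {
    sim <- simulate_spectra(units, p, n = 10,
                            seed = sample.int(1e6, 1))
    f <- fit_dfe(sim$spectra[[1]], "Neutral")
    f$params$theta - 0.01
  })
  ## MC standard error of theta-hat at this scale
  se <- sqrt(0.01 / (1e6 * sum(1 / (1:9)) + 3e6 * sum(1 / (1:9))))
  expect_lt(abs(median(err)), 3 * se * 5)
  ## Neutral family fixes omega_na = 1
  sim <- simulate_spectra(units, p, n = 10, seed = 3)
  f <- fit_dfe(sim$spectra[[1]], "Neutral")
  expect_equal(f$omega_na, 1)
  expect_equal(f$alpha, 1 - 1 / f$omega)
})

test_that("maximized likelihoods respect family nesting", {
  sim <- simulate_spectra(data.frame(unit_id = "u", Ls = 2e5, Ln = 6e5),
                          default_true_dfe(), n = 20, seed = 9)
  s <- sim$spectra[[1]]
  f_n <- fit_dfe(s, "Neutral")
  f_g <- fit_dfe(s, "Gamma")
  f_ge <- fit_dfe(s, "GammaExpo")
  expect_gte(f_ge$loglik, f_g$loglik - 1e-6)
  expect_gte(f_g$loglik, f_n$loglik - 1e-6)
})

test_that("alpha decomposition follows the defining identities", {
  s <- spectrum_set(4, Ls = 1000, Ln = 3000, sfs_syn = c(5, 2, 1),
                    sfs_nonsyn = c(6, 2, 1), Ds = 100, Dn = 60)
  d <- alpha_decompose(dfe_params("Neutral", theta = 0.01), s)
  expect_equal(unname(d["omega"]), (60 / 3000) / (100 / 1000))
  expect_equal(unname(d["omega_na"]), 1)
  expect_equal(unname(d["omega_a"]), unname(d["omega"] - d["omega_na"]))
  expect_equal(unname(d["alpha"]), unname(d["omega_a"] / d["omega"]))
  ## strong purifying selection drives omega_na toward 0
  strong <- dfe_params("Gamma", theta = 0.01, shape = 0.3, mean_del = 1e6)
  weak <- dfe_params("Gamma", theta = 0.01, shape = 0.3, mean_del = 1)
  d2 <- alpha_decompose(strong, s)
  expect_lt(unname(d2["omega_na"]), 0.05)
  mid <- dfe_params("Gamma", theta = 0.01, shape = 0.3, mean_del = 1e3)
  expect_lt(unname(d2["omega_na"]),
            unname(alpha_decompose(mid, s)["omega_na"]))
  expect_gt(unname(alpha_decompose(weak, s)["omega_na"]), 0.5)
  ## omega undefined without synonymous substitutions
  s$Ds <- 0
  expect_error(alpha_decompose(strong, s), "Ds")
})

test_that("fit results satisfy the AIC identity and parameter counts", {
  sim <- simulate_spectra(data.frame(unit_id = "u", Ls = 2e5, Ln = 6e5),
                          default_true_dfe(), n = 10, seed = 2)
  cm <- compare_models(sim$spectra[[1]])
  expect_equal(cm$aic, 2 * cm$n_params - 2 * cm$loglik)
  expect_equal(sort(cm$n_params), c(1L, 3L, 5L))
  expect_equal(cm$aic, sort(cm$aic))        # ranked ascending
  expect_equal(cm$delta_aic[1L], 0)
})

test_that("folded spectra are fitted by folding the expectation", {
  sim <- simulate_spectra(data.frame(unit_id = "u", Ls = 5e5, Ln = 15e5),
                          default_true_dfe(), n = 10, seed = 4)
  s <- sim$spectra[[1]]
  f_unf <- fit_dfe(s, "Gamma")
  f_fold <- fit_dfe(fold_spectrum(s), "Gamma")
  ## same data folded: estimates agree loosely (folding loses information)
  expect_equal(f_fold$params$theta, f_unf$params$theta, tolerance = 0.1)
  expect_true(is.finite(f_fold$loglik))
})

test_that("nuisance r multipliers absorb per-class distortions", {
  p <- dfe_params("Neutral", theta = 0.01)
  e <- expected_spectrum(p, 6, 1e5, 3e5)
  distort <- c(1, 1.5, 0.7, 1.2, 0.9)
  s <- spectrum_set(6, 1e5, 3e5, round(e$e_syn * distort),
                    round(e$e_nonsyn * distort))
  f <- fit_dfe(s, "Neutral", use_r = TRUE)
  expect_equal(length(f$params$r), 4L)
  expect_equal(f$n_params, 1L + 4L)
  expect_equal(unname(f$params$r), distort[-1L] / distort[1L],
               tolerance = 0.05)
})
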