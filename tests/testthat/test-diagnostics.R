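test_that("R-hat matches direct evaluation of the PSRF formula", {
  # identical chains: B = 0, Vhat = (n-1)/n * W
  expect_equal(gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               sqrt(3 / 4), tolerance = 1e-12)

  # well-separated chains blow up
  set.seed(1)
  a <- rnorm(1000); b <- rnorm(1000, 10)
  expect_gt(gelman_rubin(list(a, b)), 3)

  # direct formula on arbitrary chains
  set.seed(2)
  ch <- list(rnorm(50, 0, 1), rnorm(50, 0.3, 1.4), rnorm(50, -0.2, 0.7))
  W <- mean(sapply(ch, var))
  Bn <- var(sapply(ch, mean))
  expect_equal(gelman_rubin(ch), sqrt(((50 - 1) / 50 * W + Bn) / W),
               tolerance = 1e-12)

  # converges to 1 for same-distribution chains
  set.seed(3)
  expect_lt(gelman_rubin(list(rnorm(10000), rnorm(10000))), 1.01)
})

test_that("R-hat is affine invariant and rejects degenerate input", {
  set.seed(4)
  ch <- list(rnorm(200), rnorm(200))
  shifted <- lapply(ch, function(x) -3.2 * x + 7)
  expect_equal(gelman_rubin(ch), gelman_rubin(shifted), tolerance = 1e-12)
  expect_error(gelman_rubin(list(rnorm(10))), "two chains")
  expect_error(gelman_rubin(list(rep(1, 10), rep(1, 10))), "degenerate")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(6))), "equal length")
})

test_that("effective sample size is bounded by the draw count", {
  set.seed(5)
  iid <- list(rnorm(2000), rnorm(2000))
  e <- smallarea:::ess_chains(iid)
  expect_lte(e, 4000 * 1.05)          # estimator noise margin above n
  expect_gt(e, 2000)                  # iid draws are nearly fully efficient
  ar <- list(as.numeric(stats::arima.sim(list(ar = 0.9), 2000)))
  expect_lt(smallarea:::ess_chains(ar), 600)
})

test_that("DIC satisfies its algebraic identity and degenerates correctly", {
  # degenerate posterior: every draw identical -> pD = 0
  s0 <- manual_samples(rep(-0.3, 50), expected = c(1, 2), observed = c(1L, 3L))
  d0 <- compute_dic(s0)
  expect_equal(d0$pD, 0, tolerance = 1e-9)
  expect_equal(d0$DIC,
               -2 * log_likelihood(list(alpha = -0.3, beta = numeric(0)),
                                   s0$data),
               tolerance = 1e-9)

  # identity on a real fit
  ds <- simulate_dataset(generator_config(n_rows = 4, n_cols = 5, seed = 41))
  f <- fit_bym(compute_expected(ds$area_table), ds$graph,
               covariates = "immigration",
               mcmc = quick_mcmc(43, n_iter = 3000, burn_in = 500))
  expect_equal(f$dic$DIC, f$dic$Dhat + 2 * f$dic$pD, tolerance = 1e-9)
  expect_true(is.finite(f$dic$pD))

  empty <- manual_samples(numeric(0))
  expect_error(compute_dic(empty), "no retained draws")
})

test_that("the convergence report flags mixed and unmixed runs sensibly", {
  ds <- simulate_dataset(generator_config(n_rows = 4, n_cols = 5, seed = 47))
  tab <- compute_expected(ds$area_table)
  s <- run_mcmc(tab, ds$graph, model_spec("immigration"),
                quick_mcmc(49, n_iter = 6000, burn_in = 1000))
  rep <- convergence_report(s)
  expect_setequal(rep$parameter,
                  c("alpha", "beta_immigration", "sigma_S", "sigma_H"))
  expect_true(all(rep$rhat > 0))
  expect_true(all(rep$ess <= nrow(s$draws)))
  # single chain cannot produce R-hat
  s1 <- run_mcmc(tab, ds$graph, model_spec("immigration"),
                 mcmc_config(n_iter = 2000, burn_in = 300, n_chains = 1,
                             thin = 5, seed = 1))
  expect_error(convergence_report(s1), "two chains")
})
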