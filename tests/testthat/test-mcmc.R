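test_that("the sampler is reproducible from its seed", {
  ds <- simulate_dataset(generator_config(n_rows = 4, n_cols = 5, seed = 13))
  tab <- compute_expected(ds$area_table)
  spec <- model_spec(c("immigration", "policing"))
  cfg <- quick_mcmc(17, n_iter = 2000, burn_in = 300)
  s1 <- run_mcmc(tab, ds$graph, spec, cfg)
  s2 <- run_mcmc(tab, ds$graph, spec, cfg)
  expect_identical(s1$draws, s2$draws)
  s3 <- run_mcmc(tab, ds$graph, spec, quick_mcmc(18, n_iter = 2000,
                                                 burn_in = 300))
  expect_false(identical(s1$draws$alpha, s3$draws$alpha))
})

test_that("post-adaptation acceptance rates sit in the efficient band", {
  ds <- simulate_dataset(generator_config(seed = 19))
  tab <- compute_expected(ds$area_table)
  s <- run_mcmc(tab, ds$graph,
                model_spec(c("immigration", "policing", "physical_disorder")),
                quick_mcmc(23, n_iter = 16000, burn_in = 8000))
  rw <- s$accept[!is.na(s$accept$accept_rate), ]
  expect_gt(nrow(rw), 0)
  expect_true(all(rw$accept_rate >= 0.2 & rw$accept_rate <= 0.6))
})

test_that("retained draws respect the model constraints", {
  ds <- simulate_dataset(generator_config(n_rows = 4, n_cols = 5, seed = 29))
  tab <- compute_expected(ds$area_table)
  s <- run_mcmc(tab, ds$graph, model_spec(c("immigration")),
                quick_mcmc(31, n_iter = 3000, burn_in = 500))
  n <- ds$graph$n_areas
  expect_equal(nrow(s$draws),
               2 * floor((3000 - 500) / 5))
  Smat <- as.matrix(s$draws[paste0("S_", seq_len(n))])
  expect_lt(max(abs(rowSums(Smat))), 1e-9)
  expect_true(all(s$draws$sigma_S > 0 & s$draws$sigma_S <= 1))
  expect_true(all(s$draws$sigma_H > 0 & s$draws$sigma_H <= 1))
  expect_true(all(is.finite(s$draws$loglik)))
})

test_that("prior-only sampling reproduces the prior moments", {
  tab <- tibble::tibble(area_id = as.character(1:4),
                        observed = c(1L, 2L, 1L, 0L),
                        population = rep(100L, 4), x = c(0.5, -1, 0, 1))
  tab <- compute_expected(tab)
  g <- lattice_graph(2, 2)
  # beta variance against its vague prior, ~50k draws
  sb <- run_mcmc(tab, g, model_spec("x"),
                 mcmc_config(n_iter = 205000, burn_in = 5000, thin = 4,
                             n_chains = 1, seed = 2),
                 likelihood = FALSE)
  expect_lt(abs(var(sb$draws$beta_x) / 1e5 - 1), 0.05)
  # sigma marginals against U(0,1): heavy thinning for near-independence
  keep <- seq(1, nrow(sb$draws), by = 13) # net thin 52
  expect_gt(stats::ks.test(sb$draws$sigma_S[keep], "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(sb$draws$sigma_H[keep], "punif")$p.value, 0.01)
})

test_that("island areas are rejected by default and pinned on request", {
  tab <- tibble::tibble(area_id = as.character(1:3),
                        observed = c(2L, 1L, 3L), population = rep(200L, 3))
  tab <- compute_expected(tab)
  g <- area_graph(list(2L, 1L, integer(0))) # area 3 isolated
  spec <- model_spec(character(0))
  expect_error(run_mcmc(tab, g, spec, quick_mcmc(1, n_iter = 500,
                                                 burn_in = 100)),
               "island")
  expect_warning(
    s <- run_mcmc(tab, g, spec, quick_mcmc(1, n_iter = 500, burn_in = 100),
                  islands = "pin"),
    "pinned")
  expect_true(all(s$draws$S_3 == 0))
})
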