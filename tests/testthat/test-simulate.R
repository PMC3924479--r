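test_that("truncated-normal covariates respect their bounds and moments", {
  cfg <- generator_config(seed = 42)
  X <- sample_covariates(cfg, 80, seed = 42)
  expect_true(all(X$immigration >= 6.33 & X$immigration <= 33.17))
  expect_true(all(X$physical_disorder >= 0 & X$physical_disorder <= 16))

  # sd = 0 gives a constant column
  cfg0 <- generator_config(
    covariate_specs = list(flat = c(mean = 3, sd = 0, min = 0, max = 5)),
    true_beta = c(flat = 0), seed = 1)
  expect_equal(sample_covariates(cfg0, 10, seed = 1)$flat, rep(3, 10))

  # degenerate bounds rejected
  expect_error(generator_config(
    covariate_specs = list(bad = c(mean = 2, sd = 1, min = 2, max = 2)),
    true_beta = NULL), "min >= max|min <= mean", fixed = FALSE)

  # empirical mean against the closed-form truncated-normal expectation
  cfg1 <- generator_config(
    covariate_specs = list(imm = c(mean = 16.58, sd = 6.85, min = 6.33,
                                   max = 33.17)),
    true_beta = c(imm = 0), seed = 9)
  x <- sample_covariates(cfg1, 10000, seed = 9)$imm
  mu <- truncnorm_mean(16.58, 6.85, 6.33, 33.17)
  expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
})

test_that("ICAR field draws live on the sum-to-zero subspace with the
           pairwise-difference covariance", {
  g <- lattice_graph(3, 3)
  S <- sample_icar_field(g, 0, seed = 1)
  expect_equal(S, rep(0, 9))

  S <- sample_icar_field(g, 0.5, seed = 2)
  expect_lt(abs(sum(S)), 1e-9)

  # disconnected graph: zero sum per component
  nb <- c(lattice_graph(2, 2)$neighbors,
          lapply(lattice_graph(2, 2)$neighbors, function(v) v + 4L))
  g2 <- area_graph(nb)
  S2 <- sample_icar_field(g2, 1, seed = 3)
  expect_lt(abs(sum(S2[1:4])), 1e-9)
  expect_lt(abs(sum(S2[5:8])), 1e-9)

  expect_error(sample_icar_field(g, -0.1), ">= 0")

  # 2-node path: the joint density is exp(-(S1-S2)^2 / (2 sigma^2)), so the
  # difference has variance sigma^2 (the single positive Laplacian
  # eigenvalue is 2, carried by the eigenvector (1,-1)/sqrt(2))
  gp <- area_graph(list(2L, 1L))
  set.seed(11)
  d <- replicate(20000, { s <- sample_icar_field(gp, 1); s[1] - s[2] })
  expect_lt(abs(var(d) - 1), 0.05)

  # empirical covariance matches sigma^2 * pseudo-inverse of Q on a lattice
  Q <- icar_structure(g)
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-8
  Qpinv <- eg$vectors[, pos] %*% diag(1 / eg$values[pos]) %*%
    t(eg$vectors[, pos])
  set.seed(12)
  draws <- t(replicate(6000, sample_icar_field(g, 0.7)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - 0.49 * Qpinv)), 0.06)
})

test_that("the generator is deterministic and internally consistent", {
  cfg <- generator_config(seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$area_table, d2$area_table)
  expect_identical(d1$truth, d2$truth)

  # truth record reproduces lambda exactly from the linear predictor
  X <- as.matrix(d1$area_table[names(d1$truth$beta)])
  lam <- exp(d1$truth$alpha + as.numeric(X %*% d1$truth$beta) +
               d1$truth$S + d1$truth$H)
  expect_equal(d1$truth$lambda, lam, tolerance = 1e-12)
  expect_true(all(d1$area_table$observed >= 0))
  expect_lt(abs(sum(d1$truth$S)), 1e-9)

  # null model: all effects off gives unit relative risk everywhere
  cfg0 <- generator_config(true_alpha = 0, true_beta = NULL,
                           true_sigma_S = 0, true_sigma_H = 0, seed = 3)
  d0 <- simulate_dataset(cfg0)
  expect_equal(d0$truth$lambda, rep(1, 80))
})

test_that("counts are Poisson around lambda * E", {
  # deterministic lambda (constant covariates, no random effects): replicate
  # emissions should average to lambda * E within Monte-Carlo error
  cfg <- generator_config(
    n_rows = 2, n_cols = 2,
    covariate_specs = list(z = c(mean = 1, sd = 0, min = 1, max = 1)),
    population_spec = c(mean = 500, sd = 0, min = 500, max = 500),
    true_alpha = 0.2, true_beta = c(z = 0.3),
    true_sigma_S = 0, true_sigma_H = 0, baseline_total = 40, seed = 1)
  lamE <- exp(0.2 + 0.3) * 10 # E_i = 40/4 areas
  O <- vapply(seq_len(400), function(s)
    simulate_dataset(generator_config(
      n_rows = 2, n_cols = 2,
      covariate_specs = list(z = c(mean = 1, sd = 0, min = 1, max = 1)),
      population_spec = c(mean = 500, sd = 0, min = 500, max = 500),
      true_alpha = 0.2, true_beta = c(z = 0.3),
      true_sigma_S = 0, true_sigma_H = 0, baseline_total = 40,
      seed = s))$area_table$observed[1], numeric(1))
  se <- sqrt(lamE / length(O))
  expect_lt(abs(mean(O) - lamE), 3 * se)
})
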