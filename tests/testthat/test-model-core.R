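test_that("Poisson log-likelihood matches closed forms and an independent
           oracle", {
  one <- tibble::tibble(area_id = "a", observed = 0L, population = 100L,
                        expected = 1)
  zero_state <- list(alpha = 0, beta = numeric(0))
  expect_equal(log_likelihood(zero_state, one), -1)

  two <- dplyr::bind_rows(one, dplyr::mutate(one, area_id = "b"))
  two$expected <- two$expected * sum(two$observed + 0) # keep E as given
  two$expected <- c(1, 1)
  expect_equal(
    log_likelihood(zero_state, dplyr::mutate(two, observed = c(0L, 0L))),
    2 * log_likelihood(zero_state, one))

  # random 5-area state against dpois (independent route)
  set.seed(4)
  tab <- tibble::tibble(area_id = as.character(1:5),
                        observed = as.integer(rpois(5, 4)),
                        population = 500L,
                        x1 = rnorm(5), x2 = runif(5))
  tab$expected <- tab$population * sum(tab$observed) / sum(tab$population)
  st <- list(alpha = rnorm(1, 0, 0.3),
             beta = c(x1 = 0.2, x2 = -0.4),
             S = rnorm(5, 0, 0.2), H = rnorm(5, 0, 0.2))
  lam <- exp(st$alpha + as.matrix(tab[c("x1", "x2")]) %*% st$beta +
               st$S + st$H)
  oracle <- sum(dpois(tab$observed, lam * tab$expected, log = TRUE))
  expect_equal(log_likelihood(st, tab), oracle, tolerance = 1e-10)

  expect_error(log_likelihood(zero_state, dplyr::select(one, -expected)),
               "expected")
})

test_that("the CAR full conditional is the neighbor mean with variance
           sigma^2/n_i", {
  g <- area_graph(list(c(2L, 3L, 4L), c(1L), c(1L), c(1L))) # star
  S <- c(0, 1, 2, 3)
  cond <- icar_conditional(1, S, g, sigma_S = 0.6)
  expect_equal(cond$mean, 2)
  expect_equal(cond$variance, 0.12)

  # constant field: conditional mean is that constant
  expect_equal(icar_conditional(2, rep(4.2, 4), g, 1)$mean, 4.2)

  gi <- area_graph(list(2L, 1L, integer(0)))
  expect_error(icar_conditional(3, c(0, 0, 0), gi, 1), "no neighbors")
})

# reference pairwise sum used by the Brook check (independent of the
# package internals)
icar_pairwise_ss_ref <- function(S, g) {
  q <- 0
  for (i in seq_len(g$n_areas))
    for (j in g$neighbors[[i]]) if (j > i) q <- q + (S[i] - S[j])^2
  q
}

test_that("conditionals are consistent with the pairwise-difference joint
           density (Brook's lemma on a 3-node path)", {
  g <- area_graph(list(2L, c(1L, 3L), 2L))
  sigma <- 0.8
  joint <- function(S) -icar_pairwise_ss_ref(S, g) / (2 * sigma^2)
  # Brook's lemma: p(S)/p(S0) as a telescoping product of full conditionals
  brook <- function(S, S0) {
    tot <- 0
    cur <- S0
    for (i in seq_along(S)) {
      upper <- cur; upper[i] <- S[i]
      ci <- icar_conditional(i, upper, g, sigma)
      c0 <- icar_conditional(i, cur, g, sigma)
      tot <- tot + dnorm(S[i], ci$mean, sqrt(ci$variance), log = TRUE) -
        dnorm(S0[i], c0$mean, sqrt(c0$variance), log = TRUE)
      cur <- upper
    }
    tot
  }
  S0 <- c(0, 0, 0)
  grid <- expand.grid(s1 = c(-1, 0, 1), s2 = c(-0.5, 0, 0.5),
                      s3 = c(-1, 0, 1))
  for (k in seq_len(nrow(grid))) {
    S <- as.numeric(grid[k, ])
    expect_equal(brook(S, S0), joint(S) - joint(S0), tolerance = 1e-9)
  }
})

test_that("log-prior respects supports and the ICAR quadratic form", {
  g <- area_graph(list(2L, c(1L, 3L), 2L))
  spec <- model_spec("x", spatial = TRUE, heterogeneity = TRUE)
  st <- list(alpha = 0, beta = c(x = 0.1), S = c(-1, 0, 1),
             H = c(0, 0, 0), sigma_S = 1, sigma_H = 0.5)

  # sigma outside (0, sigma_upper] is out of support
  expect_identical(log_prior(modifyList(st, list(sigma_S = 1.2)), spec, g),
                   -Inf)
  expect_identical(log_prior(modifyList(st, list(sigma_H = 0)), spec, g),
                   -Inf)

  # constant field: quadratic term vanishes
  lp_const <- log_prior(modifyList(st, list(S = rep(2, 3))), spec, g)
  lp_zero <- log_prior(modifyList(st, list(S = rep(0, 3))), spec, g)
  expect_equal(lp_const, lp_zero, tolerance = 1e-12)

  # S = (-1, 0, 1) on a path: edge sum (1 + 1) = 2, contribution -1
  expect_equal(log_prior(st, spec, g) - lp_zero, -1, tolerance = 1e-12)

  # cross-check against the matrix form -S'QS / (2 sigma^2)
  Q <- icar_structure(g)
  S <- c(0.3, -0.9, 0.6)
  expect_equal(log_prior(modifyList(st, list(S = S)), spec, g) - lp_zero,
               -as.numeric(S %*% Q %*% S) / 2, tolerance = 1e-12)
})

test_that("the joint log-posterior is invariant to shifting S into the
           intercept", {
  set.seed(8)
  g <- lattice_graph(2, 3)
  tab <- tibble::tibble(area_id = as.character(1:6),
                        observed = as.integer(rpois(6, 3)),
                        population = 400L, x = rnorm(6))
  tab <- compute_expected(tab)
  spec <- model_spec("x")
  st <- list(alpha = -0.2, beta = c(x = 0.3), S = rnorm(6, 0, 0.4),
             H = rnorm(6, 0, 0.2), sigma_S = 0.5, sigma_H = 0.4)
  shift <- 0.37
  st2 <- modifyList(st, list(alpha = st$alpha - shift, S = st$S + shift))
  f <- function(s) log_likelihood(s, tab) + log_prior(s, spec, g)
  expect_equal(f(st), f(st2), tolerance = 1e-9)
})

test_that("with random effects off the posterior matches the Poisson MLE", {
  ds <- simulate_dataset(generator_config(
    true_sigma_S = 0, true_sigma_H = 0, seed = 21))
  tab <- compute_expected(ds$area_table)
  cv <- c("immigration", "policing", "physical_disorder")
  f <- fit_bym(tab, covariates = cv, spatial = FALSE, heterogeneity = FALSE,
               mcmc = quick_mcmc(31, n_iter = 12000, burn_in = 1500))
  mle <- glm(observed ~ immigration + policing + physical_disorder,
             offset = log(expected), family = poisson, data = tab)
  co <- coef(mle)
  s <- f$summary
  for (tm in c("alpha", cv)) {
    mle_val <- if (tm == "alpha") co[["(Intercept)"]] else co[[tm]]
    row <- s[s$term == tm, ]
    expect_lt(abs(row$estimate - mle_val), 2 * row$std.error)
  }
})

test_that("degenerate MCMC configurations are rejected", {
  expect_error(mcmc_config(n_iter = 1000, burn_in = 1000), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(model_spec(prior_beta_variance = 0), "prior_beta_variance")
  expect_error(model_spec(sigma_upper = -1), "sigma_upper")
})
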