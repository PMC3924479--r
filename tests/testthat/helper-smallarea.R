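# shared fixtures: tiny area tables and short sampler settings

toy_table <- function(n = 3, observed = NULL, population = NULL, x = NULL) {
  tibble::tibble(
    area_id = sprintf("a%d", seq_len(n)),
    observed = as.integer(observed %||% rep(2L, n)),
    population = as.integer(population %||% rep(500L, n)),
    x = x %||% seq(-1, 1, length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quick_mcmc <- function(seed, n_iter = 4000, burn_in = 500, thin = 5,
                       n_chains = 2) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
              n_chains = n_chains, seed = seed)
}

# a minimal hand-built bym_samples object (intercept-only, no random
# effects) for exercising summaries without running the sampler
manual_samples <- function(alpha_draws, expected = 1, observed = 0L) {
  n <- length(expected)
  tab <- tibble::tibble(area_id = sprintf("a%d", seq_len(n)),
                        observed = as.integer(observed),
                        population = 100L,
                        expected = expected)
  d <- tibble::tibble(chain = 1L, draw = seq_along(alpha_draws),
                      alpha = alpha_draws, sigma_S = 0.5, sigma_H = 0.5)
  d$loglik <- vapply(alpha_draws, function(a)
    log_likelihood(list(alpha = a, beta = numeric(0)), tab), numeric(1))
  structure(list(draws = d, accept = NULL,
                 spec = model_spec(character(0), spatial = FALSE,
                                   heterogeneity = FALSE),
                 cfg = mcmc_config(n_iter = 2, burn_in = 0, n_chains = 1,
                                   thin = 1, seed = 1),
                 scale = NULL, X = matrix(numeric(0), n, 0),
                 area_id = tab$area_id, data = tab, graph = NULL,
                 beta_names = character(0)),
            class = "bym_samples")
}
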