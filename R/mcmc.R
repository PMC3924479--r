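#' MCMC settings
#'
#' Defaults follow the reference analysis: 100,000 iterations per chain with
#' the first 10,000 discarded as burn-in; draws thinned by 10 for storage;
#' two chains for the Gelman-Rubin diagnostic. Proposal step sizes adapt
#' toward `target_accept` during burn-in only (so the retained draws come
#' from a fixed kernel).
#'
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations (`< n_iter`).
#' @param n_chains Number of chains (>= 2 when R-hat is wanted).
#' @param thin Thinning interval.
#' @param seed Integer seed; chain `c` is seeded with `seed + c - 1`.
#' @param adapt_window Iterations between step-size adaptations.
#' @param target_accept Target acceptance rate for the random-walk blocks.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 100000, burn_in = 10000, n_chains = 2,
                        thin = 10, seed = 1L, adapt_window = 50,
                        target_accept = 0.44) {
  if (burn_in >= n_iter)
    stop("configuration error: burn_in must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if (n_chains < 1) stop("n_chains must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed),
                 adapt_window = as.integer(adapt_window),
                 target_accept = target_accept),
            class = "mcmc_config")
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Fits the Poisson convolution model by single-site adaptive random-walk
#' Metropolis updates for the intercept, each fixed effect, each spatial
#' effect `S_i` and each heterogeneity effect `H_i`, while `sigma_S` and
#' `sigma_H` are drawn exactly from their full conditionals (truncated
#' inverse-gamma on the variance scale under the uniform-on-sd prior), with
#' a Metropolis fallback for degenerate ranks. After every sweep the spatial field is recentred to sum to zero
#' per connected component, the removed constant being absorbed into the
#' intercept (the ICAR prior is improper and the intercept is otherwise
#' unidentified). Covariates are mean-centred internally for mixing and the
#' intercept draws are transformed back, so reported draws are on the
#' original covariate scale.
#'
#' @param data An area table; `expected` is computed via
#'   [compute_expected()] if absent.
#' @param graph An [area_graph()] (required when `spec$spatial`).
#' @param spec A [model_spec()].
#' @param cfg An [mcmc_config()].
#' @param scale Optional named vector of per-covariate multipliers applied
#'   before fitting (e.g. `c(property_value = 1e-3)`).
#' @param islands `"error"` (default) rejects graphs with degree-0 areas;
#'   `"pin"` fixes their spatial effect at zero with a warning.
#' @param likelihood Internal switch; `FALSE` samples the prior only (the
#'   intercept, which has an improper flat prior, is then held fixed).
#' @return An object of class `bym_samples`: list with `draws` (tibble, one
#'   row per retained draw with columns `chain`, `draw`, `alpha`,
#'   `beta_<name>`, `S_<i>`, `H_<i>`, `sigma_S`, `sigma_H`, `loglik`),
#'   `accept` (per-block acceptance rates per chain), `spec`, `cfg`,
#'   `area_id`, `data`, `graph`.
#' @export
run_mcmc <- function(data, graph = NULL, spec = model_spec(), cfg = mcmc_config(),
                     scale = NULL, islands = c("error", "pin"),
                     likelihood = TRUE) {
  islands <- match.arg(islands)
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "mcmc_config"))
  data <- validate_area_table(data)
  if (!"expected" %in% names(data)) data <- compute_expected(data)
  n <- nrow(data)
  if (spec$spatial) {
    stopifnot(inherits(graph, "area_graph"))
    if (graph$n_areas != n)
      stop("graph has ", graph$n_areas, " areas but data has ", n)
    if (any(graph$degrees == 0)) {
      if (islands == "error")
        stop("graph has island areas (no neighbors); the CAR conditional ",
             "is undefined for them. Use islands = \"pin\" to fix their ",
             "spatial effect at zero.")
      warning("island areas present: their spatial effect is pinned at zero")
    }
  } else {
    graph <- NULL
  }
  X <- model_matrix(data, spec, scale)
  p <- ncol(X)
  xbar <- if (p) colMeans(X) else numeric(0)
  Xc <- if (p) sweep(X, 2, xbar) else X

  if (likelihood) {
    init_alpha <- log(sum(data$observed) / sum(data$expected))
    if (!is.finite(init_alpha)) init_alpha <- 0
  } else init_alpha <- 0

  nbr <- if (spec$spatial) graph$neighbors else rep(list(integer(0)), n)
  comp <- if (spec$spatial) graph$component else rep(1L, n)
  n_comp <- if (spec$spatial) graph$n_components else 1L
  # rank of the ICAR quadratic form excludes islands and one dof/component
  if (spec$spatial) {
    non_island_comps <- unique(comp[graph$degrees > 0])
    n_comp_eff <- max(1L, length(non_island_comps))
    rank_comp <- sum(graph$degrees > 0) - length(non_island_comps)
    n_comp_pass <- graph$n_areas - rank_comp # so n - n_comp_pass = rank
  } else {
    n_comp_pass <- 1L
  }

  chains <- vector("list", cfg$n_chains)
  accepts <- vector("list", cfg$n_chains)
  beta_names <- if (p) paste0("beta_", colnames(X)) else character(0)
  col_names <- c("alpha", beta_names, paste0("S_", seq_len(n)),
                 paste0("H_", seq_len(n)), "sigma_S", "sigma_H", "loglik")
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(cfg$seed + ch - 1L)
    a0 <- init_alpha
    b0 <- numeric(p)
    S0 <- numeric(n)
    H0 <- numeric(n)
    sS0 <- 0.5 * spec$sigma_upper
    sH0 <- 0.5 * spec$sigma_upper
    if (ch > 1) { # overdispersed start for honest R-hat
      if (likelihood) a0 <- a0 + rnorm(1, 0, 0.5)
      if (p) b0 <- b0 + rnorm(p, 0, 0.05)
      sS0 <- runif(1, 0.1, 0.9) * spec$sigma_upper
      sH0 <- runif(1, 0.1, 0.9) * spec$sigma_upper
      if (spec$spatial) S0 <- rnorm(n, 0, 0.1)
      if (spec$heterogeneity) H0 <- rnorm(n, 0, 0.1)
    }
    if (spec$spatial) S0[graph$degrees == 0] <- 0 # pinned islands
    res <- run_mcmc_cpp(as.integer(data$observed), data$expected, Xc,
                        nbr, as.integer(comp), as.integer(n_comp_pass),
                        spec$spatial, spec$heterogeneity,
                        spec$prior_beta_variance, spec$sigma_upper,
                        cfg$n_iter, cfg$burn_in, cfg$thin,
                        cfg$adapt_window, cfg$target_accept,
                        a0, b0, S0, H0, sS0, sH0, isTRUE(likelihood))
    d <- res$draws
    colnames(d) <- col_names
    d <- tibble::as_tibble(d)
    # undo internal covariate centering on the intercept
    if (p && likelihood) {
      bmat <- as.matrix(d[beta_names])
      d$alpha <- d$alpha - as.numeric(bmat %*% xbar)
    }
    d$chain <- ch
    d$draw <- seq_len(nrow(d))
    chains[[ch]] <- d
    block_names <- c("alpha", beta_names, "S", "H", "sigma_S", "sigma_H")
    accepts[[ch]] <- tibble::tibble(chain = ch, block = block_names,
                                    accept_rate = as.numeric(res$accept_rate),
                                    step_size = as.numeric(res$step_size))
  }
  draws <- dplyr::bind_rows(chains)
  draws <- dplyr::select(draws, "chain", "draw", dplyr::everything())
  structure(list(draws = draws, accept = dplyr::bind_rows(accepts),
                 spec = spec, cfg = cfg, scale = scale, X = X,
                 area_id = data$area_id, data = data, graph = graph,
                 beta_names = beta_names),
            class = "bym_samples")
}

#' @export
print.bym_samples <- function(x, ...) {
  cat("<bym_samples> ", nrow(x$draws), " retained draws (",
      x$cfg$n_chains, " chain(s) x ", x$cfg$n_iter, " iterations, burn-in ",
      x$cfg$burn_in, ", thin ", x$cfg$thin, ")\n", sep = "")
  invisible(x)
}

# posterior mean parameter state from a bym_samples object
posterior_mean_state <- function(samples) {
  d <- samples$draws
  n <- length(samples$area_id)
  list(alpha = mean(d$alpha),
       beta = stats::setNames(vapply(samples$beta_names,
                                     function(b) mean(d[[b]]), numeric(1)),
                              sub("^beta_", "", samples$beta_names)),
       S = if (samples$spec$spatial)
         vapply(seq_len(n), function(i) mean(d[[paste0("S_", i)]]),
                numeric(1)) else numeric(n),
       H = if (samples$spec$heterogeneity)
         vapply(seq_len(n), function(i) mean(d[[paste0("H_", i)]]),
                numeric(1)) else numeric(n),
       sigma_S = mean(d$sigma_S), sigma_H = mean(d$sigma_H))
}
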