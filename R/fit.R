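#' Fit a small-area Poisson model
#'
#' High-level wrapper: validates the area table, derives expected counts by
#' internal standardization if needed, runs the Metropolis-within-Gibbs
#' sampler, and assembles posterior summaries, the DIC report and the
#' convergence report.
#'
#' @param data An area table (see [read_area_table()]).
#' @param graph An [area_graph()]; required when `spatial = TRUE`.
#' @param covariates Covariate names to include; default all covariate
#'   columns.
#' @param spatial,heterogeneity Random-effect switches (both `TRUE` gives
#'   the convolution/BYM model; both `FALSE` a plain Poisson regression).
#' @param prior_beta_variance,sigma_upper Prior settings, see
#'   [model_spec()].
#' @param scale Optional named vector of per-covariate multipliers applied
#'   before fitting (e.g. `c(property_value = 1e-3)` to express cadastral
#'   value in thousands).
#' @param mcmc An [mcmc_config()].
#' @param islands Island policy, see [run_mcmc()].
#' @return An object of class `bym_fit`: list with `samples`
#'   (`bym_samples`), `summary` (tibble: term, estimate, sd, conf.low,
#'   conf.high, prob_positive), `dic` (`dic_report`), `convergence`
#'   (tibble), `spec`, `data`.
#' @export
fit_bym <- function(data, graph = NULL, covariates = NULL,
                    spatial = TRUE, heterogeneity = TRUE,
                    prior_beta_variance = 1e5, sigma_upper = 1,
                    scale = NULL, mcmc = mcmc_config(), islands = "error") {
  data <- validate_area_table(data)
  if (is.null(covariates)) covariates <- area_covariates(data)
  spec <- model_spec(covariates, spatial = spatial,
                     heterogeneity = heterogeneity,
                     prior_beta_variance = prior_beta_variance,
                     sigma_upper = sigma_upper)
  samples <- run_mcmc(data, graph, spec, mcmc, scale = scale,
                      islands = islands)
  summ <- summarize_draws(samples)
  conv <- if (mcmc$n_chains >= 2) convergence_report(samples) else NULL
  structure(list(samples = samples, summary = summ,
                 dic = compute_dic(samples),
                 convergence = conv, spec = spec,
                 data = samples$data),
            class = "bym_fit")
}

# posterior summaries of the scalar parameters
summarize_draws <- function(samples) {
  d <- samples$draws
  params <- c("alpha", samples$beta_names,
              if (samples$spec$spatial) "sigma_S",
              if (samples$spec$heterogeneity) "sigma_H")
  purrr::map_dfr(params, function(pn) {
    x <- d[[pn]]
    tibble::tibble(
      term = sub("^beta_", "", pn),
      estimate = mean(x), std.error = sd(x),
      conf.low = unname(quantile(x, 0.025)),
      conf.high = unname(quantile(x, 0.975)),
      prob_positive = mean(x > 0))
  })
}

#' @export
print.bym_fit <- function(x, ...) {
  kind <- if (x$spec$spatial && x$spec$heterogeneity) {
    "spatial convolution (BYM)"
  } else if (!x$spec$spatial && !x$spec$heterogeneity) {
    "non-spatial Poisson"
  } else "partial random-effects"
  cat("<bym_fit> ", kind, " model, ", length(x$samples$area_id),
      " areas\n", sep = "")
  print(x$summary, n = Inf)
  print(x$dic)
  if (!is.null(x$convergence))
    cat("max R-hat:", format(max(x$convergence$rhat), digits = 4), "\n")
  invisible(x)
}

#' Tidy a fitted small-area model
#'
#' @param x A `bym_fit`.
#' @param ... Unused.
#' @return Tibble with one row per scalar parameter: `term`, `estimate`
#'   (posterior mean), `std.error` (posterior SD), `conf.low`/`conf.high`
#'   (95% credible interval), `prob_positive`, and when available `rhat`
#'   and `ess`.
#' @export
tidy.bym_fit <- function(x, ...) {
  out <- x$summary
  if (!is.null(x$convergence)) {
    conv <- dplyr::rename(x$convergence, term = "parameter")
    conv$term <- sub("^beta_", "", conv$term)
    out <- dplyr::left_join(out, conv, by = "term")
  }
  out
}

#' One-row model summary
#'
#' @param x A `bym_fit`.
#' @param ... Unused.
#' @return Tibble with `DIC`, `pD`, `Dbar`, `Dhat`, `max_rhat`, `converged`,
#'   `n_areas`, `n_draws`.
#' @export
glance.bym_fit <- function(x, ...) {
  tibble::tibble(
    DIC = x$dic$DIC, pD = x$dic$pD, Dbar = x$dic$Dbar, Dhat = x$dic$Dhat,
    max_rhat = if (is.null(x$convergence)) NA_real_ else
      max(x$convergence$rhat),
    converged = if (is.null(x$convergence)) NA else
      isTRUE(attr(x$convergence, "converged")),
    n_areas = length(x$samples$area_id), n_draws = nrow(x$samples$draws))
}

#' Posterior densities of the fixed effects
#'
#' @param object A `bym_fit`.
#' @param ... Unused.
#' @return A ggplot: one density panel per fixed effect with a reference
#'   line at zero.
#' @export
autoplot.bym_fit <- function(object, ...) {
  d <- object$samples$draws
  keep <- c("alpha", object$samples$beta_names)
  long <- tidyr::pivot_longer(d[keep], dplyr::all_of(keep),
                              names_to = "term", values_to = "value")
  long$term <- sub("^beta_", "", long$term)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "posterior draw", y = "density")
}
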