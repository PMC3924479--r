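#' Model specification for the Poisson convolution model
#'
#' Defines which covariates enter the linear predictor and which random
#' effects are switched on. The non-spatial Poisson regression ("Model 1"
#' in the workflow) has both random-effect flags off; the convolution (BYM)
#' models have both on. Priors follow the vague defaults: `beta_k ~
#' N(0, prior_beta_variance)` (variance scale), an improper flat prior on
#' the intercept, and `sigma_S, sigma_H ~ U(0, sigma_upper)` on the
#' standard-deviation scale.
#'
#' @param covariates Character vector of covariate names (may be empty).
#' @param spatial Include the ICAR spatial effect `S`?
#' @param heterogeneity Include the exchangeable heterogeneity `H`?
#' @param prior_beta_variance Prior variance of the fixed effects
#'   (default 1e5).
#' @param sigma_upper Upper bound of the uniform priors on the random-effect
#'   standard deviations (default 1).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(covariates = character(), spatial = TRUE,
                       heterogeneity = TRUE, prior_beta_variance = 1e5,
                       sigma_upper = 1) {
  if (prior_beta_variance <= 0) stop("prior_beta_variance must be > 0")
  if (sigma_upper <= 0) stop("sigma_upper must be > 0")
  structure(list(covariates = as.character(covariates),
                 spatial = isTRUE(spatial),
                 heterogeneity = isTRUE(heterogeneity),
                 prior_beta_variance = prior_beta_variance,
                 sigma_upper = sigma_upper),
            class = "model_spec")
}

# design matrix for a spec (applies optional per-covariate scaling)
model_matrix <- function(data, spec, scale = NULL) {
  miss <- setdiff(spec$covariates, names(data))
  if (length(miss))
    stop("covariate(s) not in area table: ", paste(miss, collapse = ", "))
  X <- as.matrix(data[spec$covariates])
  if (!is.null(scale) && length(scale)) {
    for (nm in intersect(names(scale), colnames(X)))
      X[, nm] <- X[, nm] * scale[[nm]]
  }
  X
}

#' Poisson log-likelihood of a parameter state
#'
#' `sum_i [ O_i log(lambda_i E_i) - lambda_i E_i - log(O_i!) ]` with
#' `lambda_i = exp(alpha + x_i' beta + S_i + H_i)`. The `log(O_i!)` constant
#' is included so that `-2 * log_likelihood` is the full Poisson deviance
#' used by the DIC report.
#'
#' @param state List with `alpha` (scalar), `beta` (vector, may be empty),
#'   `S` and `H` (vectors of length n, optional — treated as zero when
#'   absent).
#' @param data An area table with an `expected` column.
#' @param covariates Covariate names matching `state$beta`; defaults to
#'   `names(state$beta)`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(state, data, covariates = names(state$beta)) {
  if (!"expected" %in% names(data))
    stop("expected counts are missing; run compute_expected() first")
  n <- nrow(data)
  eta <- rep(state$alpha, n)
  if (length(state$beta)) {
    X <- as.matrix(data[covariates])
    eta <- eta + as.numeric(X %*% as.numeric(state$beta))
  }
  if (!is.null(state$S)) eta <- eta + state$S
  if (!is.null(state$H)) eta <- eta + state$H
  mu <- exp(eta) * data$expected
  sum(data$observed * log(mu) - mu - lgamma(data$observed + 1))
}

#' Full conditional of one area's ICAR spatial effect
#'
#' Under the intrinsic CAR prior, `S_i | S_{-i}` is normal with mean the
#' average of the neighbors' values and variance `sigma_S^2 / n_i`.
#'
#' @param i Area index (1-based).
#' @param S Current spatial-effect vector.
#' @param graph An [area_graph()].
#' @param sigma_S Standard-deviation parameter.
#' @return List with `mean` and `variance`.
#' @export
icar_conditional <- function(i, S, graph, sigma_S) {
  stopifnot(inherits(graph, "area_graph"))
  ni <- graph$degrees[i]
  if (ni == 0)
    stop("area ", i, " has no neighbors: the CAR conditional is undefined")
  list(mean = mean(S[graph$neighbors[[i]]]), variance = sigma_S^2 / ni)
}

#' Joint log-prior of a parameter state
#'
#' Sums: 0 for the flat improper prior on `alpha`; normal log-densities for
#' `beta`; the improper ICAR log-density
#' `-(n - c) log(sigma_S) - sum_{i~j, i<j} (S_i - S_j)^2 / (2 sigma_S^2)`
#' (`c` = number of connected components); iid normal log-densities for `H`
#' given `sigma_H`; and 0 inside / `-Inf` outside the uniform supports
#' `(0, sigma_upper]` of the standard deviations.
#'
#' @param state List with `alpha`, `beta`, `S`, `H`, `sigma_S`, `sigma_H`
#'   (random-effect pieces may be omitted when the spec excludes them).
#' @param spec A [model_spec()].
#' @param graph An [area_graph()] (required when `spec$spatial`).
#' @return Scalar log-prior (possibly `-Inf`).
#' @export
log_prior <- function(state, spec, graph = NULL) {
  lp <- 0
  if (length(state$beta))
    lp <- lp + sum(dnorm(as.numeric(state$beta), 0,
                         sqrt(spec$prior_beta_variance), log = TRUE))
  if (spec$spatial) {
    stopifnot(inherits(graph, "area_graph"))
    s <- state$sigma_S
    if (is.null(s) || s <= 0 || s > spec$sigma_upper) return(-Inf)
    q <- icar_pairwise_ss(state$S, graph)
    rank <- graph$n_areas - graph$n_components
    lp <- lp - rank * log(s) - q / (2 * s^2)
  }
  if (spec$heterogeneity) {
    s <- state$sigma_H
    if (is.null(s) || s <= 0 || s > spec$sigma_upper) return(-Inf)
    lp <- lp + sum(dnorm(state$H, 0, s, log = TRUE))
  }
  lp
}

# sum over unordered neighbor pairs of squared differences; equals S'QS
icar_pairwise_ss <- function(S, graph) {
  q <- 0
  for (i in seq_len(graph$n_areas)) {
    for (j in graph$neighbors[[i]]) if (j > i) q <- q + (S[i] - S[j])^2
  }
  q
}
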