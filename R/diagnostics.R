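#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF on m chains of equal length n: with `W` the mean
#' within-chain variance and `B/n` the variance of the chain means,
#' `Vhat = ((n - 1)/n) W + B/n` and `Rhat = sqrt(Vhat / W)`. Values near 1
#' indicate that the chains have mixed. Computed on the retained
#' (post-burn-in, thinned) draws; `split = TRUE` additionally halves each
#' chain (split-R-hat) to detect within-chain drift.
#'
#' @param chains A list of equal-length numeric vectors (one per chain) or a
#'   matrix with one column per chain.
#' @param split Use split chains? Default `FALSE` (the classic diagnostic).
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2)
    stop("at least two chains are required for R-hat")
  len <- lengths(chains)
  if (length(unique(len)) != 1) stop("chains must have equal length")
  if (split) {
    half <- floor(len[1] / 2)
    chains <- unlist(lapply(chains, function(x)
      list(x[seq_len(half)], x[seq.int(half + 1, 2 * half)])),
      recursive = FALSE)
  }
  n <- length(chains[[1]])
  if (n < 2) stop("chains must have length >= 2")
  W <- mean(vapply(chains, var, numeric(1)))
  if (W == 0) stop("degenerate chains: zero within-chain variance")
  Bn <- var(vapply(chains, mean, numeric(1))) # = B / n
  Vhat <- (n - 1) / n * W + Bn
  sqrt(Vhat / W)
}

# effective sample size via Geyer's initial positive sequence, summed over
# chains
ess_chains <- function(chains) {
  per_chain <- function(x) {
    n <- length(x)
    if (n < 4 || var(x) == 0) return(ifelse(var(x) == 0, 0, n))
    rho <- as.numeric(acf(x, lag.max = min(n - 2, 500),
                          plot = FALSE)$acf)[-1]
    tau <- 1
    k <- 1
    while (k + 1 <= length(rho)) {
      g <- rho[k] + rho[k + 1]
      if (g <= 0) break
      tau <- tau + 2 * g
      k <- k + 2
    }
    n / tau
  }
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  sum(vapply(chains, per_chain, numeric(1)))
}

#' Convergence report for a set of MCMC samples
#'
#' Computes R-hat and effective sample size for the intercept, every fixed
#' effect and the random-effect standard deviations, flagging convergence
#' when all R-hat values are at or below `threshold` (default 1.05, a
#' conservative reading of "near 1.0").
#'
#' @param samples A `bym_samples` object from [run_mcmc()].
#' @param threshold R-hat threshold for the `converged` flag.
#' @param split Use split-R-hat? Default `FALSE`.
#' @return Tibble with columns `parameter`, `rhat`, `ess`, plus attribute
#'   `"converged"`.
#' @export
convergence_report <- function(samples, threshold = 1.05, split = FALSE) {
  stopifnot(inherits(samples, "bym_samples"))
  params <- c("alpha", samples$beta_names,
              if (samples$spec$spatial) "sigma_S",
              if (samples$spec$heterogeneity) "sigma_H")
  if (samples$cfg$n_chains < 2)
    stop("R-hat requires at least two chains")
  rows <- purrr::map(params, function(pn) {
    per <- split(samples$draws[[pn]], samples$draws$chain)
    tibble::tibble(parameter = pn,
                   rhat = gelman_rubin(per, split = split),
                   ess = ess_chains(per))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "converged") <- all(out$rhat <= threshold)
  out
}

#' Deviance Information Criterion
#'
#' `Dbar` is the posterior mean of the deviance `-2 log L`; `Dhat` is the
#' deviance at the posterior means of the natural (log-scale) parameters
#' `alpha, beta, S, H` (the plug-in used by WinBUGS, on which DIC is
#' parameterization-dependent); `pD = Dbar - Dhat` is the effective number
#' of parameters and `DIC = Dbar + pD = Dhat + 2 pD`. The deviance includes
#' the `log(O_i!)` normalizing term.
#'
#' @param samples A `bym_samples` object with stored per-draw
#'   log-likelihoods.
#' @param data Optional area table (defaults to the one stored with the
#'   samples).
#' @return A list of class `dic_report` with `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
compute_dic <- function(samples, data = NULL) {
  stopifnot(inherits(samples, "bym_samples"))
  if (is.null(data)) data <- samples$data
  if (nrow(samples$draws) == 0) stop("no retained draws")
  Dbar <- mean(-2 * samples$draws$loglik)
  st <- posterior_mean_state(samples)
  n <- length(samples$area_id)
  eta <- rep(st$alpha, n)
  if (length(st$beta)) eta <- eta + as.numeric(samples$X %*% st$beta)
  if (samples$spec$spatial) eta <- eta + st$S
  if (samples$spec$heterogeneity) eta <- eta + st$H
  mu <- exp(eta) * data$expected
  Dhat <- -2 * sum(data$observed * log(mu) - mu - lgamma(data$observed + 1))
  pD <- Dbar - Dhat
  structure(list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD),
            class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("DIC %.2f (Dbar %.2f, Dhat %.2f, pD %.2f)\n",
              x$DIC, x$Dbar, x$Dhat, x$pD))
  invisible(x)
}
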