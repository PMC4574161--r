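#' Deviance information criterion
#'
#' `Dbar` is the posterior mean deviance (mean over draws of minus twice
#' the data log-likelihood); `Dhat` is the deviance at the posterior mean
#' of all parameters (the classic plug-in convention); the effective
#' number of parameters is `pD = Dbar - Dhat` and `DIC = Dbar + pD`.
#'
#' @param fit a `seadiv_fit` (per-draw log-likelihoods are stored by
#'   [fit_model()]).
#' @return A list with `Dbar`, `Dhat`, `pD` and `DIC`.
#' @export
dic <- function(fit) {
  if (is.null(fit$loglik) || !length(fit$loglik))
    stop("fit carries no per-draw log-likelihood")
  dic_components(fit$loglik,
                 sum(pointwise_loglik(fit$md, posterior_mean_params(fit))))
}

#' DIC from raw log-likelihood values
#'
#' The arithmetic behind [dic()], usable with any model whose per-draw
#' total log-likelihood and plug-in log-likelihood are available.
#'
#' @param loglik_draws per-draw total data log-likelihood.
#' @param loglik_at_mean log-likelihood at the posterior mean of the
#'   parameters.
#' @return A list with `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
dic_components <- function(loglik_draws, loglik_at_mean) {
  Dbar <- mean(-2 * loglik_draws)
  Dhat <- -2 * loglik_at_mean
  pD <- Dbar - Dhat
  list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD)
}

#' DIC weights
#'
#' Relative model support computed exactly as AIC weights:
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = DIC_i - min(DIC)`, expressed in percent. Subtracting the
#' minimum before exponentiating keeps the computation stable, and makes
#' the weights invariant to adding a constant to every DIC.
#'
#' @param dics numeric vector of DIC values (all finite).
#' @return Numeric vector of weights in percent, summing to 100.
#' @export
dic_weights <- function(dics) {
  if (!length(dics) || any(!is.finite(dics)))
    stop("all DIC values must be finite")
  d <- dics - min(dics)
  w <- exp(-d / 2)
  100 * w / sum(w)
}

#' Posterior predictive p-value
#'
#' For each retained draw, a replicate dataset is simulated from the
#' fitted likelihood at that draw's parameters and a discrepancy
#' statistic is compared between replicate and observed data. The PPP is
#' the fraction of draws whose replicate discrepancy is at least the
#' observed one; values outside (0.05, 0.95) flag a model contradicted
#' by the data (`extreme` in the result).
#'
#' @param fit a `seadiv_fit` with at least 200 retained draws.
#' @param discrepancy `"sd"` (default: standard deviation of the
#'   response), `"mean"`, or `"chisq"` (sum of squared Pearson residuals
#'   at each draw's fitted mean and variance).
#' @param draws optional number of draws to use (default: all; evenly
#'   subsampled when fewer are requested).
#' @return A list with `ppp`, `discrepancy`, `extreme`, and the vectors
#'   of observed/replicate statistics.
#' @export
posterior_predictive_p <- function(fit, discrepancy = c("sd", "mean", "chisq"),
                                   draws = NULL) {
  discrepancy <- match.arg(discrepancy)
  total <- nrow(fit$draws)
  if (total < 200) stop("need at least 200 retained draws for a PPP")
  use <- if (is.null(draws)) seq_len(total)
         else unique(round(seq(1, total, length.out = draws)))
  y <- fit$md$y
  d_rep <- d_obs <- numeric(length(use))
  for (k in seq_along(use)) {
    pr <- draw_params(fit, use[k])
    mm <- fitted_moments(fit$md, pr)
    yrep <- simulate_response(fit$md, mm)
    if (discrepancy == "sd") {
      d_rep[k] <- stats::sd(yrep); d_obs[k] <- stats::sd(y)
    } else if (discrepancy == "mean") {
      d_rep[k] <- mean(yrep); d_obs[k] <- mean(y)
    } else {
      d_rep[k] <- sum((yrep - mm$mean)^2 / mm$var)
      d_obs[k] <- sum((y - mm$mean)^2 / mm$var)
    }
  }
  ppp <- mean(d_rep >= d_obs)
  list(ppp = ppp, discrepancy = discrepancy,
       extreme = ppp < 0.05 || ppp > 0.95,
       observed = d_obs, replicated = d_rep)
}

# per-observation mean/variance (and beta shape parameters) at a state
fitted_moments <- function(md, params) {
  eta <- drop(md$X %*% params$beta) + params$S[md$species_idx]
  if (md$spec$region) eta <- eta + params$R[md$region_idx]
  ld <- params$gamma[1] + params$gamma[2] * md$logn
  if (md$spec$response == "H") {
    mu <- stats::plogis(eta)
    delta <- exp(ld)
    list(family = "beta", mean = mu, var = mu * (1 - mu) / (1 + delta),
         a = mu * delta, b = (1 - mu) * delta)
  } else {
    list(family = "gaussian", mean = eta, var = exp(-ld))
  }
}

simulate_response <- function(md, mm) {
  n <- length(mm$mean)
  if (mm$family == "beta") stats::rbeta(n, mm$a, mm$b)
  else stats::rnorm(n, mm$mean, sqrt(mm$var))
}

#' Gelman-Rubin potential scale reduction
#'
#' Classic (non-split) R-hat computed per parameter from between- and
#' within-chain variances over the retained draws. Values near 1
#' indicate the chains agree; the usual working threshold is 1.1.
#'
#' @param chains a list of draw matrices (one per chain, identical
#'   columns), or a `seadiv_fit`.
#' @return Named numeric vector of R-hat values (`NA` for parameters with
#'   zero within-chain variance, e.g. constants).
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "seadiv_fit")) chains <- chains$chains
  m <- length(chains)
  if (m < 2) stop("need at least two chains")
  n <- nrow(chains[[1]])
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    x <- vapply(chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W == 0) return(if (B == 0) 1 else NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(chains[[1]]))
}
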