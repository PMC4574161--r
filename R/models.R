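#' Specify one model from the two ladders
#'
#' Models come in two families distinguished by their response: `"Z"`
#' (Gaussian on within-study standardised diversity) and `"H"` (beta
#' regression on raw diversity). Species effects (S) and the sample-size
#' dispersion term (n) are always present; marker (M) is present in every
#' H model and absent from every Z model (standardisation already removes
#' study-by-marker level differences); latitude (L), latitude squared
#' (L2) and region (R) are optional, with L2 requiring L.
#'
#' @param response `"H"` or `"Z"`.
#' @param latitude include a linear latitude covariate?
#' @param latitude_sq include squared latitude (requires `latitude`)?
#' @param region include CAR-structured region effects?
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response = c("H", "Z"), latitude = FALSE,
                       latitude_sq = FALSE, region = FALSE) {
  response <- match.arg(response)
  if (latitude_sq && !latitude)
    stop("latitude_sq requires latitude")
  structure(list(response = response, marker = response == "H",
                 latitude = latitude, latitude_sq = latitude_sq,
                 region = region),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  paste(c("S", if (x$marker) "M", "n", if (x$latitude) "L",
          if (x$latitude_sq) "L2", if (x$region) "R"),
        collapse = " + ")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model spec [", x$response, "]: ", format(x), "\n", sep = "")
  invisible(x)
}

#' The six-model ladder for one response family
#'
#' Base terms plus, in order: nothing, L, L + L2, R, L + R, L + L2 + R.
#'
#' @param response `"H"` or `"Z"`.
#' @return Named list of six `model_spec` objects (names are the term
#'   labels).
#' @export
ladder_specs <- function(response = c("H", "Z")) {
  response <- match.arg(response)
  specs <- list(
    model_spec(response),
    model_spec(response, latitude = TRUE),
    model_spec(response, latitude = TRUE, latitude_sq = TRUE),
    model_spec(response, region = TRUE),
    model_spec(response, latitude = TRUE, region = TRUE),
    model_spec(response, latitude = TRUE, latitude_sq = TRUE, region = TRUE))
  stats::setNames(specs, vapply(specs, format, character(1)))
}

#' Prior configuration
#'
#' Vague-but-proper defaults: normal(0, 10^2) on fixed and dispersion
#' coefficients, half-normal(1) on the species-effect scale, and a
#' gamma(0.5, 0.0005) hyperprior on the CAR spatial precision (the
#' conventional vague choice for intrinsic CAR precisions).
#'
#' @param beta_sd,gamma_sd normal prior standard deviations.
#' @param sigma_s_scale half-normal scale for the species-effect sd.
#' @param tau_r_shape,tau_r_rate gamma hyperprior on the CAR precision.
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(beta_sd = 10, gamma_sd = 10, sigma_s_scale = 1,
                         tau_r_shape = 0.5, tau_r_rate = 0.0005) {
  stopifnot(beta_sd > 0, gamma_sd > 0, sigma_s_scale > 0,
            tau_r_shape > 0, tau_r_rate > 0)
  structure(list(beta_sd = beta_sd, gamma_sd = gamma_sd,
                 sigma_s_scale = sigma_s_scale,
                 tau_r_shape = tau_r_shape, tau_r_rate = tau_r_rate),
            class = "prior_config")
}

#' MCMC settings
#'
#' @param chains number of chains (>= 2, so convergence diagnostics are
#'   always available).
#' @param iterations total iterations per chain, including burn-in.
#' @param burnin iterations discarded from the front of each chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 2, iterations = 3000, burnin = 1000,
                          thin = 2) {
  stopifnot(chains >= 2, iterations > burnin, burnin >= 0, thin >= 1,
            (iterations - burnin) >= thin)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin)),
            class = "mcmc_settings")
}

#' Named MCMC presets
#'
#' `"desk"` is a short adaptive run for interactive work and automated
#' checks; `"survey"` mirrors screening runs of 100k iterations, thin 100,
#' burn-in 5000 over three chains; `"final"` mirrors a long confirmation
#' run of 500k iterations with burn-in 50k.
#'
#' @param name one of `"desk"`, `"survey"`, `"final"`.
#' @return An `mcmc_settings` object.
#' @export
mcmc_preset <- function(name = c("desk", "survey", "final")) {
  switch(match.arg(name),
         desk = mcmc_settings(2, 3000, 1000, 2),
         survey = mcmc_settings(3, 100000, 5000, 100),
         final = mcmc_settings(3, 500000, 50000, 100))
}

#' Assemble the data objects a model fit needs
#'
#' Builds the response, design matrix, grouping indices and prior
#' structure matrices for a dataset/spec pair. For the H family the
#' response is the squeezed diversity (see [squeeze_unit_interval()]);
#' for the Z family it is the within-dataID z-score, and populations in
#' degenerate dataIDs are dropped. The design matrix carries an
#' intercept, marker dummies (reference level allozyme), and centred,
#' scaled latitude (squared after scaling); the scaling record is kept so
#' coefficients are interpretable on the standardised scale.
#'
#' @param ds a `diversity_dataset`.
#' @param spec a `model_spec`.
#' @param graph a `region_graph`; required when `spec$region`.
#' @param rho Grafen exponent for the taxonomy correlation.
#' @return A list of class `model_data` with elements `y`, `X`, `logn`,
#'   `species_idx`, `region_idx`, `species`, `region_ids`, `corr`
#'   (species correlation), `prec` (its inverse), `car` (a
#'   `car_structure` or `NULL`), `records`, `spec`, `lat_center`,
#'   `lat_scale`.
#' @export
prepare_model_data <- function(ds, spec, graph = NULL, rho = 1) {
  stopifnot(inherits(ds, "diversity_dataset"), inherits(spec, "model_spec"))
  r <- ds$records
  if (spec$response == "Z") {
    if (is.null(r$z)) {
      ds <- add_zscores(ds)
      r <- ds$records
    }
    drop <- is.na(r$z)
    if (any(drop)) {
      message("dropping ", sum(drop),
              " population(s) in degenerate dataIDs from the Z analysis")
      r <- r[!drop, , drop = FALSE]
      z_kept <- r$z
      ds <- diversity_dataset(r[record_cols])
      r <- ds$records
      r$z <- z_kept
    }
    y <- r$z
  } else {
    # only exact-boundary values are squeezed: interior observations stay
    # untouched so the likelihood sees the reported diversity itself
    y <- r$diversity
    at_edge <- y <= 0 | y >= 1
    if (any(at_edge))
      y[at_edge] <- squeeze_unit_interval(y[at_edge], r$n[at_edge])
  }

  X <- cbind(`(Intercept)` = rep(1, nrow(r)))
  if (spec$marker) {
    lev <- intersect(marker_levels(), unique(r$marker))
    if (length(lev) > 1L) {
      f <- factor(r$marker, levels = lev)
      M <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(M) <- paste0("marker:", lev[-1])
      X <- cbind(X, M)
    }
  }
  lat_center <- mean(r$latitude)
  lat_scale <- stats::sd(r$latitude)
  if (spec$latitude) {
    L <- (r$latitude - lat_center) / lat_scale
    X <- cbind(X, latitude = L)
    if (spec$latitude_sq) X <- cbind(X, latitude_sq = L^2)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  car <- NULL
  region_idx <- integer(0)
  region_ids <- character(0)
  if (spec$region) {
    if (is.null(graph)) stop("spec includes region effects: supply 'graph'")
    missing <- setdiff(ds$regions, graph$ids)
    if (length(missing))
      stop("region(s) absent from the adjacency graph: ",
           paste(missing, collapse = ", "))
    car <- build_car(graph, allow_isolated = TRUE)
    region_ids <- graph$ids
    region_idx <- match(r$region, region_ids)
  }

  corr <- taxonomy_correlation(ds, rho = rho)
  prec <- chol2inv(chol(corr + diag(1e-8, nrow(corr))))

  structure(list(y = y, X = X, logn = log(r$n),
                 species_idx = match(r$species, ds$species),
                 region_idx = region_idx,
                 species = ds$species, region_ids = region_ids,
                 corr = corr, prec = prec, car = car,
                 records = r, spec = spec,
                 lat_center = lat_center, lat_scale = lat_scale),
            class = "model_data")
}

#' Log joint density of one model state
#'
#' Sum of the data log-likelihood (beta or Gaussian, depending on the
#' spec's response) and the log prior terms: normal on fixed and
#' dispersion coefficients, multivariate normal with the taxonomy
#' correlation on species effects, intrinsic CAR (improper, evaluated on
#' the sum-to-zero subspace with its `rank/2 * log(tau_R)` normalising
#' power) on region effects, half-normal on `sigma_S` and gamma on
#' `tau_R`. Errors if any component is non-finite.
#'
#' @param md a `model_data` from [prepare_model_data()].
#' @param params list with `beta` (named as `colnames(md$X)`), `gamma`
#'   (length 2), `S` (length = number of species), `sigma_s`, and, for
#'   region models, `R` and `tau_r`.
#' @param priors a `prior_config`.
#' @return Scalar log joint density.
#' @export
log_joint <- function(md, params, priors = prior_config()) {
  ll <- sum(pointwise_loglik(md, params))
  if (!is.finite(ll)) stop("non-finite log-likelihood at supplied parameters")
  lp <- sum(stats::dnorm(params$beta, 0, priors$beta_sd, log = TRUE)) +
    sum(stats::dnorm(params$gamma, 0, priors$gamma_sd, log = TRUE))
  S <- params$S
  sig <- params$sigma_s
  Tn <- length(S)
  q <- drop(t(S) %*% md$prec %*% S)
  ld <- as.numeric(determinant(md$corr + diag(1e-8, Tn),
                               logarithm = TRUE)$modulus)
  lp <- lp - Tn * log(sig) - 0.5 * q / sig^2 - 0.5 * ld -
    0.5 * Tn * log(2 * pi)
  lp <- lp + stats::dnorm(sig, 0, priors$sigma_s_scale, log = TRUE) + log(2)
  if (md$spec$region) {
    R <- params$R
    qr_ <- drop(t(R) %*% md$car$Q %*% R)
    lp <- lp + 0.5 * md$car$rank * log(params$tau_r) - 0.5 * params$tau_r * qr_ +
      stats::dgamma(params$tau_r, priors$tau_r_shape, priors$tau_r_rate,
                    log = TRUE)
  }
  out <- ll + lp
  if (!is.finite(out)) stop("non-finite log prior at supplied parameters")
  out
}

#' Per-observation log-likelihood at a parameter state
#'
#' Evaluates the data log-likelihood (beta or Gaussian according to the
#' spec) observation by observation, without prior terms. Useful for
#' cross-checking stored sampler likelihoods and for information
#' criteria.
#'
#' @param md a `model_data`.
#' @param params parameter list as in [log_joint()].
#' @return Numeric vector, one log-density per observation.
#' @export
model_loglik <- function(md, params) pointwise_loglik(md, params)

# per-observation log-likelihood at a parameter state
pointwise_loglik <- function(md, params) {
  eta <- drop(md$X %*% params$beta) + params$S[md$species_idx]
  if (md$spec$region) eta <- eta + params$R[md$region_idx]
  ld <- params$gamma[1] + params$gamma[2] * md$logn
  if (md$spec$response == "H") {
    mu <- stats::plogis(eta)
    delta <- exp(ld)
    stats::dbeta(md$y, mu * delta, (1 - mu) * delta, log = TRUE)
  } else {
    stats::dnorm(md$y, eta, exp(-0.5 * ld), log = TRUE)
  }
}

#' Fit a diversity mixed model by MCMC
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler for the spec's model:
#' scalar random-walk updates for fixed effects, dispersion coefficients,
#' species effects (multivariate-normal prior through the taxonomy
#' precision) and region effects (intrinsic CAR prior, overall level
#' transferred to the intercept each sweep), a conjugate gamma update for
#' the CAR precision and a log-scale walk for the species-effect scale.
#' Fully reproducible given `seed`; attaches split-free Gelman-Rubin
#' R-hat per parameter and warns (does not fail) when any exceeds 1.1.
#'
#' @param ds a `diversity_dataset`.
#' @param spec a `model_spec`.
#' @param graph a `region_graph` (required for region models).
#' @param priors a `prior_config`.
#' @param mcmc an `mcmc_settings`.
#' @param seed integer seed for all chains.
#' @param rho Grafen exponent for the taxonomy correlation.
#' @return An object of class `seadiv_fit`: list with `spec`, `md` (the
#'   `model_data`), `chains` (list of per-chain draw matrices),
#'   `draws` (all chains stacked), `loglik` (per-draw data
#'   log-likelihood), `loglik_obs` (per-draw per-observation matrix),
#'   `rhat`, `priors`, `mcmc`, `seed`.
#' @export
fit_model <- function(ds, spec, graph = NULL, priors = prior_config(),
                      mcmc = mcmc_settings(), seed = 1, rho = 1) {
  md <- prepare_model_data(ds, spec, graph = graph, rho = rho)
  fit_model_data(md, priors = priors, mcmc = mcmc, seed = seed)
}

# fit from prepared model data (shared by fit_model and the ladder)
fit_model_data <- function(md, priors = prior_config(),
                           mcmc = mcmc_settings(), seed = 1) {
  spec <- md$spec
  family <- if (spec$response == "H") 0L else 1L
  K <- length(md$region_ids)
  Tn <- length(md$species)
  p <- ncol(md$X)

  if (K) {
    Wu <- md$car$W
    up <- which(upper.tri(Wu) & Wu > 0, arr.ind = TRUE)
    ci <- up[, 1]; cj <- up[, 2]; cw <- Wu[up]
    car_rank <- md$car$rank
  } else {
    ci <- cj <- integer(0); cw <- numeric(0); car_rank <- 0L
  }
  # latitude-type columns get dedicated directional moves against the
  # region effects (they share the spatial axis with the CAR term)
  confound_cols <- if (K) which(colnames(md$X) %in% c("latitude", "latitude_sq"))
                   else integer(0)

  # centre log(n) for sampling: decorrelates the two dispersion
  # coefficients; draws are transformed back to the raw-log(n) scale
  mln <- mean(md$logn)
  logn_c <- md$logn - mln

  set.seed(as.integer(seed) %% .Machine$integer.max)
  chains <- vector("list", mcmc$chains)
  ll <- ll_obs <- NULL
  for (ch in seq_len(mcmc$chains)) {
    init <- list(
      beta = c(if (family == 0L) stats::qlogis(mean(md$y)) else mean(md$y),
               rep(0, p - 1)) + stats::rnorm(p, 0, 0.1),
      gamma = c(if (family == 0L) log(10) else -log(stats::var(md$y)), 0) +
        stats::rnorm(2, 0, 0.1),
      S = stats::rnorm(Tn, 0, 0.05),
      R = if (K) stats::rnorm(K, 0, 0.05) else numeric(0),
      sigma_s = 0.3 * exp(stats::rnorm(1, 0, 0.2)),
      tau_r = 10)
    res <- run_mcmc_chain(family, md$y, md$X, logn_c,
                          md$species_idx, md$region_idx, md$prec,
                          ci, cj, cw, car_rank, confound_cols,
                          unclass(priors), unclass(mcmc), init)
    p_g0 <- p + 1L
    res$draws[, p_g0] <- res$draws[, p_g0] - res$draws[, p_g0 + 1L] * mln
    colnames(res$draws) <- c(
      paste0("beta[", colnames(md$X), "]"), "gamma0", "gamma1",
      paste0("S[", md$species, "]"), "sigma_S",
      if (K) c(paste0("R[", md$region_ids, "]"), "tau_R"))
    chains[[ch]] <- res$draws
    ll <- c(ll, res$loglik)
    ll_obs <- rbind(ll_obs, res$loglik_obs)
  }
  draws <- do.call(rbind, chains)
  rhat <- gelman_rubin(chains)
  high <- rhat[!is.na(rhat) & rhat > 1.1]
  if (length(high))
    warning(length(high), " parameter(s) with R-hat > 1.1 (max ",
            round(max(high), 3), "); consider a longer run")
  structure(list(spec = spec, md = md, chains = chains, draws = draws,
                 loglik = ll, loglik_obs = ll_obs, rhat = rhat,
                 priors = priors, mcmc = mcmc, seed = seed),
            class = "seadiv_fit")
}

#' @export
print.seadiv_fit <- function(x, ...) {
  cat("Bayesian ", if (x$spec$response == "H") "beta-regression" else
        "Gaussian", " mixed model [", format(x$spec), "]\n",
      nrow(x$draws), " draws (", x$mcmc$chains, " chains), ",
      length(x$md$y), " populations, ", length(x$md$species),
      " species\n", "max R-hat ", round(max(x$rhat, na.rm = TRUE), 3),
      "\n", sep = "")
  invisible(x)
}

# posterior means of every parameter, as a params list
posterior_mean_params <- function(fit) {
  m <- colMeans(fit$draws)
  p <- ncol(fit$md$X)
  Tn <- length(fit$md$species)
  K <- length(fit$md$region_ids)
  list(beta = unname(m[seq_len(p)]),
       gamma = unname(m[p + 1:2]),
       S = unname(m[p + 2 + seq_len(Tn)]),
       sigma_s = unname(m[p + 2 + Tn + 1]),
       R = if (K) unname(m[p + 3 + Tn + seq_len(K)]) else numeric(0),
       tau_r = if (K) unname(m[p + 3 + Tn + K + 1]) else NA_real_)
}

# params list for one stored draw
draw_params <- function(fit, i) {
  m <- fit$draws[i, ]
  p <- ncol(fit$md$X)
  Tn <- length(fit$md$species)
  K <- length(fit$md$region_ids)
  list(beta = unname(m[seq_len(p)]),
       gamma = unname(m[p + 1:2]),
       S = unname(m[p + 2 + seq_len(Tn)]),
       sigma_s = unname(m[p + 2 + Tn + 1]),
       R = if (K) unname(m[p + 3 + Tn + seq_len(K)]) else numeric(0),
       tau_r = if (K) unname(m[p + 3 + Tn + K + 1]) else NA_real_)
}

#' Posterior summary of region effects
#'
#' Per region: posterior mean, sd and equal-tailed 95% interval of the
#' region effect (logit scale for H models, z scale for Z models), a
#' significance flag (interval excludes zero) and a low-support flag for
#' regions with fewer than ten sampled populations, whose means should
#' not be over-interpreted.
#'
#' @param fit a `seadiv_fit` whose spec includes region effects.
#' @return data.frame with columns `region`, `n_species`, `n_pops`,
#'   `mean`, `sd`, `lower`, `upper`, `significant`, `low_support`.
#' @export
regional_summary <- function(fit) {
  if (!fit$spec$region) stop("model spec does not include region effects")
  ids <- fit$md$region_ids
  cols <- paste0("R[", ids, "]")
  d <- fit$draws[, cols, drop = FALSE]
  qs <- apply(d, 2, stats::quantile, probs = c(0.025, 0.975))
  r <- fit$md$records
  n_pops <- as.integer(table(factor(r$region, levels = ids)))
  n_species <- vapply(ids, function(g)
    length(unique(r$species[r$region == g])), integer(1))
  out <- data.frame(region = ids, n_species = n_species, n_pops = n_pops,
                    mean = colMeans(d), sd = apply(d, 2, stats::sd),
                    lower = qs[1, ], upper = qs[2, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$lower > 0 | out$upper < 0
  out$low_support <- out$n_pops < 10
  out
}
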