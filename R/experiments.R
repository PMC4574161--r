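#' Parameter-recovery experiment for the latitude coefficients
#'
#' Repeatedly simulates data with the default latitudinal hump
#' (0.558 / -0.920 on the standardised scale) and no spatial effects,
#' fits the matching beta-regression spec (S + M + n + L + L2), and
#' records whether each coefficient's equal-tailed 95% credible interval
#' covers its true value. Simulating from the model actually fitted is
#' what makes the nominal coverage level the right yardstick; spatial
#' effects are exercised separately (see [selection_experiment()]),
#' because a fresh intrinsic-CAR draw projects unpredictably onto the
#' latitude axis and would turn this calibration check into a test of
#' spatial confounding instead.
#'
#' @param n_rep number of replicates.
#' @param n_species,n_populations,n_regions replicate scale.
#' @param mcmc an `mcmc_settings`.
#' @param seed integer; replicate r uses `seed * 1000 + r`.
#' @return A list with `coverage_lat`, `coverage_lat_sq` (proportions),
#'   `mean_lat`, `mean_lat_sq` (average posterior means) and the
#'   per-replicate data.frame `detail`.
#' @export
recovery_experiment <- function(n_rep = 100, n_species = 25,
                                n_populations = 150, n_regions = 8,
                                mcmc = mcmc_settings(2, 3000, 1000, 2),
                                seed = 1) {
  graph <- chain_adjacency(n_regions)
  truth <- simulation_truth(sigma_r = 0)
  spec <- model_spec("H", latitude = TRUE, latitude_sq = TRUE)
  detail <- data.frame(rep = seq_len(n_rep), cover_lat = NA, cover_lat_sq = NA,
                       mean_lat = NA_real_, mean_lat_sq = NA_real_)
  for (r in seq_len(n_rep)) {
    s <- (seed * 1000 + r) %% .Machine$integer.max
    sim <- simulate_dataset(n_species, n_populations, graph = graph,
                            truth = truth, seed = s)
    f <- suppressWarnings(fit_model(sim$dataset, spec, mcmc = mcmc, seed = s + 1))
    q1 <- stats::quantile(f$draws[, "beta[latitude]"], c(0.025, 0.975))
    q2 <- stats::quantile(f$draws[, "beta[latitude_sq]"], c(0.025, 0.975))
    detail$cover_lat[r] <- q1[1] <= truth$beta_lat && truth$beta_lat <= q1[2]
    detail$cover_lat_sq[r] <- q2[1] <= truth$beta_lat2 && truth$beta_lat2 <= q2[2]
    detail$mean_lat[r] <- mean(f$draws[, "beta[latitude]"])
    detail$mean_lat_sq[r] <- mean(f$draws[, "beta[latitude_sq]"])
  }
  list(coverage_lat = mean(detail$cover_lat),
       coverage_lat_sq = mean(detail$cover_lat_sq),
       mean_lat = mean(detail$mean_lat),
       mean_lat_sq = mean(detail$mean_lat_sq),
       detail = detail)
}

#' Model-selection consistency experiment
#'
#' Simulates data under the full default truth — spatially structured
#' region effects plus the latitudinal hump — runs the six-spec
#' beta-family ladder and counts how often the full model
#' (S + M + n + L + L2 + R) has the lowest DIC.
#'
#' @param n_rep number of replicates.
#' @param n_species,n_populations replicate scale (17 coastal-chain
#'   regions).
#' @param mcmc an `mcmc_settings`.
#' @param seed integer seed.
#' @return A list with `wins` (count), `n_rep`, and per-replicate
#'   best-model labels `best`.
#' @export
selection_experiment <- function(n_rep = 10, n_species = 40,
                                 n_populations = 300,
                                 mcmc = mcmc_settings(2, 3000, 1000, 2),
                                 seed = 1) {
  graph <- chain_adjacency(17, ids = 25:41)
  best <- character(n_rep)
  full <- "S + M + n + L + L2 + R"
  for (r in seq_len(n_rep)) {
    s <- (seed * 1000 + 500 + r) %% .Machine$integer.max
    sim <- simulate_dataset(n_species, n_populations, graph = graph, seed = s)
    lad <- suppressWarnings(run_ladder(sim$dataset, graph, mcmc = mcmc,
                                       seed = s + 1, families = "H"))
    cmp <- lad$comparison
    best[r] <- cmp$model[which.min(cmp$DIC)]
  }
  list(wins = sum(best == full), n_rep = n_rep, best = best)
}

#' Posterior-predictive calibration experiment
#'
#' Simulates data from the full default truth, fits the matching full
#' beta-regression model and computes the posterior predictive p-value
#' (response-sd discrepancy). When the fitted model is the generating
#' model the PPP should rarely be extreme; the experiment reports the
#' fraction of replicates with PPP inside (0.05, 0.95).
#'
#' @param n_rep number of replicates.
#' @param n_species,n_populations,n_regions replicate scale.
#' @param mcmc an `mcmc_settings`.
#' @param seed integer seed.
#' @return A list with `inside` (proportion in the open interval),
#'   `ppp` (vector of p-values).
#' @export
ppp_experiment <- function(n_rep = 100, n_species = 20,
                           n_populations = 120, n_regions = 8,
                           mcmc = mcmc_settings(2, 3000, 1000, 2),
                           seed = 1) {
  graph <- chain_adjacency(n_regions)
  spec <- model_spec("H", latitude = TRUE, latitude_sq = TRUE, region = TRUE)
  ppp <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    s <- (seed * 1000 + 900 + r) %% .Machine$integer.max
    sim <- simulate_dataset(n_species, n_populations, graph = graph, seed = s)
    f <- suppressWarnings(fit_model(sim$dataset, spec, graph = graph,
                                    mcmc = mcmc, seed = s + 1))
    ppp[r] <- posterior_predictive_p(f)$ppp
  }
  list(inside = mean(ppp > 0.05 & ppp < 0.95), ppp = ppp)
}
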