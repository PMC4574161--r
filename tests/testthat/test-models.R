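test_that("model specs enforce the ladder's structural rules", {
  expect_error(model_spec("H", latitude = FALSE, latitude_sq = TRUE),
               "latitude_sq requires latitude")
  expect_true(model_spec("H")$marker)
  expect_false(model_spec("Z")$marker)

  z <- ladder_specs("Z")
  h <- ladder_specs("H")
  expect_equal(names(z), c("S + n", "S + n + L", "S + n + L + L2",
                           "S + n + R", "S + n + L + R",
                           "S + n + L + L2 + R"))
  expect_equal(names(h), c("S + M + n", "S + M + n + L",
                           "S + M + n + L + L2", "S + M + n + R",
                           "S + M + n + L + R", "S + M + n + L + L2 + R"))
})

test_that("the design matrix uses allozyme as reference and standardised latitude", {
  sim <- small_sim()
  md <- prepare_model_data(sim$dataset,
                           model_spec("H", TRUE, TRUE, TRUE),
                           graph = small_graph())
  cn <- colnames(md$X)
  expect_false("marker:allozyme" %in% cn)
  expect_true(any(grepl("^marker:", cn)))
  expect_equal(mean(md$X[, "latitude"]), 0, tolerance = 1e-12)
  expect_equal(sd(md$X[, "latitude"]), 1, tolerance = 1e-12)
  expect_equal(md$X[, "latitude_sq"], md$X[, "latitude"]^2)
  expect_equal(qr(md$X)$rank, ncol(md$X))
})

test_that("the beta log-likelihood matches per-term brute force and the uniform case", {
  rec <- toy_records(5, diversity = c(0.5, 0.31, 0.62, 0.44, 0.57))
  md <- prepare_model_data(diversity_dataset(rec), model_spec("H"))
  # single marker level in the toy data: X is just the intercept
  params <- list(beta = 0.2, gamma = c(1.1, 0.3), S = 0.15, sigma_s = 0.4)
  ll <- model_loglik(md, params)
  mu <- plogis(0.2 + 0.15)
  delta <- exp(1.1 + 0.3 * log(20))
  oracle <- dbeta(rec$diversity, mu * delta, (1 - mu) * delta, log = TRUE)
  expect_equal(ll, oracle, tolerance = 1e-12)

  # Beta(1, 1) is the uniform density: zero log-likelihood contribution
  u <- prepare_model_data(diversity_dataset(toy_records(1, diversity = 0.5)),
                          model_spec("H"))
  params_u <- list(beta = 0, gamma = c(log(2), 0), S = 0, sigma_s = 0.4)
  expect_equal(model_loglik(u, params_u), 0, tolerance = 1e-12)
})

test_that("the log joint is invariant to transferring the region level to the intercept", {
  sim <- small_sim()
  md <- prepare_model_data(sim$dataset, model_spec("H", TRUE, TRUE, TRUE),
                           graph = small_graph())
  k <- length(md$region_ids)
  Tn <- length(md$species)
  params <- list(beta = c(0.4, rep(0.1, ncol(md$X) - 1)),
                 gamma = c(2, 0.2), S = rep(0.05, Tn), sigma_s = 0.5,
                 R = seq(-0.2, 0.2, length.out = k), tau_r = 20)
  shifted <- params
  shifted$R <- params$R + 0.3
  shifted$beta[1] <- params$beta[1] - 0.3
  expect_equal(sum(model_loglik(md, shifted)), sum(model_loglik(md, params)),
               tolerance = 1e-10)
  # the joint moves only by the intercept's prior: the CAR quadratic is
  # itself invariant to a constant shift of the region effects
  prior_diff <- dnorm(shifted$beta[1], 0, 10, log = TRUE) -
    dnorm(params$beta[1], 0, 10, log = TRUE)
  expect_equal(log_joint(md, shifted) - log_joint(md, params), prior_diff,
               tolerance = 1e-10)
})

test_that("fitting is deterministic given the seed", {
  sim <- small_sim()
  spec <- model_spec("H", latitude = TRUE)
  m <- mcmc_settings(2, 600, 200, 2)
  f1 <- suppressWarnings(fit_model(sim$dataset, spec, mcmc = m, seed = 31))
  f2 <- suppressWarnings(fit_model(sim$dataset, spec, mcmc = m, seed = 31))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_model(sim$dataset, spec, mcmc = m, seed = 32))
  expect_false(identical(f3$draws, f1$draws))
})

test_that("stored sampler likelihoods match an independent recomputation", {
  f <- small_fit()
  idx <- c(1, 50, 500, nrow(f$draws))
  for (i in idx) {
    pars <- list(beta = unname(f$draws[i, seq_len(ncol(f$md$X))]),
                 gamma = unname(f$draws[i, c("gamma0", "gamma1")]),
                 S = unname(f$draws[i, paste0("S[", f$md$species, "]")]),
                 sigma_s = unname(f$draws[i, "sigma_S"]),
                 R = unname(f$draws[i, paste0("R[", f$md$region_ids, "]")]),
                 tau_r = unname(f$draws[i, "tau_R"]))
    expect_equal(sum(model_loglik(f$md, pars)), f$loglik[i], tolerance = 1e-8)
    expect_equal(model_loglik(f$md, pars), unname(f$loglik_obs[i, ]),
                 tolerance = 1e-8)
  }
})

test_that("the Gaussian family recovers ordinary least squares without grouping noise", {
  # one species, five dataIDs: after z-scoring, the only real structure is
  # the latitude slope; the posterior mean must sit near the OLS estimate
  set.seed(77)
  n <- 100
  ids <- rep(paste0("study", 1:5, ":allozyme"), each = 20)
  lat <- runif(n, -40, -10)
  z_raw <- 0.8 * scale(lat)[, 1] + rnorm(n, 0, 0.6)
  rec <- data.frame(
    data_id = ids, class = "C", order = "O", family = "F", genus = "G",
    species = "G_sp", marker = "allozyme", latitude = lat, longitude = 150,
    region = "r1", n = 20, diversity = plogis(z_raw), stringsAsFactors = FALSE)
  ds <- diversity_dataset(rec)
  f <- suppressWarnings(fit_model(ds, model_spec("Z", latitude = TRUE),
                                  mcmc = mcmc_settings(2, 2000, 800, 2),
                                  seed = 3))
  zz <- add_zscores(ds)$records
  L <- (zz$latitude - mean(zz$latitude)) / sd(zz$latitude)
  ols <- coef(lm(zz$z ~ L))[["L"]]
  post <- f$draws[, "beta[latitude]"]
  expect_lt(abs(mean(post) - ols), 2 * sd(post))
})

test_that("regional summaries flag certainty, symmetry and support correctly", {
  f <- small_fit()
  rs <- regional_summary(f)
  expect_equal(rs$region, f$md$region_ids)
  expect_true(all(rs$lower <= rs$mean & rs$mean <= rs$upper))
  expect_equal(rs$low_support, rs$n_pops < 10)

  # doctored draws: region 1 certain at +0.5, region 2 symmetric around 0
  f2 <- f
  f2$draws[, "R[1]"] <- 0.5
  sym <- rnorm(nrow(f2$draws) / 2, 0, 0.3)
  f2$draws[, "R[2]"] <- c(sym, -sym)
  rs2 <- regional_summary(f2)
  expect_equal(rs2$mean[1], 0.5)
  expect_equal(rs2$sd[1], 0)
  expect_true(rs2$significant[1])
  expect_false(rs2$significant[2])
  expect_equal(rs2$mean[2], 0, tolerance = 1e-12)

  # brute-force check of the interval against sorted draws
  d <- f$draws[, "R[3]"]
  rs3 <- regional_summary(f)
  inside <- mean(d >= rs3$lower[3] & d <= rs3$upper[3])
  expect_equal(inside, 0.95, tolerance = 0.005)

  expect_error(regional_summary(suppressWarnings(
    fit_model(small_sim()$dataset, model_spec("H"),
              mcmc = mcmc_settings(2, 400, 100, 2), seed = 5))),
    "does not include region")
})

test_that("beta parameterisation has the stated mean and variance", {
  set.seed(40)
  for (mu in c(0.3, 0.7)) {
    for (delta in c(5, 40)) {
      x <- rbeta(1e5, mu * delta, (1 - mu) * delta)
      se_m <- sqrt(mu * (1 - mu) / (1 + delta) / 1e5)
      expect_lt(abs(mean(x) - mu), 3 * se_m)
      expect_equal(var(x), mu * (1 - mu) / (1 + delta), tolerance = 0.05)
    }
  }
})

test_that("the full model recovers the hump signs at coastal scale", {
  g <- chain_adjacency(17, ids = 25:41)
  sim <- simulate_dataset(84, 959, graph = g, seed = 5)
  f <- suppressWarnings(fit_model(sim$dataset,
                                  model_spec("H", TRUE, TRUE, TRUE),
                                  graph = g,
                                  mcmc = mcmc_settings(2, 3000, 1000, 2),
                                  seed = 2))
  lat <- f$draws[, "beta[latitude]"]
  lat2 <- f$draws[, "beta[latitude_sq]"]
  expect_gt(mean(lat > 0), 0.95)    # diversity rises toward the equator
  expect_gt(mean(lat2 < 0), 0.95)   # with a hump across the range
})
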