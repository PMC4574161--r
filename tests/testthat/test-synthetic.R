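flat_truth <- function(intercept = qlogis(0.6), ...) {
  simulation_truth(intercept = intercept,
                   marker = c(microsatellite = 0, mtDNA_sequence = 0,
                              mtDNA_restriction = 0, nuclear_sequence = 0,
                              other = 0),
                   beta_lat = 0, beta_lat2 = 0, sigma_s = 0, sigma_r = 0, ...)
}

test_that("the same seed reproduces a dataset exactly", {
  g <- chain_adjacency(5)
  a <- simulate_dataset(15, 80, graph = g, seed = 123)
  b <- simulate_dataset(15, 80, graph = g, seed = 123)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$truth$region_effects, b$truth$region_effects)
  c <- simulate_dataset(15, 80, graph = g, seed = 124)
  expect_false(identical(a$dataset$records, c$dataset$records))
})

test_that("a flat truth yields the requested mean diversity", {
  g <- chain_adjacency(4)
  sim <- simulate_dataset(20, 8000, graph = g, truth = flat_truth(), seed = 2)
  H <- sim$dataset$records$diversity
  # mean of Beta(mu delta, (1-mu) delta) is mu = 0.6; 3 MC standard errors
  se <- sd(H) / sqrt(length(H))
  expect_lt(abs(mean(H) - 0.6), 3 * se)
})

test_that("an injected region effect appears with the right magnitude", {
  g <- chain_adjacency(4)
  tr <- flat_truth(intercept = 0)
  tr$region_effects <- c("1" = 0, "2" = 1, "3" = 0, "4" = 0)
  sim <- simulate_dataset(20, 8000, graph = g, truth = tr, seed = 3)
  r <- sim$dataset$records
  lg <- qlogis(pmin(pmax(r$diversity, 1e-6), 1 - 1e-6))
  m <- tapply(lg, r$region, mean)
  gap <- m["2"] - mean(m[c("1", "3", "4")])
  expect_lt(abs(gap - 1), 0.1)
})

test_that("generated datasets always satisfy the record invariants", {
  g <- chain_adjacency(17, ids = 25:41)
  sim <- simulate_dataset(84, 959, graph = g, seed = 6)
  ds <- sim$dataset                    # construction already validates
  r <- ds$records
  expect_equal(nrow(r), 959)
  expect_equal(length(ds$species), 84)
  expect_true(all(table(r$data_id) >= 3))
  expect_true(all(r$n >= 5))
  expect_true(all(r$marker %in% marker_levels()))
  expect_true(all(r$diversity >= 0 & r$diversity <= 1))
  # marker mix lands near the target frequencies
  expect_lt(abs(mean(r$marker == "allozyme") - 0.328), 0.12)
  expect_lt(abs(mean(r$marker == "microsatellite") - 0.314), 0.12)
  # latitudes span the coastal gradient, region-ordered
  cen <- tapply(r$latitude, r$region, mean)
  expect_lt(min(r$latitude), -40)
  expect_gt(max(r$latitude), -13)
  expect_true(cor(as.numeric(names(cen)), cen) < -0.9)
})

test_that("diversity variance declines with sample size when gamma1 > 0", {
  g <- chain_adjacency(4)
  sim <- simulate_dataset(20, 10000, graph = g, truth = flat_truth(), seed = 4)
  r <- sim$dataset$records
  qs <- quantile(r$n, c(0.25, 0.75))
  v_small <- var(r$diversity[r$n <= qs[1]])
  v_large <- var(r$diversity[r$n >= qs[2]])
  expect_gt(v_small, v_large)
})

test_that("a written synthetic dataset reads back identically", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sim$dataset, path)
  back <- read_dataset(path)
  expect_equal(back$records, sim$dataset$records, tolerance = 1e-12)
  expect_equal(back$species, sim$dataset$species)
  expect_equal(back$data_ids, sim$dataset$data_ids)
})

test_that("likelihood replicates concentrate at mu as dispersion grows", {
  sim <- small_sim()
  md <- prepare_model_data(sim$dataset, model_spec("H"))
  Tn <- length(md$species)
  params <- list(beta = qlogis(0.55), gamma = c(log(1e6), 0),
                 S = rep(0, Tn), sigma_s = 0.3)
  if (ncol(md$X) > 1) params$beta <- c(qlogis(0.55), rep(0, ncol(md$X) - 1))
  rep1 <- simulate_null_for_ppp(md, params, seed = 11)
  expect_lt(sd(rep1), 0.01)
  rep2 <- simulate_null_for_ppp(md, params, seed = 11)
  expect_identical(rep1, rep2)
  rep3 <- simulate_null_for_ppp(md, params, seed = 12)
  expect_false(identical(rep1, rep3))
})

test_that("the full-database emulation restricts exactly to the coastal component", {
  full <- simulate_full_database(seed = 9)
  expect_equal(nrow(full$dataset$records), 1154)
  expect_equal(length(full$dataset$species), 101)
  coastal <- filter_regions(full$dataset, 25:41, min_pops_per_data_id = 3)
  expect_equal(nrow(coastal$records), 959)
  expect_equal(length(coastal$species), 84)
  expect_equal(coastal$records, full$coastal$records)
})
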