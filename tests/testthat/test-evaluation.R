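test_that("a degenerate posterior has zero effective parameters", {
  f <- small_fit()
  one <- f$draws[17, , drop = FALSE]
  f2 <- f
  f2$draws <- one[rep(1, 400), ]
  pars <- list(beta = unname(one[1, seq_len(ncol(f$md$X))]),
               gamma = unname(one[1, c("gamma0", "gamma1")]),
               S = unname(one[1, paste0("S[", f$md$species, "]")]),
               sigma_s = unname(one[1, "sigma_S"]),
               R = unname(one[1, paste0("R[", f$md$region_ids, "]")]),
               tau_r = unname(one[1, "tau_R"]))
  f2$loglik <- rep(sum(model_loglik(f$md, pars)), 400)
  d <- dic(f2)
  expect_equal(d$pD, 0, tolerance = 1e-8)
  expect_equal(d$DIC, d$Dhat, tolerance = 1e-8)
})

test_that("DIC counts one effective parameter in a conjugate normal-mean toy", {
  # y ~ N(theta, 1), flat-limit prior: posterior theta ~ N(ybar, 1/n);
  # with one free parameter pD must approach 1
  set.seed(8)
  n <- 50
  y <- rnorm(n, 2, 1)
  theta <- rnorm(40000, mean(y), 1 / sqrt(n))
  ll <- vapply(theta, function(t) sum(dnorm(y, t, 1, log = TRUE)), numeric(1))
  d <- dic_components(ll, sum(dnorm(y, mean(theta), 1, log = TRUE)))
  expect_equal(d$pD, 1, tolerance = 0.1)
})

test_that("DIC recomputed from exported draws matches the fit exactly", {
  f <- small_fit()
  d <- dic(f)
  # independent recomputation from the stored draw matrix
  ll <- vapply(seq_len(nrow(f$draws)), function(i) {
    pars <- list(beta = unname(f$draws[i, seq_len(ncol(f$md$X))]),
                 gamma = unname(f$draws[i, c("gamma0", "gamma1")]),
                 S = unname(f$draws[i, paste0("S[", f$md$species, "]")]),
                 sigma_s = unname(f$draws[i, "sigma_S"]),
                 R = unname(f$draws[i, paste0("R[", f$md$region_ids, "]")]),
                 tau_r = unname(f$draws[i, "tau_R"]))
    sum(model_loglik(f$md, pars))
  }, numeric(1))
  expect_equal(mean(-2 * ll), d$Dbar, tolerance = 1e-8)
  expect_equal(d$pD, d$Dbar - d$Dhat, tolerance = 1e-12)
  expect_gt(d$pD, 0)
})

test_that("DIC weights are stable, normalised and shift-invariant", {
  expect_equal(dic_weights(42), 100)
  w <- dic_weights(c(-661.8, -681.2, -692.1, -697.2, -711.8, -715.5))
  expect_equal(sum(w), 100, tolerance = 1e-10)
  expect_equal(dic_weights(c(-661.8, -681.2, -692.1, -697.2, -711.8, -715.5) + 1e4),
               w, tolerance = 1e-10)
  # an irrelevant model with huge DIC leaves the others unchanged
  w2 <- dic_weights(c(-661.8, -681.2, -692.1, -697.2, -711.8, -715.5, 1e3))
  expect_equal(round(w2[1:6], 4), round(w, 4))
  expect_error(dic_weights(c(1, Inf)), "finite")
  expect_error(dic_weights(numeric(0)), "finite")
})

test_that("posterior predictive p-values detect impossible data and need draws", {
  f <- small_fit()
  p <- posterior_predictive_p(f)
  expect_true(p$ppp >= 0 && p$ppp <= 1)
  expect_equal(p$extreme, p$ppp < 0.05 || p$ppp > 0.95)

  # constant observed response: zero sd is beneath every replicate's sd
  f2 <- f
  f2$md$y <- rep(0.62, length(f$md$y))
  p2 <- posterior_predictive_p(f2)
  expect_equal(p2$ppp, 1)
  expect_true(p2$extreme)

  f3 <- f
  f3$draws <- f$draws[1:50, ]
  expect_error(posterior_predictive_p(f3), "at least 200")
  expect_error(posterior_predictive_p(f, discrepancy = "entropy"))
})

test_that("alternative discrepancies run and stay in [0, 1]", {
  f <- small_fit()
  for (d in c("mean", "chisq")) {
    p <- posterior_predictive_p(f, discrepancy = d, draws = 250)
    expect_true(p$ppp >= 0 && p$ppp <= 1)
  }
})

test_that("Gelman-Rubin matches the textbook formula and flags divergence", {
  set.seed(13)
  chains <- lapply(1:3, function(i) matrix(rnorm(600), 200, 3,
                                           dimnames = list(NULL, c("a", "b", "c"))))
  got <- gelman_rubin(chains)
  # independent textbook implementation
  oracle <- sapply(1:3, function(j) {
    x <- sapply(chains, function(ch) ch[, j])
    n <- nrow(x)
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    sqrt(((n - 1) / n * W + B / n) / W)
  })
  expect_equal(unname(got), oracle, tolerance = 1e-12)

  same <- chains[c(1, 1)]
  expect_equal(unname(gelman_rubin(same)), rep(sqrt(199 / 200), 3),
               tolerance = 1e-12)

  apart <- list(chains[[1]], chains[[2]] + 50)
  expect_true(all(gelman_rubin(apart) > 10))

  expect_error(gelman_rubin(chains[1]), "at least two chains")
})
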