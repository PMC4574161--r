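#' Run the twelve-model comparison ladder
#'
#' Fits the six-spec ladder for both response families (Gaussian on
#' standardised diversity, beta regression on raw diversity), computes
#' DIC, delta-DIC, DIC weights (percent, within each family) and a
#' posterior predictive p-value per model, and extracts a regional
#' posterior summary from every region-containing model. The best model
#' per family is the lowest DIC; an extreme PPP on the winner is flagged
#' rather than overriding the DIC ranking.
#'
#' @param ds a `diversity_dataset` (already restricted to the modelled
#'   regions).
#' @param graph a `region_graph` covering the dataset's regions.
#' @param priors a `prior_config`.
#' @param mcmc an `mcmc_settings`.
#' @param seed integer; each model uses a seed derived from it, so a
#'   rerun reproduces the ladder exactly.
#' @param families which response families to run.
#' @param keep_fits keep the full `seadiv_fit` objects (memory-heavy for
#'   long runs)?
#' @return A list of class `ladder_result`: `comparison` (data.frame with
#'   family, model, DIC, pD, delta, weight, PPP, best flag),
#'   `regional` (named list of regional summaries for R-containing
#'   models), `fits` (if kept), `seed`.
#' @export
run_ladder <- function(ds, graph, priors = prior_config(),
                       mcmc = mcmc_settings(), seed = 1,
                       families = c("Z", "H"), keep_fits = FALSE) {
  rows <- list()
  regional <- list()
  fits <- list()
  counter <- 0L
  for (fam in families) {
    specs <- ladder_specs(fam)
    res <- data.frame(family = fam, model = names(specs), DIC = NA_real_,
                      pD = NA_real_, PPP = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(specs)) {
      counter <- counter + 1L
      f <- fit_model(ds, specs[[i]], graph = graph, priors = priors,
                     mcmc = mcmc, seed = seed + counter)
      d <- dic(f)
      res$DIC[i] <- d$DIC
      res$pD[i] <- d$pD
      res$PPP[i] <- posterior_predictive_p(f)$ppp
      key <- paste0(fam, ": ", names(specs)[i])
      if (specs[[i]]$region) regional[[key]] <- regional_summary(f)
      if (keep_fits) fits[[key]] <- f
    }
    res$delta <- res$DIC - min(res$DIC)
    res$weight <- dic_weights(res$DIC)
    res$best <- seq_len(nrow(res)) == which.min(res$DIC)
    res$ppp_extreme <- res$PPP < 0.05 | res$PPP > 0.95
    rows[[fam]] <- res[c("family", "model", "DIC", "pD", "delta",
                         "weight", "PPP", "best", "ppp_extreme")]
  }
  structure(list(comparison = do.call(rbind, c(rows, make.row.names = FALSE)),
                 regional = regional, fits = fits, seed = seed),
            class = "ladder_result")
}

#' @export
print.ladder_result <- function(x, ...) {
  out <- x$comparison
  out$DIC <- round(out$DIC, 1)
  out$delta <- round(out$delta, 1)
  out$weight <- round(out$weight, 2)
  out$PPP <- round(out$PPP, 3)
  print(out[c("family", "model", "DIC", "delta", "weight", "PPP", "best")],
        row.names = FALSE)
  invisible(x)
}

#' Correlation between two sets of regional means
#'
#' Squared Pearson correlation of posterior regional means across the
#' regions shared by two summaries, restricted to regions where the
#' second ("restricting") summary has at least `min_pops` sampled
#' populations — the rule used when comparing a full-data summary with a
#' taxon-subset rerun. The one-sided p-value of a positive correlation
#' is reported alongside; note R-squared itself is sign-blind.
#'
#' @param a,b regional summary data.frames (columns `region`, `mean`,
#'   `n_pops`), e.g. from [regional_summary()].
#' @param min_pops minimum `n_pops` in `b` for a region to enter.
#' @return A list with `n_regions`, `r`, `r_squared` and `p_value`
#'   (one-sided, positive association).
#' @export
cross_model_correlation <- function(a, b, min_pops = 0) {
  shared <- intersect(a$region, b$region[b$n_pops >= min_pops])
  if (length(shared) < 3)
    stop("fewer than three shared regions after restriction")
  x <- a$mean[match(shared, a$region)]
  y <- b$mean[match(shared, b$region)]
  r <- stats::cor(x, y)
  n <- length(shared)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(n_regions = n, r = r, r_squared = r^2,
       p_value = stats::pt(tstat, n - 2, lower.tail = FALSE))
}
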