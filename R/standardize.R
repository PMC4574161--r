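#' Z-score values within groups
#'
#' Centres and scales `values` within each level of `groups`, using the
#' sample (n - 1 denominator) standard deviation. Groups with fewer than
#' two members, or with zero variance, cannot be standardised: their
#' entries are returned as `NA` and the group labels are reported in the
#' `skipped` component rather than being silently zero-filled.
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`.
#' @return A list with `z` (numeric, input order preserved) and `skipped`
#'   (character vector of group labels that could not be standardised).
#' @export
zscore_by_group <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  z <- rep(NA_real_, length(values))
  skipped <- character()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    v <- values[idx]
    s <- stats::sd(v)
    if (length(idx) < 2L || !is.finite(s) || s == 0) {
      skipped <- c(skipped, g)
    } else {
      z[idx] <- (v - mean(v)) / s
    }
  }
  list(z = z, skipped = skipped)
}

#' Add a within-dataID z-scored diversity column
#'
#' Standardises diversity within each dataID (study-by-marker group),
#' producing the response for the Gaussian model family. Populations in
#' degenerate dataIDs (single member or zero variance) get `NA` and are
#' listed in the `skipped_data_ids` attribute; model fitting drops them.
#'
#' @param ds a `diversity_dataset`.
#' @return The dataset with a `z` column added to `records` and an
#'   attribute `skipped_data_ids`.
#' @export
add_zscores <- function(ds) {
  zs <- zscore_by_group(ds$records$diversity, ds$records$data_id)
  ds$records$z <- zs$z
  attr(ds, "skipped_data_ids") <- zs$skipped
  ds
}
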