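#' Reference model-comparison table
#'
#' DIC and posterior-predictive p-values reported for the twelve-model
#' ladder in the published coastal bioregion analysis whose conditions
#' the package's defaults emulate. Used as a fixed input for DIC-weight
#' and delta-DIC arithmetic and as a yardstick in the analysis scripts;
#' nothing in the package estimates these numbers from this file.
#'
#' @return data.frame with columns `family`, `model`, `DIC`, `PPP`.
#' @export
reference_model_table <- function() {
  utils::read.csv(system.file("extdata", "reference_model_dic.csv",
                              package = "seadiv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference regional posterior means
#'
#' Published regional posterior means and standard deviations for the
#' best standardised (Z) and unstandardised (H) models, plus the
#' fish-only and mollusc-only beta-model reruns, over the 17 coastal
#' bioregions. Serves as fixed input for cross-model correlation
#' arithmetic.
#'
#' @return data.frame, one row per coastal region.
#' @export
reference_regional_means <- function() {
  utils::read.csv(system.file("extdata", "reference_regional_means.csv",
                              package = "seadiv"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

# regional-summary-shaped view of one block of the reference table
reference_summary <- function(block = c("z", "h", "fish", "mollusc")) {
  block <- match.arg(block)
  ref <- reference_regional_means()
  pick <- function(mean_col, pop_col) {
    out <- data.frame(region = as.character(ref$region),
                      mean = ref[[mean_col]], n_pops = ref[[pop_col]],
                      stringsAsFactors = FALSE)
    out[!is.na(out$mean), , drop = FALSE]
  }
  switch(block,
         z = pick("z_mean", "n_pops"),
         h = pick("h_mean", "n_pops"),
         fish = pick("fish_mean", "fish_pops"),
         mollusc = pick("mollusc_mean", "mollusc_pops"))
}
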