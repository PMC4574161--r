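# shared builders for the test suite; everything is generated in code

# a minimal valid record table (one species, one region unless overridden)
toy_records <- function(n = 3, diversity = seq(0.3, 0.7, length.out = n),
                        region = "r1", species = "Genus_alpha",
                        data_id = "study1:allozyme", marker = "allozyme",
                        n_samples = 20L) {
  data.frame(
    data_id = data_id, class = "Actinopterygii", order = "Perciformes",
    family = "Sparidae", genus = "Genus", species = species,
    marker = marker, latitude = seq(-30, -28, length.out = n),
    longitude = 150, region = region, n = n_samples,
    diversity = diversity, stringsAsFactors = FALSE)
}

# small cached simulation + full-model fit shared across test files
.seadiv_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.seadiv_cache$sim)) {
    g <- chain_adjacency(4)
    .seadiv_cache$graph <- g
    .seadiv_cache$sim <- simulate_dataset(12, 70, graph = g, seed = 99)
  }
  .seadiv_cache$sim
}

small_graph <- function() {
  small_sim()
  .seadiv_cache$graph
}

small_fit <- function() {
  if (is.null(.seadiv_cache$fit)) {
    sim <- small_sim()
    .seadiv_cache$fit <- suppressWarnings(fit_model(
      sim$dataset, model_spec("H", TRUE, TRUE, TRUE), graph = small_graph(),
      mcmc = mcmc_settings(2, 1600, 600, 2), seed = 7))
  }
  .seadiv_cache$fit
}

# independent pairwise-correlation oracle: deepest shared rank, Grafen
# height = (tips below MRCA - 1) / (T - 1)
taxonomy_corr_oracle <- function(paths) {
  ranks <- c("class", "order", "family", "genus", "species")
  Tn <- nrow(paths)
  out <- diag(1, Tn)
  dimnames(out) <- list(paths$species, paths$species)
  if (Tn == 1) return(out)
  for (i in seq_len(Tn - 1)) {
    for (j in (i + 1):Tn) {
      shared <- NULL
      for (rk in ranks) if (paths[[rk]][i] == paths[[rk]][j]) shared <- rk
      if (is.null(shared)) {
        out[i, j] <- out[j, i] <- 0
      } else {
        m <- sum(paths[[shared]] == paths[[shared]][i])
        out[i, j] <- out[j, i] <- 1 - (m - 1) / (Tn - 1)
      }
    }
  }
  out
}

# random rank-consistent species paths
random_paths <- function(n, seed) {
  set.seed(seed)
  cls <- sample(paste0("C", 1:3), n, replace = TRUE)
  ord <- paste0(cls, "_O", sample(1:2, n, replace = TRUE))
  fam <- paste0(ord, "_F", sample(1:2, n, replace = TRUE))
  gen <- paste0(fam, "_G", sample(1:2, n, replace = TRUE))
  data.frame(class = cls, order = ord, family = fam, genus = gen,
             species = paste0(gen, "_s", seq_len(n)),
             stringsAsFactors = FALSE)
}
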