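#!/usr/bin/env Rscript
# Step 4: regional posterior summaries from the full beta model, plus
# taxon-subset reruns and cross-model correlations of regional means.
#
# The full model (S + M + n + L + L2 + R) is refitted with a longer run;
# its region effects are summarised with 95% equal-tailed intervals and
# significance flags. The same spec is then refitted on the fish-only
# (ray-finned + cartilaginous) and mollusc-only subsets, and regional
# means are compared across models by squared Pearson correlation over
# regions with at least 10 populations in the restricting subset.

library(seadiv)

coastal <- read_dataset("results/coastal.csv")
graph <- chain_adjacency(17, ids = 25:41)
spec_full <- model_spec("H", latitude = TRUE, latitude_sq = TRUE, region = TRUE)
spec_z <- model_spec("Z", region = TRUE)
mc <- mcmc_settings(2, 6000, 2000, 4)

fit_h <- fit_model(coastal, spec_full, graph = graph, mcmc = mc, seed = 201)
fit_z <- fit_model(coastal, spec_z, graph = graph, mcmc = mc, seed = 202)
sum_h <- regional_summary(fit_h)
sum_z <- regional_summary(fit_z)

fish <- filter_taxa(coastal, c("Actinopterygii", "Chondrichthyes"))
mol <- try(filter_taxa(coastal, c("Gastropoda", "Bivalvia")), silent = TRUE)
sum_fish <- regional_summary(fit_model(fish, spec_full, graph = graph,
                                       mcmc = mc, seed = 203))
sum_mol <- if (!inherits(mol, "try-error") && nrow(mol$records) >= 30)
  regional_summary(fit_model(mol, spec_full, graph = graph, mcmc = mc,
                             seed = 204)) else NULL

tab <- data.frame(region = sum_h$region,
                  n_species = sum_h$n_species, n_pops = sum_h$n_pops,
                  z_mean = sum_z$mean, z_sd = sum_z$sd,
                  h_mean = sum_h$mean, h_sd = sum_h$sd,
                  h_significant = sum_h$significant,
                  low_support = sum_h$low_support)
write.csv(tab, "results/regional_means.csv", row.names = FALSE)
print(tab, digits = 2)

cors <- list(z_vs_h = cross_model_correlation(sum_z, sum_h))
cors$h_vs_fish <- cross_model_correlation(sum_h, sum_fish, min_pops = 10)
if (!is.null(sum_mol))
  cors$h_vs_molluscs <- cross_model_correlation(sum_h, sum_mol, min_pops = 10)
out <- do.call(rbind, lapply(names(cors), function(nm)
  data.frame(comparison = nm, n_regions = cors[[nm]]$n_regions,
             r = cors[[nm]]$r, r_squared = cors[[nm]]$r_squared,
             p_value = cors[[nm]]$p_value)))
write.csv(out, "results/cross_correlations.csv", row.names = FALSE)
cat("\ncross-model correlations of regional means:\n")
print(out, digits = 2)

lat <- fit_h$draws[, "beta[latitude]"]
lat2 <- fit_h$draws[, "beta[latitude_sq]"]
cat(sprintf("\nlatitude: %.3f [%.3f, %.3f]; latitude^2: %.3f [%.3f, %.3f]\n",
            mean(lat), quantile(lat, 0.025), quantile(lat, 0.975),
            mean(lat2), quantile(lat2, 0.025), quantile(lat2, 0.975)))
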