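#!/usr/bin/env Rscript
# Step 2: region co-sampling cluster analysis.
#
# Which regions have been surveyed for the same species? Regions are
# clustered on their binary species-sampled profiles with Ward's
# minimum-variance criterion (distances squared going in, merge heights
# square-rooted coming out). Regions with fewer than five sampled
# species are left out.

library(seadiv)

coastal <- read_dataset("results/coastal.csv")

pm <- presence_matrix(coastal, min_species = 5)
cat("presence matrix:", nrow(pm), "regions x", ncol(pm), "species\n")
dropped <- attr(pm, "dropped_regions")
if (length(dropped)) cat("dropped (under 5 species):",
                         paste(dropped, collapse = ", "), "\n")

hc <- ward_cluster(pm)
write.csv(pm, "results/presence_matrix.csv")
write_dendrogram(hc, "results/cosampling_dendrogram.nwk")

# adjacent coastal regions should tend to merge early
cat("first merges:\n")
for (i in 1:4) {
  members <- function(x) if (x < 0) hc$labels[-x] else
    paste0("{step ", x, "}")
  cat(sprintf("  height %.2f: %s + %s\n", hc$height[i],
              members(hc$merge[i, 1]), members(hc$merge[i, 2])))
}
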