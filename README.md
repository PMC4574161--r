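# seadiv

Bayesian regional analysis of multi-species population genetic
diversity.

## What problem this solves

Published population-genetic studies report, per sampled population, a
diversity value in [0, 1] — expected heterozygosity (H_E) for nuclear
markers or haplotype diversity (h) for mitochondrial ones. Pooling
hundreds of such values across species to ask *which bioregions hold
unusually high or low genetic diversity* must deal with species-level
baselines (and their shared ancestry), marker-class differences,
uneven sampling effort, and spatial autocorrelation between
neighbouring regions. `seadiv` is for researchers doing this kind of
macrogenetic meta-analysis.

## The model

Two families, each a six-spec ladder (S + n base, then + L, + L2, + R):

- **H family** (beta regression on raw diversity):
  `y_i ~ Beta(mu_i * delta_i, (1 - mu_i) * delta_i)` with
  `logit(mu_i) = x_i' beta + R[region_i] + S[species_i]` and
  `log(delta_i) = gamma0 + gamma1 * log(n_i)`; `x_i` holds marker
  dummies and (optionally) standardised latitude and its square.
- **Z family** (Gaussian on within-study z-scored diversity):
  `z_i ~ N(x_i' beta + R[region_i] + S[species_i], 1 / tau_i)` with
  `log(tau_i) = gamma0 + gamma1 * log(n_i)`; no marker term, since
  z-scoring removes study-by-marker levels.

Structured priors carry the multi-species, multi-region information:

- `S ~ MVN(0, sigma_S^2 * C)`, where `C` is the Brownian-motion
  correlation implied by the Linnaean taxonomy under Grafen branch
  lengths (`corr(i, j) = 1 - height(MRCA)` on a depth-1 tree);
- `R` has an intrinsic CAR prior over the region adjacency graph,
  `p(R | tau_R) ∝ tau_R^(rank(Q)/2) exp(-tau_R/2 * R' Q R)`,
  `Q = D - W`.

Model comparison uses DIC (`pD = Dbar - Dhat`, plug-in convention) with
DIC weights in percent; model checking uses posterior predictive
p-values. A separate co-sampling analysis Ward-clusters regions on
binary species-sampled profiles (distances squared in, heights
square-rooted out).

Everything is fitted by an adaptive Metropolis-within-Gibbs sampler
(C++), reproducible from one integer seed, with Gelman-Rubin
diagnostics attached.

## Worked example

```r
library(seadiv)

graph <- chain_adjacency(17, ids = 25:41)        # coastal region chain
sim <- simulate_dataset(n_species = 84, n_populations = 959,
                        graph = graph, seed = 5)  # emulated database
fit <- fit_model(sim$dataset,
                 model_spec("H", latitude = TRUE, latitude_sq = TRUE,
                            region = TRUE),
                 graph = graph, seed = 2)
round(colMeans(fit$draws[, c("beta[latitude]", "beta[latitude_sq]")]), 3)
#> beta[latitude]  beta[latitude_sq]
#>          0.786             -0.796
dic(fit)$DIC
#> [1] -2587.986
posterior_predictive_p(fit)$ppp
#> [1] 0.3
head(regional_summary(fit), 3)
#>   region n_species n_pops  mean    sd  lower upper significant low_support
#> 1     25         6     25 0.095 0.261 -0.424 0.608       FALSE       FALSE
#> 2     26         8     22 0.311 0.229 -0.132 0.760       FALSE       FALSE
#> 3     27         7     13 0.201 0.195 -0.182 0.582       FALSE       FALSE
```

The generating truth here had latitude 0.558 and latitude² −0.920: the
fit recovers the hump's signs decisively; the point values shift by the
random smooth component of the drawn region effects, which is
spatially confounded with latitude (see the methods vignette). The
regional summary gives each bioregion's posterior mean effect on the
logit scale, its 95% interval, and flags regions whose interval
excludes zero or that hold fewer than 10 populations.

`dic_weights()` turns a ladder of DICs into percent support:

```r
ref <- reference_model_table()
h <- ref[ref$family == "H", ]
round(dic_weights(h$DIC), 2)
#> [1]  0.00  0.00  0.00  0.01 13.59 86.40
```

The scripted analysis lives under `analysis/` (01 simulate database,
02 co-sampling dendrogram, 03 model ladder, 04 regional summaries and
cross-model correlations, 05 reference-table checks); each step writes
its tables under `results/`.

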