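#' Region-by-species presence matrix
#'
#' Binary matrix recording which species have been sampled in which
#' region (1 = at least one population). Regions with fewer than
#' `min_species` species sampled carry too little information for a
#' co-sampling comparison and are dropped (reported via the
#' `dropped_regions` attribute).
#'
#' @param ds a `diversity_dataset`.
#' @param min_species minimum species per retained region (default 5).
#' @return 0/1 matrix, rows = regions, columns = species, with attribute
#'   `dropped_regions`.
#' @export
presence_matrix <- function(ds, min_species = 5) {
  r <- ds$records
  pm <- table(r$region, r$species) > 0
  pm <- matrix(as.integer(pm), nrow(pm), ncol(pm), dimnames = dimnames(pm))
  keep <- rowSums(pm) >= min_species
  dropped <- rownames(pm)[!keep]
  pm <- pm[keep, , drop = FALSE]
  if (nrow(pm) < 2)
    stop("fewer than two regions with at least ", min_species,
         " species sampled")
  attr(pm, "dropped_regions") <- dropped
  pm
}

#' Ward minimum-variance clustering of regions
#'
#' Agglomerates the rows of a presence matrix by Ward's criterion:
#' pairwise Euclidean distances are squared before clustering and the
#' merge heights are square-rooted afterwards (the Murtagh-Legendre
#' recommendation for Ward on Euclidean input). Implemented directly via
#' the Lance-Williams update so ties in the merge criterion break
#' deterministically on the lowest row-index pair.
#'
#' @param pm a numeric matrix (rows are clustered), e.g. from
#'   [presence_matrix()].
#' @return An `hclust` object (merge heights square-rooted), with
#'   `labels` from `rownames(pm)`.
#' @export
ward_cluster <- function(pm) {
  n <- nrow(pm)
  if (is.null(n) || n < 2) stop("need at least two rows to cluster")
  labels <- rownames(pm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  d2 <- as.matrix(stats::dist(pm))^2

  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -seq_len(n)              # hclust coding: negative = singleton
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    act <- which(active)
    for (a in seq_along(act)[-length(act)]) {
      i <- act[a]
      for (j in act[(a + 1L):length(act)]) {
        if (d2[i, j] < best_d - 1e-12) {
          best_d <- d2[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    pair <- sort(c(id[i], id[j]))
    if (all(pair < 0)) pair <- rev(pair)   # two singletons: -small, -large
    merge[step, ] <- pair
    height[step] <- best_d
    # Lance-Williams Ward update onto slot i
    for (k in act) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((size[i] + size[k]) * d2[i, k] + (size[j] + size[k]) * d2[j, k] -
           size[k] * d2[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }

  hc <- structure(list(merge = merge, height = sqrt(pmax(height, 0)),
                       order = dendrogram_order(merge),
                       labels = labels, method = "ward",
                       dist.method = "euclidean (squared)",
                       call = match.call()),
                  class = "hclust")
  hc
}

# leaf order by left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` object, e.g. from [ward_cluster()].
#' @param path output file path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
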