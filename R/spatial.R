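#' Region adjacency graph
#'
#' Wraps a symmetric, nonnegative adjacency weight matrix over regions —
#' weights represent the extent of shared boundary between neighbouring
#' bioregions (binary adjacency is the simplest choice). The diagonal
#' must be zero. Regions with no positive weight to any other region are
#' recorded as `isolated`.
#'
#' @param W square numeric matrix of adjacency weights.
#' @param ids region identifiers; defaults to `rownames(W)` or `1..k`.
#' @return An object of class `region_graph`: list with `ids` and `W`
#'   (dimnames set to `ids`).
#' @export
region_graph <- function(W, ids = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (is.null(ids)) ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  ids <- as.character(ids)
  if (length(ids) != nrow(W)) stop("length(ids) must match nrow(W)")
  if (any(W < 0)) stop("adjacency weights must be nonnegative")
  if (any(abs(W - t(W)) > 1e-12)) stop("adjacency matrix must be symmetric")
  if (any(diag(W) != 0)) stop("adjacency matrix must have zero diagonal")
  dimnames(W) <- list(ids, ids)
  structure(list(ids = ids, W = W,
                 isolated = ids[rowSums(W) == 0]),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region graph:", length(x$ids), "regions,",
      sum(x$W > 0) / 2, "edges\n")
  invisible(x)
}

#' Chain adjacency fixture
#'
#' A path-graph adjacency over `k` regions (region i adjacent to i - 1
#' and i + 1), emulating a sequence of coastal bioregions ordered along
#' the coastline. Stands in for a boundary-sharing matrix that would
#' otherwise need GIS data.
#'
#' @param k number of regions (>= 2).
#' @param weights optional vector of `k - 1` edge weights (default all 1).
#' @param ids optional region identifiers.
#' @return A `region_graph`.
#' @export
chain_adjacency <- function(k, weights = NULL, ids = NULL) {
  stopifnot(k >= 2)
  if (is.null(weights)) weights <- rep(1, k - 1L)
  stopifnot(length(weights) == k - 1L)
  W <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) W[i, i + 1L] <- W[i + 1L, i] <- weights[i]
  region_graph(W, ids = ids)
}

#' Intrinsic CAR structure for a region graph
#'
#' Builds the intrinsic conditional-autoregression precision structure
#' `Q = D - W` (`D` the diagonal of row sums), used as the improper prior
#' for spatially smooth region effects: conditioned on its neighbours, a
#' region's effect is normal around their weighted mean with precision
#' `tau_R * sum_j w_ij`. Rows of `Q` sum to zero; `Q` is PSD with one
#' zero eigenvalue per connected component, so effects are identified by
#' a sum-to-zero constraint.
#'
#' @param graph a `region_graph`.
#' @param allow_isolated if `FALSE` (default) isolated regions are an
#'   error; if `TRUE` they are kept and receive an independent-normal
#'   fallback during sampling (their CAR row is empty).
#' @return An object of class `car_structure`: list with `ids`, `W`, `Q`,
#'   `components` (integer membership), `n_components`, and `rank`
#'   (`k - n_components`, the rank of `Q`).
#' @export
build_car <- function(graph, allow_isolated = FALSE) {
  stopifnot(inherits(graph, "region_graph"))
  if (length(graph$isolated) && !allow_isolated)
    stop("isolated region(s): ", paste(graph$isolated, collapse = ", "),
         " (set allow_isolated = TRUE for an independent-normal fallback)")
  W <- graph$W
  k <- nrow(W)
  Q <- diag(rowSums(W), k) - W
  dimnames(Q) <- dimnames(W)
  comp <- graph_components(W)
  structure(list(ids = graph$ids, W = W, Q = Q,
                 components = comp, n_components = max(comp),
                 rank = k - max(comp)),
            class = "car_structure")
}

graph_components <- function(W) {
  k <- nrow(W)
  comp <- integer(k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Draw region effects from the intrinsic CAR prior
#'
#' Samples from the intrinsic CAR distribution restricted to the
#' sum-to-zero subspace of each connected component, via the spectral
#' pseudo-inverse of `Q = D - W`. The draw is rescaled so that the
#' root-mean-square marginal standard deviation across regions equals
#' `sigma`, which makes the spatial scale easy to state when simulating.
#'
#' @param graph a `region_graph`.
#' @param sigma target root-mean-square marginal standard deviation.
#' @param n number of draws.
#' @return An `n` by `k` matrix of region effects (columns named by
#'   region id); each row sums to zero within every component.
#' @export
sample_car <- function(graph, sigma = 1, n = 1) {
  car <- build_car(graph, allow_isolated = TRUE)
  e <- eigen(car$Q, symmetric = TRUE)
  pos <- e$values > 1e-10
  if (!any(pos)) stop("CAR structure has no positive eigenvalues")
  V <- e$vectors[, pos, drop = FALSE]
  lam <- e$values[pos]
  k <- length(car$ids)
  # marginal covariance of the unscaled intrinsic draw
  Sigma0 <- V %*% (t(V) / lam)
  s0 <- sqrt(mean(diag(Sigma0)))
  z <- matrix(stats::rnorm(n * length(lam)), n, length(lam))
  draws <- z %*% (t(V) / sqrt(lam)) * (sigma / s0)
  colnames(draws) <- car$ids
  draws
}
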