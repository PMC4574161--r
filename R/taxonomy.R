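#' Build a taxonomic tree from Linnaean classifications
#'
#' Turns a table of (class, order, family, genus, species) paths into a
#' rooted tree whose tips are species and whose internal nodes are shared
#' ranks: the most recent common ancestor of two tips is their deepest
#' shared rank. Rank levels that do not split anything (a family holding
#' a single genus, say) are collapsed — they would change no MRCA and
#' hence no correlation.
#'
#' @param species_paths data.frame with columns `class`, `order`,
#'   `family`, `genus`, `species` (one row per species; duplicate rows are
#'   collapsed).
#' @return An object of class `taxonomy_tree`: list with `phy` (an
#'   [ape::read.tree()] style `phylo`, branch lengths unset until
#'   [grafen_heights()] is applied) and `species` (tip labels in input
#'   order of first appearance).
#' @export
build_taxonomy <- function(species_paths) {
  p <- unique(as.data.frame(species_paths, stringsAsFactors = FALSE)[rank_cols])
  if (!nrow(p)) stop("no species paths supplied")
  if (anyDuplicated(p$species))
    stop("species '", p$species[duplicated(p$species)][1],
         "' appears with more than one classification")
  for (col in rank_cols)
    if (any(is.na(p[[col]]) | !nzchar(p[[col]])))
      stop("empty taxonomic rank '", col, "'")
  for (i in seq_along(rank_cols)[-1]) {
    tab <- unique(p[c(rank_cols[i], rank_cols[i - 1L])])
    dup <- tab[[1]][duplicated(tab[[1]])]
    if (length(dup))
      stop("rank inconsistency: ", rank_cols[i], " '", dup[1],
           "' assigned to more than one ", rank_cols[i - 1L])
  }
  p$.tip <- newick_safe(p$species)

  if (nrow(p) == 1L) {
    phy <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          tip.label = p$.tip, Nnode = 1L,
                          edge.length = 1),
                     class = "phylo", order = "cladewise")
  } else {
    txt <- paste0(newick_clade(p, 1L), ";")
    phy <- ape::read.tree(text = txt)
  }
  structure(list(phy = phy, species = p$species), class = "taxonomy_tree")
}

newick_safe <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

# recursive Newick for one clade; unary rank levels are skipped
newick_clade <- function(p, depth) {
  if (nrow(p) == 1L) return(p$.tip)
  while (depth <= length(rank_cols) &&
         length(unique(p[[rank_cols[depth]]])) == 1L)
    depth <- depth + 1L
  groups <- split(p, p[[rank_cols[depth]]])
  parts <- vapply(groups, newick_clade, character(1), depth = depth + 1L)
  paste0("(", paste(parts, collapse = ","), ")")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy tree with", length(x$species), "species tips\n")
  invisible(x)
}

#' Assign Grafen branch lengths to a taxonomy tree
#'
#' Each internal node gets a raw height equal to its number of descendant
#' tips minus one; heights are rescaled so the root has height 1 and tips
#' height 0, then raised to the power `rho` (1 by default); branch
#' lengths are the differences between parent and child heights. The
#' result is an ultrametric depth-1 tree.
#'
#' @param tt a `taxonomy_tree` from [build_taxonomy()].
#' @param rho height exponent; 1 leaves Grafen heights untransformed.
#' @return The `taxonomy_tree` with branch lengths set.
#' @export
grafen_heights <- function(tt, rho = 1) {
  stopifnot(inherits(tt, "taxonomy_tree"), rho > 0)
  if (length(tt$species) > 1L)
    tt$phy <- ape::compute.brlen(tt$phy, method = "Grafen", power = rho)
  else
    tt$phy$edge.length <- 1
  tt
}

#' Node heights of an ultrametric taxonomy tree
#'
#' @param tt a `taxonomy_tree` with branch lengths (see
#'   [grafen_heights()]).
#' @return Numeric vector of heights (root = 1, tips = 0) for all nodes,
#'   tips first, in `phylo` node numbering.
#' @export
tree_heights <- function(tt) {
  stopifnot(!is.null(tt$phy$edge.length))
  depth <- ape::node.depth.edgelength(tt$phy)
  max(depth) - depth
}

#' Brownian-motion correlation matrix among species
#'
#' Under Brownian trait evolution on a depth-1 ultrametric tree, the
#' correlation between two tips is the depth of the path shared from the
#' root, i.e. `1 - height(MRCA)`. The matrix has unit diagonal, is
#' symmetric and positive semi-definite, and serves as the correlation of
#' the multivariate-normal prior on species effects.
#'
#' @param tt a `taxonomy_tree` with Grafen branch lengths.
#' @return Square correlation matrix with species names as dimnames, rows
#'   ordered alphabetically.
#' @export
brownian_correlation <- function(tt) {
  stopifnot(inherits(tt, "taxonomy_tree"))
  if (is.null(tt$phy$edge.length))
    stop("assign branch lengths first (grafen_heights)")
  if (length(tt$species) == 1L) {
    m <- matrix(1, 1, 1, dimnames = list(tt$species, tt$species))
    return(m)
  }
  v <- ape::vcv(tt$phy, corr = TRUE)
  key <- stats::setNames(tt$species, newick_safe(tt$species))
  dimnames(v) <- list(unname(key[rownames(v)]), unname(key[colnames(v)]))
  ord <- sort(rownames(v))
  v <- v[ord, ord, drop = FALSE]
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("species correlation matrix is not positive semi-definite ",
         "(min eigenvalue ", format(min(ev)), ")")
  v
}

#' Species correlation matrix for a dataset
#'
#' Convenience wrapper: builds the taxonomy from the dataset's species
#' classifications, assigns Grafen heights and returns the Brownian
#' correlation matrix ordered to match `ds$species`.
#'
#' @param ds a `diversity_dataset`.
#' @param rho Grafen height exponent, see [grafen_heights()].
#' @return Correlation matrix with rows/columns in `ds$species` order.
#' @export
taxonomy_correlation <- function(ds, rho = 1) {
  tt <- grafen_heights(build_taxonomy(ds$records[rank_cols]), rho = rho)
  v <- brownian_correlation(tt)
  v[ds$species, ds$species, drop = FALSE]
}

#' Export a taxonomy tree as Newick
#'
#' @param tt a `taxonomy_tree` (branch lengths written when present).
#' @param path output file path.
#' @export
write_taxonomy <- function(tt, path) {
  ape::write.tree(tt$phy, file = path)
  invisible(path)
}
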