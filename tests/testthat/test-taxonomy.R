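single_path <- function() {
  data.frame(class = "C", order = "O", family = "F", genus = "G",
             species = "G_sp1", stringsAsFactors = FALSE)
}

star_paths <- function() {
  data.frame(class = paste0("C", 1:4), order = paste0("O", 1:4),
             family = paste0("F", 1:4), genus = paste0("G", 1:4),
             species = paste0("sp", 1:4), stringsAsFactors = FALSE)
}

# four species, two sharing a genus, the others in their own classes
cherry_paths <- function() {
  data.frame(class = c("C1", "C1", "C2", "C3"),
             order = c("O1", "O1", "O2", "O3"),
             family = c("F1", "F1", "F2", "F3"),
             genus = c("G1", "G1", "G2", "G3"),
             species = c("sp1", "sp2", "sp3", "sp4"),
             stringsAsFactors = FALSE)
}

test_that("a single species gives a one-tip tree and unit correlation", {
  tt <- grafen_heights(build_taxonomy(single_path()))
  V <- brownian_correlation(tt)
  expect_equal(V, matrix(1, 1, 1, dimnames = list("G_sp1", "G_sp1")))
})

test_that("species with nothing in common form a star with identity correlation", {
  tt <- grafen_heights(build_taxonomy(star_paths()))
  h <- tree_heights(tt)
  expect_equal(unname(h[1:4]), rep(0, 4))          # tips
  expect_equal(max(h), 1)                          # root
  expect_equal(sort(unique(tt$phy$edge.length)), 1)
  V <- brownian_correlation(tt)
  expect_equal(unname(V), diag(4))
})

test_that("a two-species genus sits at Grafen height 1/3 with correlation 2/3", {
  tt <- grafen_heights(build_taxonomy(cherry_paths()))
  V <- brownian_correlation(tt)
  expect_equal(V["sp1", "sp2"], 2 / 3, tolerance = 1e-12)
  off <- V[upper.tri(V)]
  expect_equal(sort(off, decreasing = TRUE)[1], 2 / 3, tolerance = 1e-12)
  expect_equal(sum(off > 1e-12), 1)                # all other pairs 0
  # the genus node height is (2 - 1) / (4 - 1)
  h <- tree_heights(tt)
  expect_true(any(abs(h - 1 / 3) < 1e-12))
})

test_that("rho = 1 leaves the root at height 1 and rho reshapes interior heights", {
  tt1 <- grafen_heights(build_taxonomy(cherry_paths()), rho = 1)
  tt2 <- grafen_heights(build_taxonomy(cherry_paths()), rho = 2)
  expect_equal(max(tree_heights(tt1)), 1)
  expect_equal(max(tree_heights(tt2)), 1)
  expect_equal(brownian_correlation(tt2)["sp1", "sp2"], 1 - (1 / 3)^2,
               tolerance = 1e-12)
})

test_that("inconsistent ranks are rejected", {
  bad <- cherry_paths()
  bad$family[2] <- "F9"                            # same genus, two families
  expect_error(build_taxonomy(bad), "rank inconsistency")
})

test_that("correlations match the pairwise deepest-shared-rank oracle", {
  for (seed in 1:4) {
    paths <- random_paths(8, seed = seed)
    tt <- grafen_heights(build_taxonomy(paths))
    V <- brownian_correlation(tt)
    O <- taxonomy_corr_oracle(paths)
    ord <- rownames(V)
    expect_equal(V, O[ord, ord], tolerance = 1e-10)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) > -1e-10)
    expect_equal(unname(diag(V)), rep(1, nrow(V)))
  }
})

test_that("correlation is monotone in taxonomic closeness", {
  paths <- data.frame(
    class = c("C1", "C1", "C1", "C1", "C2"),
    order = c("O1", "O1", "O1", "O2", "O3"),
    family = c("F1", "F1", "F2", "F3", "F4"),
    genus = c("G1", "G1", "G2", "G3", "G4"),
    species = paste0("sp", 1:5), stringsAsFactors = FALSE)
  V <- brownian_correlation(grafen_heights(build_taxonomy(paths)))
  same_genus <- V["sp1", "sp2"]
  same_family <- V["sp1", "sp3"]   # deepest shared rank: family? no - order
  same_order <- V["sp1", "sp3"]
  same_class <- V["sp1", "sp4"]
  diff_class <- V["sp1", "sp5"]
  expect_true(same_genus >= same_order)
  expect_true(same_order >= same_class)
  expect_true(same_class >= diff_class)
  expect_equal(diff_class, 0)
})

test_that("taxonomy export writes readable Newick with depth-1 tips", {
  tt <- grafen_heights(build_taxonomy(cherry_paths()))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_taxonomy(tt, path)
  phy <- ape::read.tree(path)
  expect_equal(sort(phy$tip.label), sort(paste0("sp", 1:4)))
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(unname(depths), rep(1, 4))
})

test_that("dataset-level correlation aligns with the dataset species order", {
  sim <- small_sim()
  V <- taxonomy_correlation(sim$dataset)
  expect_equal(rownames(V), sim$dataset$species)
  expect_equal(unname(diag(V)), rep(1, length(sim$dataset$species)))
})
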