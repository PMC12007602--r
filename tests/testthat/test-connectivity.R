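# Edge thresholding, hierarchical clustering of connectivity patterns and
# afferent/efferent comparison.

planted_regions <- c("vmPFC", "rACC", "cACC", "latOFC1", "latOFC2",
                     "IFGpt", "AI", "RO", "IFJ")
planted_blocks <- list(1:3, 4:5, 6:7, 8:9)

test_that("edge thresholding keeps the inclusive boundary", {
  m <- matrix(0.1, 4, 4, dimnames = list(paste0("r", 1:4),
                                         paste0("r", 1:4)))
  m["r1", "r2"] <- 0.49
  m["r1", "r3"] <- 0.50
  m["r2", "r4"] <- 0.80
  m["r3", "r4"] <- 0.63
  diag(m) <- 1  # self-connections must be ignored
  cm <- connectivity_matrix(m, "afferent")
  edges <- threshold_edges(cm)
  expect_equal(nrow(edges), 3)
  expect_false(any(edges$source == edges$target))
  expect_true(any(edges$source == "r1" & edges$target == "r3"))
  expect_false(any(edges$source == "r1" & edges$target == "r2"))
  expect_true(all(edges$probability >= 0.5))

  strict <- threshold_edges(cm, strict_gt = TRUE)
  expect_equal(nrow(strict), 2)
  expect_false(any(strict$source == "r1" & strict$target == "r3"))
})

test_that("identical probability patterns merge first at height zero", {
  m <- matrix(c(0, 0.9, 0.2, 0.2,
                0.9, 0, 0.2, 0.2,
                0.2, 0.2, 0, 0.8,
                0.2, 0.2, 0.8, 0), 4, 4, byrow = TRUE,
              dimnames = list(paste0("r", 1:4), paste0("r", 1:4)))
  cm <- connectivity_matrix(m, "afferent")
  tree <- cluster_regions(cm)
  # rows r1/r2 are identical once mutual entries are masked, as are r3/r4
  expect_equal(tree$height[1], 0)
  first <- sort(-tree$merge[1, ])
  expect_true(identical(first, c(1L, 2L)) || identical(first, c(3L, 4L)))
})

test_that("a binary tree over R regions has R-1 merges", {
  cm <- simulate_connectivity(planted_regions, planted_blocks, seed = 40)
  tree <- cluster_regions(cm)
  expect_equal(nrow(tree$merge), 8)
  expect_equal(length(tree$height), 8)
  expect_true(all(diff(tree$height) >= -1e-12))
  expect_error(cluster_regions(
    connectivity_matrix(matrix(0.5, 1, 1, dimnames = list("a", "a")))),
    "at least 2")
})

test_that("planted two-block structure is recovered at the root split", {
  regions <- paste0("r", 1:8)
  blocks <- list(1:4, 5:8)
  planted <- block_membership(regions, blocks)
  for (s in 1:30) {
    cm <- simulate_connectivity(regions, blocks, p_within = 0.8,
                                p_between = 0.1, noise_sd = 0.02,
                                seed = 500 + s)
    part <- cut_regions(cluster_regions(cm), 2)
    expect_true(faceseeg:::same_partition(part, planted))
  }
})

test_that("clustering is invariant to region permutation", {
  cm <- simulate_connectivity(planted_regions, planted_blocks,
                              noise_sd = 0.02, seed = 41)
  part <- cut_regions(cluster_regions(cm), 4)
  set.seed(41)
  perm <- sample(9)
  m2 <- cm$prob[perm, perm]
  cm2 <- connectivity_matrix(m2, "afferent")
  part2 <- cut_regions(cluster_regions(cm2), 4)
  expect_true(faceseeg:::same_partition(part[cm2$regions], part2))
})

test_that("cluster trees export to readable Newick", {
  cm <- simulate_connectivity(planted_regions, planted_blocks, seed = 42)
  tree <- cluster_regions(cm)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, planted_regions)
  expect_equal(ape::Ntip(phy), 9)
})

test_that("identical afferent and efferent matrices agree perfectly", {
  cm <- simulate_connectivity(planted_regions, planted_blocks, seed = 43)
  eff <- connectivity_matrix(cm$prob, "efferent")
  cmp <- compare_directions(cm, eff)
  expect_equal(cmp$correlation, 1)
  expect_equal(cmp$edge_agreement, 1)
  expect_true(cmp$same_partition)
})

test_that("anti-correlated directions report correlation -1", {
  cm <- simulate_connectivity(planted_regions, planted_blocks, seed = 44)
  m2 <- 1 - cm$prob
  diag(m2) <- diag(cm$prob)
  eff <- connectivity_matrix(m2, "efferent")
  cmp <- compare_directions(cm, eff)
  expect_equal(cmp$correlation, -1)
})

test_that("independently noised copies keep the same k=4 partition", {
  hits <- 0
  for (s in 1:30) {
    aff <- simulate_connectivity(planted_regions, planted_blocks,
                                 noise_sd = 0.05, seed = 600 + s,
                                 direction = "afferent")
    eff <- simulate_connectivity(planted_regions, planted_blocks,
                                 noise_sd = 0.05, seed = 900 + s,
                                 direction = "efferent")
    hits <- hits + compare_directions(aff, eff)$same_partition
  }
  expect_gte(hits / 30, 0.95)

  cm <- simulate_connectivity(planted_regions, planted_blocks, seed = 45)
  other <- simulate_connectivity(rev(planted_regions),
                                 planted_blocks, seed = 45)
  expect_error(compare_directions(cm, other), "region order")
})
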