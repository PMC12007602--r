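# Geodesic distances, the logistic kernel and the continuous surface maps.

test_that("the logistic kernel has its closed-form values", {
  expect_equal(node_weight(7.5), 0.5)
  expect_equal(node_weight(5), 1 / (1 + exp(-5)))
  expect_equal(node_weight(5), 0.9933071, tolerance = 1e-6)
  expect_gt(node_weight(4), node_weight(9))
  # strictly decreasing over a fine grid
  d <- seq(0, 15, by = 0.1)
  expect_true(all(diff(node_weight(d)) < 0))
  expect_error(node_weight(-1), "non-negative")
})

test_that("geodesic distances match a brute-force all-paths oracle", {
  set.seed(21)
  # random planar mesh on 10 nodes via jittered grid triangulation
  mesh <- make_mesh("grid", 10, 2)
  jitter <- matrix(runif(length(mesh$node_positions), -0.3, 0.3),
                   ncol = 3)
  jitter[, 3] <- 0
  mesh$node_positions <- mesh$node_positions + jitter
  g <- mesh_graph(mesh)
  for (from in c(1, 4)) {
    d <- geodesic_distances(mesh, from, graph = g)
    for (to in c(2, 6, 9)) {
      expect_equal(unname(d[as.character(to)]),
                   brute_force_geodesic(mesh, from, to),
                   tolerance = 1e-10)
    }
  }
  expect_error(geodesic_distances(mesh, 99), "out of range")
})

test_that("disconnected components are absent from distance results", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
               c(100, 0, 0), c(101, 0, 0), c(100, 1, 0))
  mesh <- cortical_mesh(pos, rbind(c(1, 2, 3), c(4, 5, 6)))
  d <- geodesic_distances(mesh, 1)
  expect_setequal(names(d), c("1", "2", "3"))
})

test_that("neighbourhoods collect the radius disk with logistic weights", {
  mesh <- make_mesh("strip", 41, 1)
  nb <- build_neighbourhood(mesh, 21)
  expect_length(nb$members, 21)  # centre plus 10 nodes each side
  expect_setequal(nb$members, 11:31)
  ord <- order(nb$members)
  expect_equal(nb$weight[ord],
               node_weight(abs(-10:10)), tolerance = 1e-12)
  # symmetric geometry, symmetric weights
  w <- nb$weight[ord]
  expect_equal(w, rev(w))

  # isolated node: neighbourhood is itself at weight w(0)
  pos <- rbind(c(0, 0, 0), c(50, 0, 0), c(51, 0, 0), c(50, 1, 0))
  mesh2 <- cortical_mesh(pos, matrix(c(2, 3, 4), 1))
  nb2 <- build_neighbourhood(mesh2, 1)
  expect_equal(nb2$members, 1L)
  expect_equal(nb2$weight, node_weight(0))
})

test_that("map values equal a from-definition weighted recomputation", {
  cfg <- analysis_config()
  mesh <- make_mesh("strip", 60, 1)
  assignment <- tiled_strip_assignment(8)
  flags <- data.frame(lead_id = sprintf("L%d", 1:8),
                      responsive = c(FALSE, TRUE, FALSE, TRUE,
                                     FALSE, FALSE, TRUE, FALSE),
                      selective = c(FALSE, TRUE, FALSE, FALSE,
                                    FALSE, FALSE, FALSE, FALSE))
  maps <- lapply(c("density", "overall", "relative"), compute_map,
                 mesh = mesh, assignment = assignment, flags = flags,
                 config = cfg)
  names(maps) <- c("density", "overall", "relative")

  # oracle: explicit loops from the definitions, strip distances |i - j|
  node_lead <- rep(NA_integer_, 60)
  node_lead[assignment$node] <- rep(1:8, each = 7)
  w_of <- function(d) 1 / (1 + exp(2 * (d - 7.5)))
  for (j in c(1, 10, 18, 25, 33, 47, 60)) {
    members <- which(abs(seq_len(60) - j) <= 10)
    w <- w_of(abs(members - j))
    expl <- !is.na(node_lead[members])
    resp <- expl & flags$responsive[node_lead[members]] %in% TRUE
    sel <- expl & flags$selective[node_lead[members]] %in% TRUE
    expect_equal(maps$density$values[j],
                 (sum(w[expl]) / 7) / (pi * 1^2), tolerance = 1e-12)
    expect_equal(maps$overall$values[j],
                 100 * sum(w[resp]) / sum(w[expl]), tolerance = 1e-12)
    if (sum(w[resp]) > 0) {
      expect_equal(maps$relative$values[j],
                   100 * sum(w[sel]) / sum(w[resp]), tolerance = 1e-12)
    }
  }
})

test_that("a lone responsive lead among explored leads yields 100% overall", {
  cfg <- analysis_config()
  mesh <- make_mesh("strip", 20, 1)
  assignment <- tiled_strip_assignment(2)
  flags <- data.frame(lead_id = c("L1", "L2"),
                      responsive = c(TRUE, TRUE),
                      selective = c(FALSE, FALSE))
  map <- compute_map("overall", mesh, assignment, flags, cfg)
  expect_true(all(map$values[map$mask] == 100))
})

test_that("the 10% mask removes a ~8% node and keeps a ~12% node", {
  cfg <- analysis_config()
  mesh <- make_mesh("strip", 120, 0.5)
  assignment <- tiled_strip_assignment(17)
  flags <- data.frame(lead_id = sprintf("L%d", 1:17),
                      responsive = c(rep(FALSE, 7), TRUE, rep(FALSE, 9)),
                      selective = rep(FALSE, 17))
  map <- compute_map("overall", mesh, assignment, flags, cfg)
  expect_gt(map$values[37], 7.5)
  expect_lt(map$values[37], 9)
  expect_false(map$mask[37])
  expect_gt(map$values[38], 11)
  expect_lt(map$values[38], 12.5)
  expect_true(map$mask[38])
})

test_that("single isolated lead density is 1/pi leads per cm^2", {
  cfg <- analysis_config()
  # dense 7-node cluster well inside a 10-mm-radius empty plane
  mesh <- make_mesh("grid", 49, 0.5)
  pl <- make_leads(mesh, 1, seed = 2)
  flags <- data.frame(lead_id = pl$leads$lead_id,
                      responsive = TRUE, selective = FALSE)
  map <- compute_map("density", mesh, pl$assignment, flags, cfg)
  centre <- pl$assignment$node[1]
  expect_equal(map$values[centre], 1 / pi, tolerance = 0.02)
})

test_that("maps respect range, mask and consistency invariants", {
  cfg <- analysis_config()
  mesh <- make_mesh("grid", 100, 2)
  set.seed(22)
  pl <- make_leads(mesh, 10, seed = 22)
  resp <- runif(10) < 0.5
  sel <- resp & runif(10) < 0.5
  flags <- data.frame(lead_id = pl$leads$lead_id,
                      responsive = resp, selective = sel)
  for (kind in c("overall", "relative")) {
    map <- compute_map(kind, mesh, pl$assignment, flags, cfg)
    expect_true(all(map$values >= 0 & map$values <= 100))
    expect_true(all(map$values[map$mask] >= cfg$map_threshold_pct))
  }
  expect_error(compute_map("overall", mesh, pl$assignment,
                           data.frame(lead_id = pl$leads$lead_id,
                                      responsive = FALSE,
                                      selective = sel)),
               "inconsistent")
  expect_error(compute_map("bogus", mesh, pl$assignment, flags, cfg))
})

test_that("maps are invariant under lead relabelling", {
  cfg <- analysis_config()
  mesh <- make_mesh("grid", 64, 2)
  pl <- make_leads(mesh, 6, seed = 5)
  flags <- data.frame(lead_id = pl$leads$lead_id,
                      responsive = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                      selective = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  m1 <- compute_map("overall", mesh, pl$assignment, flags, cfg)
  relabel <- setNames(sprintf("Z%d", 6:1), pl$leads$lead_id)
  a2 <- pl$assignment; a2$lead_id <- relabel[a2$lead_id]
  f2 <- flags; f2$lead_id <- relabel[f2$lead_id]
  m2 <- compute_map("overall", mesh, a2, f2, cfg)
  expect_equal(m1$values, m2$values)
  expect_equal(m1$mask, m2$mask)
})

test_that("an all-unresponsive relative map warns and masks everything", {
  cfg <- analysis_config()
  mesh <- make_mesh("strip", 30, 1)
  assignment <- tiled_strip_assignment(3)
  flags <- data.frame(lead_id = sprintf("L%d", 1:3),
                      responsive = FALSE, selective = FALSE)
  expect_warning(map <- compute_map("relative", mesh, assignment, flags, cfg),
                 "fully masked")
  expect_false(any(map$mask))
})
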