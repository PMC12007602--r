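# Synthetic meshes, lead placements, epoched recordings and
# block-structured connectivity matrices.

test_that("strip meshes have exact chain geodesics", {
  mesh <- make_mesh("strip", 6, 1)
  d <- geodesic_distances(mesh, 1)
  expect_equal(unname(d[as.character(2:6)]), 1:5)
  # consecutive nodes sit one spacing apart everywhere
  for (i in 1:5) {
    expect_equal(unname(geodesic_distances(mesh, i)[as.character(i + 1)]), 1)
  }
})

test_that("sphere meshes are well connected", {
  mesh <- make_mesh("sphere", 40, 3)
  expect_gte(nrow(mesh$node_positions), 40)
  g <- mesh_graph(mesh)
  expect_true(all(igraph::degree(g) >= 3))
  expect_equal(igraph::count_components(g), 1)
})

test_that("generators are pure functions of parameters and seed", {
  m1 <- make_mesh("grid", 50, 1.5, seed = 9)
  m2 <- make_mesh("grid", 50, 1.5, seed = 9)
  expect_identical(m1, m2)

  pl1 <- make_leads(m1, 4, seed = 3)
  pl2 <- make_leads(m2, 4, seed = 3)
  expect_identical(pl1, pl2)

  ev <- list(smiling = evoked_spec(2, 250), neutral = NULL)
  r1 <- simulate_epochs(pl1, ev, noise_spec(1), 4, seed = 11)
  r2 <- simulate_epochs(pl2, ev, noise_spec(1), 4, seed = 11)
  expect_identical(r1$data, r2$data)

  c1 <- simulate_connectivity(paste0("r", 1:6), list(1:3, 4:6), seed = 5)
  c2 <- simulate_connectivity(paste0("r", 1:6), list(1:3, 4:6), seed = 5)
  expect_identical(c1$prob, c2$prob)
})

test_that("lead placement assigns disjoint blocks of 7 nearest nodes", {
  mesh <- make_mesh("grid", 20, 5)
  pl <- make_leads(mesh, 2, seed = 1)
  expect_equal(nrow(pl$assignment), 14)
  expect_equal(length(unique(pl$assignment$node)), 14)

  pl1 <- make_leads(mesh, 1, seed = 2)
  pos <- pl1$leads[1, c("x", "y", "z")]
  d2 <- colSums((t(mesh$node_positions) - as.numeric(pos))^2)
  nearest7 <- order(d2)[1:7]
  expect_setequal(pl1$assignment$node, nearest7)

  expect_error(make_leads(mesh, 5, seed = 1), "too many leads")
})

test_that("zero-amplitude simulations average to noise", {
  lead <- line_leads(1)
  ev <- list(smiling = evoked_spec(0, 300), neutral = NULL)
  rec <- simulate_epochs(lead, ev, noise_spec(1), 54, seed = 42)
  ierp <- compute_ierp(rec, 1, "smiling")
  se <- 1 / sqrt(54)
  # baseline-corrected mean stays within 3 SE of zero everywhere
  expect_lt(max(abs(ierp$waveform)), 3 * se * 1.3)
})

test_that("planted bumps peak at the planted latency", {
  lead <- line_leads(1)
  ev <- list(smiling = evoked_spec(5, 300, 100), neutral = NULL)
  for (s in 1:20) {
    rec <- simulate_epochs(lead, ev, noise_spec(1), 54, seed = 400 + s)
    ierp <- compute_ierp(rec, 1, "smiling")
    peak <- ierp$times[which.max(abs(ierp$waveform))]
    expect_lte(abs(peak - 300), 20)
  }
})

test_that("the baseline segment carries no evoked component", {
  lead <- line_leads(1)
  ev <- list(smiling = evoked_spec(50, 100, 200), neutral = NULL)
  rec <- simulate_epochs(lead, ev, noise_spec(0.001), 5, seed = 2)
  times <- epoch_times(rec)
  pre <- rec$data[1, 1, times < 0]
  expect_lt(max(abs(pre)), 0.01)
  # huge bump at t >= 0
  expect_gt(max(rec$data[1, 1, times >= 0]), 25)
})

test_that("out-of-window evoked latencies are rejected", {
  lead <- line_leads(1)
  expect_error(
    simulate_epochs(lead, list(smiling = evoked_spec(1, 800)),
                    noise_spec(1), 4),
    "outside the analysis window")
  expect_error(
    simulate_epochs(lead, list(smiling = evoked_spec(1, 300)),
                    noise_spec(1), 1),
    "at least 2 trials")
})

test_that("pink noise adds 1/f power at low frequencies", {
  set.seed(8)
  x <- replicate(30, faceseeg:::pink_noise(900))
  spec <- apply(x, 2, function(v) Mod(fft(v))^2)
  lowf <- mean(spec[2:10, ])
  highf <- mean(spec[301:450, ])
  expect_gt(lowf / highf, 5)
})

test_that("block connectivity matrices are exact without noise", {
  cm <- simulate_connectivity(paste0("r", 1:6), list(1:3, 4:6),
                              p_within = 0.8, p_between = 0.1,
                              noise_sd = 0, seed = 1)
  off <- cm$prob[row(cm$prob) != col(cm$prob)]
  expect_setequal(unique(off), c(0.8, 0.1))
  member <- block_membership(paste0("r", 1:6), list(1:3, 4:6))
  same_block <- outer(member, member, "==")
  expect_true(all(cm$prob[same_block] == 0.8))
  expect_true(all(cm$prob[!same_block] == 0.1))
})

test_that("noisy connectivity values stay clipped to [0,1]", {
  cm <- simulate_connectivity(paste0("r", 1:5), list(1:2, 3:5),
                              noise_sd = 50, seed = 3)
  expect_true(all(cm$prob >= 0 & cm$prob <= 1))
})

test_that("overlapping or incomplete block partitions are rejected", {
  expect_error(simulate_connectivity(paste0("r", 1:4),
                                     list(1:2, 2:4)), "overlap")
  expect_error(simulate_connectivity(paste0("r", 1:4),
                                     list(1:2)), "partition")
  expect_error(simulate_connectivity(paste0("r", 1:4), list(1:2, 3:4),
                                     p_within = 0.1, p_between = 0.8))
})
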