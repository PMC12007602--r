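# Condition-by-Time selectivity ANOVA, planned contrasts and peak
# latency classification.

# from-scratch split-plot sums of squares: conditions between trials,
# bins repeated within trials; balanced design
splitplot_F <- function(bm1, bm2) {
  nb <- ncol(bm1)
  y <- rbind(bm1, bm2)
  cond <- rep(1:2, c(nrow(bm1), nrow(bm2)))
  n <- nrow(y)
  n_by <- as.numeric(table(cond))
  grand <- mean(y)
  trial_means <- rowMeans(y)
  cond_means <- tapply(trial_means, cond, mean)
  bin_means_all <- colMeans(y)
  ss_cond <- nb * sum(n_by * (cond_means - grand)^2)
  ss_trial <- nb * sum((trial_means - cond_means[cond])^2)
  ss_bin <- n * sum((bin_means_all - grand)^2)
  cell <- rbind(colMeans(bm1), colMeans(bm2))
  dev <- cell - outer(as.vector(cond_means), rep(1, nb)) -
    outer(rep(1, 2), bin_means_all) + grand
  ss_int <- sum(n_by * dev^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_trial - ss_bin - ss_int
  df_cond <- 1; df_trial <- n - 2
  df_bin <- nb - 1; df_int <- nb - 1
  df_err <- (n - 2) * (nb - 1)
  list(F_condition = (ss_cond / df_cond) / (ss_trial / df_trial),
       F_time = (ss_bin / df_bin) / (ss_err / df_err),
       F_interaction = (ss_int / df_int) / (ss_err / df_err))
}

make_two_condition_recording <- function(gen_a, gen_b, n_trials = 54) {
  build_recording(c("smiling", "neutral"), n_trials, function(cond, tr)
    if (cond == "smiling") gen_a(tr) else gen_b(tr))
}

test_that("duplicated groups give zero interaction and no selectivity", {
  set.seed(10)
  trials <- matrix(rnorm(20 * 900), 20)
  k <- 0
  rec <- build_recording(c("smiling", "neutral"), 20, function(cond, tr) {
    k <<- k + 1
    trials[(k - 1) %% 20 + 1, ]
  })
  res <- test_selectivity(rec, 1, "smiling_vs_neutral")
  expect_equal(res$F_interaction, 0)
  expect_equal(res$F_condition, 0)
  expect_false(res$selective)
  expect_null(res$posthoc_bins)
  expect_null(res$peak_latency_ms)
})

test_that("a planted 5-sigma condition difference is selective", {
  times <- default_times()
  set.seed(11)
  rec <- make_two_condition_recording(
    function(tr) rnorm(900) + bump_waveform(times, 5, 300, 120),
    function(tr) rnorm(900))
  res <- test_selectivity(rec, 1, "smiling_vs_neutral")
  expect_true(res$selective)
  expect_lt(res$p_interaction, 0.05)
  # post-hoc bins light up around the bump (bins 13-17 cover 240-340 ms)
  expect_true(all(res$posthoc_bins[14:16]))
  expect_false(any(res$posthoc_bins[1:5]))
  expect_equal(res$peak_class_ms, 300L)
  expect_lte(abs(res$peak_latency_ms - 300), 20)
})

test_that("ANOVA F statistics match from-scratch sums of squares", {
  cfg3 <- analysis_config(n_time_bins = 3L, analysis_window = c(0, 60))
  set.seed(12)
  for (rep in 1:3) {
    rec <- make_two_condition_recording(
      function(tr) rnorm(900) + bump_waveform(default_times(), 1, 30, 40),
      function(tr) rnorm(900),
      n_trials = 6)
    res <- test_selectivity(rec, 1, "smiling_vs_neutral", cfg3)
    times <- default_times()
    x1 <- faceseeg:::baseline_correct(
      rec$data[1, rec$conditions == "smiling", ], times, cfg3)
    x2 <- faceseeg:::baseline_correct(
      rec$data[1, rec$conditions == "neutral", ], times, cfg3)
    oracle <- splitplot_F(faceseeg:::bin_means(x1, times, cfg3),
                          faceseeg:::bin_means(x2, times, cfg3))
    expect_equal(res$F_condition, oracle$F_condition, tolerance = 1e-8)
    expect_equal(res$F_time, oracle$F_time, tolerance = 1e-8)
    expect_equal(res$F_interaction, oracle$F_interaction, tolerance = 1e-8)
  }
})

test_that("the joint selectivity criterion is conservative under the null", {
  set.seed(13)
  hits <- 0
  n_leads <- 60
  for (l in seq_len(n_leads)) {
    rec <- make_two_condition_recording(function(tr) rnorm(900),
                                        function(tr) rnorm(900),
                                        n_trials = 20)
    res <- test_selectivity(rec, 1, "smiling_vs_neutral")
    hits <- hits + res$selective
  }
  # joint criterion (interaction AND a main effect) is rarer than alpha;
  # at 60 null leads even the plain alpha rate would give ~3 hits
  expect_lt(hits / n_leads, 0.05)
})

test_that("sphericity correction only shrinks within-trial significance", {
  times <- default_times()
  set.seed(14)
  rec <- make_two_condition_recording(
    function(tr) rnorm(900) + bump_waveform(times, 2, 300, 120),
    function(tr) rnorm(900), n_trials = 20)
  plain <- test_selectivity(rec, 1, "smiling_vs_neutral")
  gg <- test_selectivity(rec, 1, "smiling_vs_neutral",
                         sphericity_correction = TRUE)
  expect_gte(gg$p_interaction, plain$p_interaction)
  expect_gte(gg$p_time, plain$p_time)
  expect_equal(gg$p_condition, plain$p_condition)
})

test_that("peak latencies classify into half-open 100-ms classes", {
  times <- default_times()
  mk_ierp <- function(peak_ms, amp = 2) {
    structure(list(lead_id = "L01", condition = "smiling",
                   waveform = bump_waveform(times, amp, peak_ms, 60),
                   times = times, n_trials = 10),
              class = "ierp")
  }
  expect_equal(peak_latency(mk_ierp(320)),
               list(peak_latency_ms = 320, peak_class_ms = 300L))
  expect_equal(peak_latency(mk_ierp(150))$peak_class_ms, 200L)
  expect_equal(peak_latency(mk_ierp(149))$peak_class_ms, 100L)
  expect_equal(peak_latency(mk_ierp(30))$peak_class_ms, 100L)
  expect_equal(peak_latency(mk_ierp(580))$peak_class_ms, 500L)
  expect_equal(peak_latency(mk_ierp(449))$peak_class_ms, 400L)
  expect_equal(peak_latency(mk_ierp(450))$peak_class_ms, 500L)

  # negative deflections peak on |waveform|
  neg <- mk_ierp(250); neg$waveform <- -neg$waveform
  expect_equal(peak_latency(neg)$peak_latency_ms, 250)

  flat <- mk_ierp(300); flat$waveform <- rep(1, 900)
  expect_error(peak_latency(flat), "constant")
})

test_that("argmax ties resolve to the earliest sample", {
  times <- default_times()
  w <- rep(0, 900)
  w[times %in% c(200, 400)] <- 1
  ierp <- structure(list(lead_id = "L01", condition = "smiling",
                         waveform = w, times = times, n_trials = 5),
                    class = "ierp")
  expect_equal(peak_latency(ierp)$peak_latency_ms, 200)
})
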