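# Simulation-based calibration of the statistical criteria: null false-alarm
# rate of the run-length rule, detection power and latency-class recovery
# for planted responses, and planted-partition recovery of the clustering.

#' Null flag rate of the responsiveness criterion
#'
#' Simulates leads carrying pure white Gaussian noise (no evoked
#' component), applies the consecutive-bin responsiveness criterion to
#' each, and returns the flag rate together with the exact
#' independent-bin run-length probability ([runlength_null_prob()]) for
#' reference. Because all bins share each trial's baseline mean, the bin
#' statistics are weakly positively correlated, so the empirical rate can
#' sit slightly above the independent-bin value.
#'
#' @param n_leads number of simulated null leads.
#' @param n_trials trials per lead (default 54).
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @param sampling_rate Hz.
#' @param epoch_window epoch window, ms, half-open.
#' @return List: `rate`, `n_flagged`, `n_leads`, `oracle` (exact
#'   independent-bin probability of a qualifying run).
#' @export
responsiveness_null_rate <- function(n_leads, n_trials = 54L,
                                     config = NULL, seed = 1L,
                                     sampling_rate = 1000,
                                     epoch_window = c(-200, 700)) {
  config <- as_config(config)
  step <- 1000 / sampling_rate
  times <- seq(epoch_window[1], epoch_window[2] - step, by = step)
  set.seed(seed)
  flagged <- 0L
  for (l in seq_len(n_leads)) {
    x <- matrix(stats::rnorm(n_trials * length(times)),
                nrow = n_trials)
    p <- responsiveness_pvalues(x, times, config)
    if (max_run(p < config$alpha) >= config$min_consecutive_bins) {
      flagged <- flagged + 1L
    }
  }
  list(rate = flagged / n_leads,
       n_flagged = flagged,
       n_leads = n_leads,
       oracle = runlength_null_prob(config$n_time_bins, config$alpha,
                                    config$min_consecutive_bins))
}

#' Detection power and latency-class recovery for planted responses
#'
#' Each replicate simulates one lead: the emotional condition carries a
#' Gaussian-bump evoked response of amplitude `amplitude_sd` noise SDs at
#' a planted latency, the neutral condition carries noise only. The
#' replicate records whether the lead is flagged responsive
#' (emotional condition), whether the emotional-vs-neutral contrast is
#' selective, and whether the recovered peak-latency class matches the
#' planted class.
#'
#' @param n_seeds number of replicates.
#' @param amplitude_sd evoked amplitude in units of the noise SD.
#' @param latencies_ms pool of planted latencies, cycled over replicates.
#' @param width_ms bump FWHM in ms (spans several 20-ms bins).
#' @param n_trials trials per condition.
#' @param config an [analysis_config()].
#' @param seed integer base seed; replicate r uses `seed + r`.
#' @return data.frame per replicate: `planted_latency_ms`,
#'   `planted_class_ms`, `responsive`, `selective`, `recovered_class_ms`,
#'   `class_recovered`.
#' @export
planted_response_recovery <- function(n_seeds = 100L, amplitude_sd = 5,
                                      latencies_ms = c(100, 200, 300, 400, 500),
                                      width_ms = 100, n_trials = 54L,
                                      config = NULL, seed = 1000L) {
  config <- as_config(config)
  lead <- as_lead_set(data.frame(
    lead_id = "sim", x = 0, y = 0, z = 0,
    hemisphere = "L", grey_matter = TRUE, stringsAsFactors = FALSE))
  rows <- lapply(seq_len(n_seeds), function(r) {
    lat <- latencies_ms[(r - 1) %% length(latencies_ms) + 1]
    ev <- list(
      smiling = evoked_spec(amplitude_sd, lat, width_ms),
      neutral = NULL)
    rec <- simulate_epochs(lead, ev, noise_spec(1), n_trials,
                           config, seed = seed + r)
    resp <- detect_responsive(rec, "sim", "smiling", config)
    sel <- test_selectivity(rec, "sim", "smiling_vs_neutral", config)
    recovered <- if (sel$selective) sel$peak_class_ms else NA_integer_
    planted_class <- as.integer(min(max(100 * floor((lat + 50) / 100),
                                        100), 500))
    data.frame(planted_latency_ms = lat,
               planted_class_ms = planted_class,
               responsive = resp$responsive,
               selective = sel$selective,
               recovered_class_ms = recovered,
               class_recovered = isTRUE(recovered == planted_class))
  })
  do.call(rbind, rows)
}

#' Planted-partition recovery of the connectivity clustering
#'
#' Simulates block-structured connectivity matrices and asks whether
#' cutting the hierarchical cluster tree at the planted number of blocks
#' recovers the planted partition exactly (up to label permutation).
#'
#' @param n_seeds number of replicates.
#' @param regions region names.
#' @param blocks planted partition (list of vectors over `regions`).
#' @param p_within,p_between,noise_sd generator parameters
#'   (see [simulate_connectivity()]).
#' @param seed integer base seed.
#' @return List: `rate` (fraction recovered), `recovered` (logical per
#'   replicate).
#' @export
cluster_recovery_sim <- function(n_seeds = 100L, regions, blocks,
                                 p_within = 0.8, p_between = 0.1,
                                 noise_sd = 0.02, seed = 2000L) {
  planted <- block_membership(regions, blocks)
  recovered <- vapply(seq_len(n_seeds), function(r) {
    cm <- simulate_connectivity(regions, blocks, p_within, p_between,
                                noise_sd, seed = seed + r)
    part <- cut_regions(cluster_regions(cm), k = length(blocks))
    same_partition(part, planted)
  }, logical(1))
  list(rate = mean(recovered), recovered = recovered)
}
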