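# Per-lead evoked-potential computation and the consecutive-bin
# responsiveness criterion.

# internal: trials x samples matrix for one lead/condition
lead_trials <- function(rec, lead, condition = NULL) {
  stopifnot(inherits(rec, "epoched_recording"))
  li <- if (is.character(lead)) match(lead, rec$lead_ids) else as.integer(lead)
  if (is.na(li) || li < 1 || li > length(rec$lead_ids)) {
    stop("unknown lead: ", lead)
  }
  sel <- if (is.null(condition)) seq_along(rec$conditions) else
    which(rec$conditions == condition)
  if (length(sel) == 0) {
    stop("no trials of condition '", condition, "'")
  }
  m <- rec$data[li, sel, , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  list(x = m, lead_index = li, trials = sel)
}

baseline_columns <- function(times, config) {
  which(times >= config$baseline_window[1] & times < config$baseline_window[2])
}

# internal: subtract each trial's baseline mean; X is trials x samples
baseline_correct <- function(x, times, config) {
  bl <- baseline_columns(times, config)
  if (length(bl) == 0) stop("no samples fall in the baseline window")
  x - rowMeans(x[, bl, drop = FALSE])
}

#' Compute a lead's intracranial event-related potential (iERP)
#'
#' Subtractive baseline correction versus the pre-stimulus interval is
#' applied per trial (each trial's mean over the baseline window is
#' subtracted from that whole trial), then trials of the requested
#' condition are averaged.
#'
#' @param rec an `epoched_recording`.
#' @param lead lead id or index.
#' @param condition condition label; `NULL` averages all trials.
#' @param config an [analysis_config()].
#' @return A list of class `"ierp"`: `lead_id`, `condition`, `waveform`
#'   (one value per sample), `times` (ms) and `n_trials`.
#' @export
compute_ierp <- function(rec, lead, condition = NULL, config = NULL) {
  config <- as_config(config)
  lt <- lead_trials(rec, lead, condition)
  times <- epoch_times(rec)
  xc <- baseline_correct(lt$x, times, config)
  structure(list(
    lead_id = rec$lead_ids[lt$lead_index],
    condition = if (is.null(condition)) NA_character_ else condition,
    waveform = colMeans(xc),
    times = times,
    n_trials = nrow(xc)
  ), class = "ierp")
}

#' @export
print.ierp <- function(x, ...) {
  cat(sprintf("iERP %s / %s: %d trials, peak |amp| %.3g at %g ms\n",
              x$lead_id, x$condition, x$n_trials,
              max(abs(x$waveform)), x$times[which.max(abs(x$waveform))]))
  invisible(x)
}

# internal: per-trial bin means over the post-stimulus analysis window.
# Returns trials x n_time_bins matrix.
bin_means <- function(x, times, config) {
  edges <- config$analysis_window[1] + config$bin_ms * 0:config$n_time_bins
  out <- matrix(NA_real_, nrow(x), config$n_time_bins)
  for (b in seq_len(config$n_time_bins)) {
    cols <- which(times >= edges[b] & times < edges[b + 1])
    if (length(cols) == 0) stop("time bin ", b, " contains no samples")
    out[, b] <- rowMeans(x[, cols, drop = FALSE])
  }
  out
}

# internal: bin-wise p-values for one lead's trials x samples matrix.
# paired: one-sample t-test across trials of (bin mean - baseline mean);
# pooled: two-sample t-test of bin means vs baseline means across trials.
responsiveness_pvalues <- function(x, times, config,
                                   baseline_mode = c("paired", "pooled")) {
  baseline_mode <- match.arg(baseline_mode)
  bl <- baseline_columns(times, config)
  base <- rowMeans(x[, bl, drop = FALSE])
  bm <- bin_means(x, times, config)
  n <- nrow(x)
  if (baseline_mode == "paired") {
    d <- bm - base
    m <- colMeans(d)
    s <- sqrt(colSums((d - rep(m, each = n))^2) / (n - 1))
    tstat <- m / (s / sqrt(n))
    2 * stats::pt(-abs(tstat), df = n - 1)
  } else {
    vapply(seq_len(ncol(bm)), function(b)
      stats::t.test(bm[, b], base)$p.value, numeric(1))
  }
}

# internal: longest run of TRUE
max_run <- function(flags) {
  r <- rle(flags)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else max(runs)
}

#' Detect a responsive lead (consecutive-bin criterion)
#'
#' The post-stimulus window is divided into `n_time_bins` adjacent bins of
#' `bin_ms` ms. For each bin a two-sided t-test compares activity against
#' the pre-stimulus baseline across trials (default: paired per trial, the
#' difference between the trial's bin mean and its baseline mean; a pooled
#' variant compares the two samples unpaired). The lead is responsive iff
#' some run of at least `min_consecutive_bins` consecutive bins is
#' significant at `alpha` — a run-length rule that strongly suppresses the
#' per-bin false-positive rate (see [runlength_null_prob()]).
#'
#' @param rec an `epoched_recording`.
#' @param lead lead id or index.
#' @param condition condition label.
#' @param config an [analysis_config()].
#' @param baseline_mode `"paired"` (default) or `"pooled"`.
#' @return A list of class `"responsiveness_result"`: `lead_id`,
#'   `condition`, `bin_p_values`, `significant_bins`, `max_run_length`
#'   and `responsive`.
#' @export
detect_responsive <- function(rec, lead, condition, config = NULL,
                              baseline_mode = c("paired", "pooled")) {
  config <- as_config(config)
  baseline_mode <- match.arg(baseline_mode)
  lt <- lead_trials(rec, lead, condition)
  if (nrow(lt$x) < 2) stop("need at least 2 trials to test responsiveness")
  times <- epoch_times(rec)
  p <- responsiveness_pvalues(lt$x, times, config, baseline_mode)
  sig <- p < config$alpha
  run <- max_run(sig)
  structure(list(
    lead_id = rec$lead_ids[lt$lead_index],
    condition = condition,
    bin_p_values = p,
    significant_bins = sig,
    max_run_length = run,
    responsive = run >= config$min_consecutive_bins
  ), class = "responsiveness_result")
}

#' @export
print.responsiveness_result <- function(x, ...) {
  cat(sprintf("Responsiveness %s / %s: %sresponsive (longest run %d, %d/%d bins significant)\n",
              x$lead_id, x$condition, if (x$responsive) "" else "NOT ",
              x$max_run_length, sum(x$significant_bins),
              length(x$significant_bins)))
  invisible(x)
}

#' Exact null probability of the consecutive-bin criterion
#'
#' Probability that `n_bins` independent Bernoulli(`p`) bins contain at
#' least one run of `min_run` or more successes, computed by exact dynamic
#' programming over the trailing-run state. Serves as the analytic null
#' reference for the responsiveness flag rate under bin independence.
#'
#' @param n_bins number of bins.
#' @param p per-bin success probability.
#' @param min_run required run length.
#' @return The exact probability (scalar in `[0, 1]`).
#' @examples
#' runlength_null_prob(35, 0.05, 4)  # ~2e-4, far below the 5% per-bin rate
#' @export
runlength_null_prob <- function(n_bins, p, min_run) {
  stopifnot(n_bins >= 1, p >= 0, p <= 1, min_run >= 1)
  # state r = current trailing run length (0 .. min_run-1), no long run yet
  state <- c(1, rep(0, min_run - 1))
  hit <- 0
  for (i in seq_len(n_bins)) {
    new_state <- numeric(min_run)
    new_state[1] <- sum(state) * (1 - p)
    if (min_run > 1) new_state[2:min_run] <- state[1:(min_run - 1)] * p
    hit <- hit + state[min_run] * p
    state <- new_state
  }
  hit
}
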