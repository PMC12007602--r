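# Condition-by-Time selectivity testing and peak-latency classification.

contrast_conditions <- function(contrast) {
  switch(contrast,
         smiling_vs_neutral = c("smiling", "neutral"),
         fearful_vs_neutral = c("fearful", "neutral"),
         smiling_vs_fearful = c("smiling", "fearful"),
         stop("unknown contrast: ", contrast))
}

# Greenhouse-Geisser epsilon from the pooled within-cell covariance of the
# time bins (double-centred); optional sphericity correction.
gg_epsilon <- function(bm_by_cond) {
  k <- ncol(bm_by_cond[[1]])
  covs <- lapply(bm_by_cond, function(m) stats::cov(m))
  w <- vapply(bm_by_cond, nrow, numeric(1)) - 1
  s <- Reduce(`+`, Map(`*`, covs, w)) / sum(w)
  s <- sweep(sweep(s, 1, rowMeans(s)), 2, colMeans(s)) + mean(s)
  sum(diag(s))^2 / ((k - 1) * sum(s^2))
}

#' Test a lead's selectivity for an emotional contrast
#'
#' Fits a two-way ANOVA on per-trial time-bin means with factors Condition
#' (the two conditions of the contrast) and Time (`n_time_bins` adjacent
#' bins). Trials are the random unit: Condition varies between trials and
#' Time is repeated within each trial, a split-plot design fitted with
#' `aov` and an `Error(trial)` stratum. The lead is selective iff the
#' Condition-by-Time interaction is significant and at least one main
#' effect is significant at `alpha`. For selective leads, planned per-bin
#' contrasts (two-sample t-tests, uncorrected) compare the two conditions
#' bin by bin, and the peak latency of the first condition's iERP is
#' classified (see [peak_latency()]).
#'
#' Callers enforce the pipeline gating: selectivity is only evaluated on
#' leads already responsive in at least one emotional condition.
#'
#' @param rec an `epoched_recording`.
#' @param lead lead id or index.
#' @param contrast one of `"smiling_vs_neutral"`, `"fearful_vs_neutral"`,
#'   `"smiling_vs_fearful"`.
#' @param config an [analysis_config()].
#' @param sphericity_correction apply a Greenhouse-Geisser correction to
#'   the within-trial effects (default `FALSE`).
#' @return A list of class `"selectivity_result"` with the ANOVA F and p
#'   values (`p_interaction`, `p_condition`, `p_time`), the `selective`
#'   flag, `posthoc_bins` (logical per bin, `NULL` unless selective) and
#'   `peak_latency_ms`/`peak_class_ms` (`NULL` unless selective).
#' @export
test_selectivity <- function(rec, lead, contrast, config = NULL,
                             sphericity_correction = FALSE) {
  config <- as_config(config)
  conds <- contrast_conditions(contrast)
  times <- epoch_times(rec)
  bm_by_cond <- lapply(conds, function(cond) {
    lt <- lead_trials(rec, lead, cond)
    if (nrow(lt$x) < 2) stop("need at least 2 trials per condition")
    bin_means(baseline_correct(lt$x, times, config), times, config)
  })
  names(bm_by_cond) <- conds
  nb <- config$n_time_bins
  n_per <- vapply(bm_by_cond, nrow, integer(1))

  long <- data.frame(
    y = c(t(bm_by_cond[[1]]), t(bm_by_cond[[2]])),
    condition = factor(rep(conds, n_per * nb), levels = conds),
    bin = factor(rep(seq_len(nb), times = sum(n_per))),
    trial = factor(rep(seq_len(sum(n_per)), each = nb))
  )
  fit <- stats::aov(y ~ condition * bin + Error(trial), data = long)
  s <- summary(fit)
  between <- s[["Error: trial"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  p_cond <- between[trimws(rownames(between)) == "condition", "Pr(>F)"]
  f_cond <- between[trimws(rownames(between)) == "condition", "F value"]
  p_time <- within[rn == "bin", "Pr(>F)"]
  f_time <- within[rn == "bin", "F value"]
  p_int <- within[rn == "condition:bin", "Pr(>F)"]
  f_int <- within[rn == "condition:bin", "F value"]

  if (sphericity_correction) {
    eps <- gg_epsilon(bm_by_cond)
    df_t <- within[rn == "bin", "Df"]
    df_i <- within[rn == "condition:bin", "Df"]
    df_e <- within[rn == "Residuals", "Df"]
    p_time <- stats::pf(f_time, eps * df_t, eps * df_e, lower.tail = FALSE)
    p_int <- stats::pf(f_int, eps * df_i, eps * df_e, lower.tail = FALSE)
  }
  # identical groups give 0/0 F statistics; read them as no evidence
  if (is.na(p_int)) { p_int <- 1; f_int <- 0 }
  if (is.na(p_cond)) { p_cond <- 1; f_cond <- 0 }
  if (is.na(p_time)) { p_time <- 1; f_time <- 0 }

  selective <- (p_int < config$alpha) &&
    (min(p_cond, p_time) < config$alpha)

  posthoc <- NULL
  peak_ms <- NULL
  peak_class <- NULL
  if (selective) {
    posthoc <- vapply(seq_len(nb), function(b)
      stats::t.test(bm_by_cond[[1]][, b], bm_by_cond[[2]][, b],
                    var.equal = TRUE)$p.value < config$alpha,
      logical(1))
    pk <- peak_latency(compute_ierp(rec, lead, conds[1], config), config)
    peak_ms <- pk$peak_latency_ms
    peak_class <- pk$peak_class_ms
  }

  structure(list(
    lead_id = if (is.character(lead)) lead else rec$lead_ids[lead],
    contrast = contrast,
    F_condition = f_cond, p_condition = p_cond,
    F_time = f_time, p_time = p_time,
    F_interaction = f_int, p_interaction = p_int,
    selective = selective,
    posthoc_bins = posthoc,
    peak_latency_ms = peak_ms,
    peak_class_ms = peak_class
  ), class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("Selectivity %s / %s: %sselective (interaction p=%.3g, condition p=%.3g, time p=%.3g)\n",
              x$lead_id, x$contrast, if (x$selective) "" else "NOT ",
              x$p_interaction, x$p_condition, x$p_time))
  if (x$selective) {
    cat(sprintf("  peak %g ms (class %d ms), %d post-hoc bins significant\n",
                x$peak_latency_ms, x$peak_class_ms, sum(x$posthoc_bins)))
  }
  invisible(x)
}

#' Peak latency of an iERP and its 100-ms latency class
#'
#' The peak is the sample with maximal absolute amplitude in the
#' post-stimulus interval (polarity-free, since iERP polarity depends on
#' the reference; ties go to the earliest sample). The latency class is
#' the nearest of 100, 200, 300, 400, 500 ms with half-open bins
#' `[c - 50, c + 50)`: latencies below 50 ms fall in class 100 and
#' latencies of 550 ms or more in class 500.
#'
#' @param ierp an `"ierp"` object (see [compute_ierp()]).
#' @param config an [analysis_config()].
#' @return List with `peak_latency_ms` and `peak_class_ms`.
#' @export
peak_latency <- function(ierp, config = NULL) {
  config <- as_config(config)
  stopifnot(inherits(ierp, "ierp"))
  sel <- which(ierp$times > config$analysis_window[1] &
                 ierp$times <= config$analysis_window[2])
  w <- ierp$waveform[sel]
  if (max(w) == min(w)) {
    stop("waveform is constant over the analysis window; no peak defined")
  }
  peak_idx <- which.max(abs(w))  # earliest sample wins ties
  lat <- ierp$times[sel][peak_idx]
  cls <- 100 * floor((lat + 50) / 100)
  cls <- min(max(cls, 100), 500)
  list(peak_latency_ms = lat, peak_class_ms = as.integer(cls))
}
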