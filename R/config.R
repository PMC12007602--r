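#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' Defaults reproduce the study conditions: 20-ms bins over the 0--700 ms
#' post-stimulus window (35 bins), a run of at least four consecutive
#' significant bins for responsiveness, a 1-cm geodesic disk with a logistic
#' distance kernel (midpoint 7.5 mm, steepness 2 per mm, so nodes within
#' 5 mm are near-maximally weighted), seven mesh nodes per lead, 10%
#' display thresholds for the continuous maps and the regional selection
#' rule, and a 0.5 probability cut for connectivity edges.
#'
#' @param alpha significance level for all per-lead tests.
#' @param bin_ms width of a post-stimulus time bin, ms.
#' @param min_consecutive_bins run length of significant bins required to
#'   call a lead responsive.
#' @param baseline_window pre-stimulus interval `(start, end)` in ms used
#'   for subtractive baseline correction; half-open `[start, end)`.
#' @param analysis_window post-stimulus interval `(start, end)` in ms over
#'   which bins are laid out; half-open.
#' @param n_time_bins number of adjacent time bins; must satisfy
#'   `n_time_bins * bin_ms == diff(analysis_window)`.
#' @param map_radius_mm geodesic disk radius for the surface maps, mm.
#' @param kernel_midpoint_mm logistic kernel midpoint, mm (weight 0.5).
#' @param kernel_steepness logistic kernel steepness, per mm.
#' @param nodes_per_lead number of mesh nodes representing one lead.
#' @param map_threshold_pct mask threshold for overall/relative maps, percent.
#' @param region_min_pct minimum percentage of significant leads for a
#'   region to be selected.
#' @param region_min_leads minimum number of significant leads for a region
#'   to be selected.
#' @param conn_threshold connectivity-probability threshold for edge maps.
#' @param rng_seed integer seed recorded with the configuration.
#'
#' @return An object of class `"analysis_config"` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$n_time_bins
#' @export
analysis_config <- function(alpha = 0.05,
                            bin_ms = 20,
                            min_consecutive_bins = 4L,
                            baseline_window = c(-200, 0),
                            analysis_window = c(0, 700),
                            n_time_bins = 35L,
                            map_radius_mm = 10,
                            kernel_midpoint_mm = 7.5,
                            kernel_steepness = 2,
                            nodes_per_lead = 7L,
                            map_threshold_pct = 10,
                            region_min_pct = 10,
                            region_min_leads = 4L,
                            conn_threshold = 0.5,
                            rng_seed = 1L) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
    is.numeric(bin_ms), bin_ms > 0,
    min_consecutive_bins >= 1,
    length(baseline_window) == 2L, baseline_window[1] < baseline_window[2],
    baseline_window[2] <= 0,
    length(analysis_window) == 2L, analysis_window[1] >= 0,
    analysis_window[1] < analysis_window[2],
    map_radius_mm > 0, kernel_midpoint_mm > 0, kernel_steepness > 0,
    nodes_per_lead >= 1,
    map_threshold_pct >= 0, map_threshold_pct <= 100,
    region_min_pct >= 0, region_min_pct <= 100,
    region_min_leads >= 0,
    conn_threshold >= 0, conn_threshold <= 1
  )
  if (!isTRUE(all.equal(n_time_bins * bin_ms, diff(analysis_window)))) {
    stop("n_time_bins * bin_ms must equal the analysis window length (",
         diff(analysis_window), " ms), got ", n_time_bins * bin_ms)
  }
  structure(list(
    alpha = alpha,
    bin_ms = bin_ms,
    min_consecutive_bins = as.integer(min_consecutive_bins),
    baseline_window = as.numeric(baseline_window),
    analysis_window = as.numeric(analysis_window),
    n_time_bins = as.integer(n_time_bins),
    map_radius_mm = map_radius_mm,
    kernel_midpoint_mm = kernel_midpoint_mm,
    kernel_steepness = kernel_steepness,
    nodes_per_lead = as.integer(nodes_per_lead),
    map_threshold_pct = map_threshold_pct,
    region_min_pct = region_min_pct,
    region_min_leads = as.integer(region_min_leads),
    conn_threshold = conn_threshold,
    rng_seed = as.integer(rng_seed)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  alpha %.3g; %d x %g-ms bins over [%g, %g) ms; run >= %d\n",
              x$alpha, x$n_time_bins, x$bin_ms,
              x$analysis_window[1], x$analysis_window[2],
              x$min_consecutive_bins))
  cat(sprintf("  baseline [%g, %g) ms\n",
              x$baseline_window[1], x$baseline_window[2]))
  cat(sprintf("  map: radius %g mm, logistic(midpoint %g mm, steepness %g/mm), %d nodes/lead, mask < %g%%\n",
              x$map_radius_mm, x$kernel_midpoint_mm, x$kernel_steepness,
              x$nodes_per_lead, x$map_threshold_pct))
  cat(sprintf("  regions: >= %g%% on >= %d leads; connectivity cut %g\n",
              x$region_min_pct, x$region_min_leads, x$conn_threshold))
  invisible(x)
}

# internal: coerce/validate a config argument
as_config <- function(config) {
  if (is.null(config)) return(analysis_config())
  if (!inherits(config, "analysis_config")) {
    stop("config must be an analysis_config object")
  }
  config
}
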