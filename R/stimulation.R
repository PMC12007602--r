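# High-frequency electrical stimulation (HF-ES) outcome tabulation.

stim_categories <- c("sensorimotor", "interoceptive", "emotional",
                     "language", "unspecific_subjective", "unresponsive")
stim_districts <- c("face_mouth", "eye_neck", "hand_arm", "none")

#' Validate and normalise stimulation outcome records
#'
#' Categories come from the closed clinical vocabulary (case-insensitive):
#' sensorimotor, interoceptive, emotional, language, unspecific_subjective,
#' unresponsive. A body district (`face_mouth`, `eye_neck`, `hand_arm`) is
#' required for sensorimotor outcomes and must be absent (or `none`) for
#' every other category.
#'
#' @param records data.frame with columns `site_id`, `hemisphere`,
#'   `current_ma`, `category` and optionally `body_district`.
#' @return The validated data.frame with normalised lower-case categories
#'   and districts (`none` where not applicable).
#' @export
categorize_stimulation <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("site_id", "hemisphere", "current_ma", "category")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("stimulation records missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0) {
    records$body_district <- character(0)
    return(records)
  }
  if (!all(records$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'")
  }
  cur <- as.numeric(records$current_ma)
  if (any(is.na(cur)) || any(cur <= 0)) {
    stop("current_ma must be positive")
  }
  records$current_ma <- cur
  cat_norm <- tolower(trimws(records$category))
  bad <- setdiff(unique(cat_norm), stim_categories)
  if (length(bad) > 0) {
    stop("unknown stimulation category '", bad[1], "'; valid categories: ",
         paste(stim_categories, collapse = ", "))
  }
  records$category <- cat_norm
  if (!"body_district" %in% names(records)) {
    records$body_district <- NA_character_
  }
  dis <- tolower(trimws(as.character(records$body_district)))
  dis[is.na(records$body_district) | dis == ""] <- "none"
  bad <- setdiff(unique(dis), stim_districts)
  if (length(bad) > 0) {
    stop("unknown body district '", bad[1], "'; valid districts: ",
         paste(stim_districts, collapse = ", "))
  }
  needs <- records$category == "sensorimotor"
  if (any(needs & dis == "none")) {
    stop("sensorimotor records require a body district")
  }
  if (any(!needs & dis != "none")) {
    stop("body district is only valid for sensorimotor records")
  }
  records$body_district <- dis
  records
}

#' Tabulate stimulation outcomes
#'
#' Counts stimulated sites by outcome category and, within sensorimotor
#' outcomes, by body district, split by hemisphere. The headline
#' unresponsive percentage is derived as
#' `100 * (stimulated - responsive) / stimulated` (responsive = any
#' category other than `unresponsive`), rounded to the nearest integer
#' for display with the exact value retained.
#'
#' @param records validated records (see [categorize_stimulation()];
#'   unvalidated data.frames are validated first).
#' @return A list of class `"stimulation_summary"`: `by_category` and
#'   `by_district` data.frames (`L`, `R`, `total`), `n_stimulated`,
#'   `n_responsive`, `percent_unresponsive` (exact) and
#'   `percent_unresponsive_display`.
#' @export
tabulate_stimulation <- function(records) {
  records <- categorize_stimulation(records)
  count_lr <- function(rows, keys, levels) {
    do.call(rbind, lapply(levels, function(k) {
      i <- keys == k
      data.frame(L = sum(i & rows$hemisphere == "L"),
                 R = sum(i & rows$hemisphere == "R"),
                 total = sum(i), row.names = k)
    }))
  }
  by_category <- count_lr(records, records$category, stim_categories)
  sm <- records[records$category == "sensorimotor", , drop = FALSE]
  by_district <- count_lr(sm, sm$body_district,
                          setdiff(stim_districts, "none"))
  n_stim <- nrow(records)
  n_resp <- sum(records$category != "unresponsive")
  pct <- if (n_stim == 0) 0 else 100 * (n_stim - n_resp) / n_stim
  structure(list(by_category = by_category,
                 by_district = by_district,
                 n_stimulated = n_stim,
                 n_responsive = n_resp,
                 percent_unresponsive = pct,
                 percent_unresponsive_display = round_half_away(pct)),
            class = "stimulation_summary")
}

#' @export
print.stimulation_summary <- function(x, ...) {
  cat(sprintf("HF-ES summary: %d stimulated sites, %d responsive, %d%% unresponsive\n",
              x$n_stimulated, x$n_responsive,
              x$percent_unresponsive_display))
  cat("By category (L / R / total):\n")
  print(x$by_category)
  if (sum(x$by_district$total) > 0) {
    cat("Sensorimotor body districts (L / R / total):\n")
    print(x$by_district)
  }
  invisible(x)
}

#' Expand per-stratum counts into stimulation records
#'
#' Convenience generator: builds one record per site from counts per
#' (category, hemisphere, body district) stratum, e.g. to reconstruct a
#' published counting scheme as an input table.
#'
#' @param counts data.frame with columns `category`, `hemisphere`, `n`
#'   and optionally `body_district` and `current_ma` (default 3 mA).
#' @return A validated records data.frame.
#' @export
expand_stimulation_counts <- function(counts) {
  stopifnot(all(c("category", "hemisphere", "n") %in% names(counts)))
  if (!"body_district" %in% names(counts)) {
    counts$body_district <- NA_character_
  }
  if (!"current_ma" %in% names(counts)) counts$current_ma <- 3
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), , drop = FALSE]
  records <- data.frame(
    site_id = sprintf("site%04d", seq_len(nrow(rows))),
    hemisphere = rows$hemisphere,
    current_ma = rows$current_ma,
    category = rows$category,
    body_district = rows$body_district,
    stringsAsFactors = FALSE)
  categorize_stimulation(records)
}
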