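# Parcellation-level regional summaries and lateralization tests.

#' Assign parcellation regions to leads
#'
#' Each lead is labelled by the majority region among the labels of its
#' assigned mesh nodes; ties are broken by the region of the node nearest
#' to the lead position (Euclidean). Leads with no labelled node get `NA`
#' and drop out of regional summaries while still contributing to
#' lead-level statistics and surface maps.
#'
#' @param leads a `lead_set`.
#' @param mesh the `cortical_mesh` the assignment refers to.
#' @param assignment data.frame `lead_id`, `node`.
#' @param parc a `parcellation` for the mesh.
#' @return The `lead_set` with a `region` column added/overwritten.
#' @export
assign_regions <- function(leads, mesh, assignment, parc) {
  stopifnot(inherits(leads, "lead_set"), inherits(mesh, "cortical_mesh"),
            inherits(parc, "parcellation"))
  region <- rep(NA_character_, nrow(leads))
  for (k in seq_len(nrow(leads))) {
    nodes <- assignment$node[assignment$lead_id == leads$lead_id[k]]
    labs <- parc$node_labels[nodes]
    labs_ok <- labs[!is.na(labs)]
    if (length(labs_ok) == 0) next
    counts <- table(labs_ok)
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) == 1) {
      region[k] <- winners
    } else {
      # tie: region of the labelled node nearest to the lead position
      pos <- as.numeric(leads[k, c("x", "y", "z")])
      cand <- nodes[!is.na(labs) & labs %in% winners]
      d2 <- colSums((t(mesh$node_positions[cand, , drop = FALSE]) - pos)^2)
      region[k] <- parc$node_labels[cand[which.min(d2)]]
    }
  }
  leads$region <- region
  leads
}

#' Regional summary of significant leads
#'
#' For each (region, hemisphere) with at least one labelled lead, counts
#' explored leads and leads flagged significant, the exact percentage, a
#' display percentage rounded half-away-from-zero to integer, and the
#' selection flag: a region is selected iff the significant leads are at
#' least `region_min_pct` percent of its recording leads *and* number at
#' least `region_min_leads`.
#'
#' @param leads a `lead_set` with a `region` column (see
#'   [assign_regions()]); unlabelled leads are dropped.
#' @param significant logical vector named by `lead_id`, or a data.frame
#'   with columns `lead_id` and `significant`.
#' @param config an [analysis_config()].
#' @return data.frame `region`, `hemisphere`, `n_leads`, `n_significant`,
#'   `percent`, `percent_display`, `selected`, one row per
#'   region-hemisphere, left/right summarised separately.
#' @export
regional_summary <- function(leads, significant, config = NULL) {
  config <- as_config(config)
  stopifnot(inherits(leads, "lead_set"), "region" %in% names(leads))
  if (is.data.frame(significant)) {
    significant <- stats::setNames(as.logical(significant$significant),
                                   significant$lead_id)
  }
  labelled <- leads[!is.na(leads$region), , drop = FALSE]
  miss <- setdiff(labelled$lead_id, names(significant))
  if (length(miss) > 0) {
    stop("significance flag missing for lead(s): ",
         paste(miss, collapse = ", "))
  }
  sig <- significant[labelled$lead_id]
  key <- interaction(labelled$region, labelled$hemisphere, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    i <- which(key == k)
    n <- length(i)
    ns <- sum(sig[i])
    pct <- 100 * ns / n
    data.frame(region = labelled$region[i[1]],
               hemisphere = labelled$hemisphere[i[1]],
               n_leads = n, n_significant = ns,
               percent = pct,
               percent_display = round_half_away(pct),
               selected = pct >= config$region_min_pct &&
                 ns >= config$region_min_leads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$region, out$hemisphere), , drop = FALSE]
}

# round half away from zero to integer (Table-style display rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Chi-squared lateralization test
#'
#' Tests whether the proportion of significant leads differs between
#' hemispheres, on the 2x2 table of (significant, non-significant) counts
#' per hemisphere. Yates continuity correction is off by default.
#'
#' @param left `(n_significant, n_total)` for the left hemisphere.
#' @param right `(n_significant, n_total)` for the right hemisphere.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return A list of class `"lateralization_test"`: `contingency` (2x2),
#'   `chi2`, `p`.
#' @examples
#' chi2_lateralization(c(75, 176), c(84, 252))  # chi2 ~ 3.82, p ~ 0.051
#' @export
chi2_lateralization <- function(left, right, correct = FALSE) {
  stopifnot(length(left) == 2L, length(right) == 2L,
            left[1] >= 0, right[1] >= 0,
            left[2] >= left[1], right[2] >= right[1],
            left[2] > 0, right[2] > 0)
  tab <- rbind(L = c(sig = left[1], nonsig = left[2] - left[1]),
               R = c(sig = right[1], nonsig = right[2] - right[1]))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("an expected cell count is zero; use an exact test instead")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(contingency = tab,
                 chi2 = unname(ct$statistic),
                 p = ct$p.value,
                 correct = correct),
            class = "lateralization_test")
}

#' @export
print.lateralization_test <- function(x, ...) {
  cat(sprintf("Lateralization: chi2 = %.4g, p = %.4g (L %d/%d vs R %d/%d)%s\n",
              x$chi2, x$p,
              x$contingency[1, 1], sum(x$contingency[1, ]),
              x$contingency[2, 1], sum(x$contingency[2, ]),
              if (x$correct) " [Yates-corrected]" else ""))
  invisible(x)
}
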