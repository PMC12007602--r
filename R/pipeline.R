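# Lead-level analysis chain: responsiveness per emotional condition,
# gated selectivity testing, peak classification.

#' Run the per-lead statistical chain on a recording
#'
#' For every grey-matter lead: (1) the consecutive-bin responsiveness
#' criterion is evaluated for the smiling and fearful conditions;
#' (2) leads responsive in at least one emotional condition — and only
#' those — are tested for selectivity with the Condition-by-Time ANOVA
#' against neutral (both emotional contrasts) and for the
#' smiling-vs-fearful contrast; (3) selective leads get a peak latency
#' and its 100-ms class. This ordering guarantees the pipeline invariant
#' that selective leads are a subset of responsive leads.
#'
#' @param rec an `epoched_recording`.
#' @param leads optional `lead_set` (defaults to all leads in `rec`,
#'   treated as grey matter); white-matter leads are skipped.
#' @param config an [analysis_config()].
#' @param contrasts which contrasts to evaluate on responsive leads.
#' @return data.frame, one row per lead: responsiveness flags per
#'   condition, per-contrast selectivity flags and p-values, peak fields
#'   (NA where not evaluated).
#' @export
analyze_leads <- function(rec, leads = NULL, config = NULL,
                          contrasts = c("smiling_vs_neutral",
                                        "fearful_vs_neutral")) {
  config <- as_config(config)
  stopifnot(inherits(rec, "epoched_recording"))
  ids <- rec$lead_ids
  if (!is.null(leads)) {
    stopifnot(inherits(leads, "lead_set"))
    ids <- intersect(ids, grey_matter_leads(leads)$lead_id)
  }
  rows <- lapply(ids, function(id) {
    resp_s <- detect_responsive(rec, id, "smiling", config)
    resp_f <- detect_responsive(rec, id, "fearful", config)
    responsive_any <- resp_s$responsive || resp_f$responsive
    row <- data.frame(lead_id = id,
                      responsive_smiling = resp_s$responsive,
                      responsive_fearful = resp_f$responsive,
                      responsive_any = responsive_any,
                      stringsAsFactors = FALSE)
    for (ct in contrasts) {
      sel_col <- paste0("selective_", ct)
      p_col <- paste0("p_interaction_", ct)
      peak_col <- paste0("peak_ms_", ct)
      class_col <- paste0("peak_class_", ct)
      if (responsive_any) {
        res <- test_selectivity(rec, id, ct, config)
        row[[sel_col]] <- res$selective
        row[[p_col]] <- res$p_interaction
        row[[peak_col]] <- if (res$selective) res$peak_latency_ms else NA_real_
        row[[class_col]] <- if (res$selective) res$peak_class_ms else NA_integer_
      } else {
        row[[sel_col]] <- FALSE
        row[[p_col]] <- NA_real_
        row[[peak_col]] <- NA_real_
        row[[class_col]] <- NA_integer_
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  sel_cols <- grep("^selective_", names(out), value = TRUE)
  out$selective_any <- if (length(sel_cols) > 0) {
    Reduce(`|`, out[sel_cols])
  } else FALSE
  out
}

#' Per-lead map flags from an analysis table
#'
#' Collapses an [analyze_leads()] table to the three flags the surface
#' maps consume: explored (every analysed lead), responsive (in at least
#' one emotional condition) and selective (in the requested contrast, or
#' any).
#'
#' @param analysis data.frame from [analyze_leads()].
#' @param contrast contrast whose selectivity feeds the relative map, or
#'   `"any"`.
#' @return data.frame `lead_id`, `responsive`, `selective`.
#' @export
map_flags <- function(analysis, contrast = "any") {
  sel <- if (identical(contrast, "any")) {
    analysis$selective_any
  } else {
    col <- paste0("selective_", contrast)
    if (!col %in% names(analysis)) stop("no column ", col)
    analysis[[col]]
  }
  data.frame(lead_id = analysis$lead_id,
             responsive = analysis$responsive_any,
             selective = sel & analysis$responsive_any,
             stringsAsFactors = FALSE)
}
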