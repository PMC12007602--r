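# Continuous cortical surface maps: sampling density, overall
# responsiveness, relative responsiveness.

#' Validate and normalise per-lead significance flags
#'
#' @param flags data.frame with columns `lead_id`, `responsive`,
#'   `selective` (logical). Every lead in `flags` is treated as explored.
#' @return The validated data.frame.
#' @keywords internal
validate_flags <- function(flags) {
  stopifnot(is.data.frame(flags),
            all(c("lead_id", "responsive", "selective") %in% names(flags)))
  if (any(flags$selective & !flags$responsive)) {
    stop("inconsistent flags: a selective lead must be responsive")
  }
  flags
}

#' Continuous cortical surface map
#'
#' For every mesh node, the weighted geodesic disk of
#' [build_neighbourhood()] aggregates the mesh nodes assigned to leads
#' (a fixed `nodes_per_lead`, default 7, nodes represent each lead):
#'
#' * `density` — explored-lead density in leads/cm^2: the kernel-weighted
#'   count of explored member nodes divided by `nodes_per_lead`, over the
#'   nominal disk area `pi * (radius/10)^2` cm^2.
#' * `overall` — responsive nodes as a percentage of explored nodes within
#'   the disk (kernel-weighted); equivalently responsive leads as a
#'   percentage of explored leads. Masked below `map_threshold_pct`.
#' * `relative` — selective nodes as a percentage of responsive nodes
#'   within the disk (kernel-weighted), the topography of emotional
#'   selectivity among responding sites. Masked below `map_threshold_pct`.
#'
#' Nodes whose disk contains no explored (for `relative`: no responsive)
#' weight are masked.
#'
#' @param kind `"density"`, `"overall"` or `"relative"`.
#' @param mesh a `cortical_mesh`.
#' @param assignment data.frame `lead_id`, `node`: the nodes representing
#'   each lead (e.g. from [make_leads()]).
#' @param flags data.frame `lead_id`, `responsive`, `selective`; all its
#'   leads count as explored, and `selective` implies `responsive`.
#' @param config an [analysis_config()].
#' @return A list of class `"surface_map"`: `kind`, `values` (per node;
#'   leads/cm^2 for density, percent otherwise), `mask` (TRUE =
#'   displayable).
#' @export
compute_map <- function(kind = c("density", "overall", "relative"),
                        mesh, assignment, flags, config = NULL) {
  kind <- match.arg(kind)
  config <- as_config(config)
  stopifnot(inherits(mesh, "cortical_mesh"))
  flags <- validate_flags(flags)
  n <- nrow(mesh$node_positions)
  unknown <- setdiff(assignment$lead_id, flags$lead_id)
  if (length(unknown) > 0) {
    stop("assignment refers to lead(s) without flags: ",
         paste(unknown, collapse = ", "))
  }

  node_lead <- rep(NA_character_, n)
  node_lead[assignment$node] <- assignment$lead_id
  fl <- flags[match(node_lead, flags$lead_id), ]
  node_explored <- !is.na(node_lead)
  node_responsive <- node_explored & fl$responsive %in% TRUE
  node_selective <- node_explored & fl$selective %in% TRUE

  if (kind == "relative" && !any(node_responsive)) {
    warning("no responsive lead anywhere: relative map is fully masked")
  }

  g <- mesh_graph(mesh)
  dmat <- igraph::distances(g, algorithm = "dijkstra")
  values <- numeric(n)
  mask <- logical(n)
  disk_area_cm2 <- pi * (config$map_radius_mm / 10)^2

  for (j in seq_len(n)) {
    within <- which(is.finite(dmat[j, ]) & dmat[j, ] <= config$map_radius_mm)
    w <- node_weight(dmat[j, within], config)
    w_expl <- sum(w[node_explored[within]])
    w_resp <- sum(w[node_responsive[within]])
    w_sel <- sum(w[node_selective[within]])
    if (kind == "density") {
      values[j] <- (w_expl / config$nodes_per_lead) / disk_area_cm2
      mask[j] <- w_expl > 0
    } else if (kind == "overall") {
      if (w_expl > 0) {
        values[j] <- 100 * (w_resp / w_expl)
        mask[j] <- values[j] >= config$map_threshold_pct
      }
    } else {
      if (w_resp > 0) {
        values[j] <- 100 * (w_sel / w_resp)
        mask[j] <- values[j] >= config$map_threshold_pct
      }
    }
  }
  structure(list(kind = kind, values = values, mask = mask,
                 radius_mm = config$map_radius_mm,
                 threshold_pct = config$map_threshold_pct),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  unit <- if (x$kind == "density") "leads/cm^2" else "%"
  vals <- x$values[x$mask]
  cat(sprintf("Surface map (%s): %d/%d nodes displayable", x$kind,
              sum(x$mask), length(x$mask)))
  if (length(vals) > 0) {
    cat(sprintf(", range %.3g-%.3g %s", min(vals), max(vals), unit))
  }
  cat("\n")
  invisible(x)
}
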