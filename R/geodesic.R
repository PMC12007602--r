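# Geodesic structure of the cortical mesh and the logistic distance kernel.

#' Edge graph of a mesh
#'
#' Builds the undirected graph whose vertices are mesh nodes and whose
#' edges are triangle sides, weighted by Euclidean length. Geodesic
#' distances are shortest paths on this graph (a slight overestimate of
#' exact polyhedral geodesics that the distance kernel renders immaterial).
#'
#' @param mesh a `cortical_mesh`.
#' @return An `igraph` graph with an `weight` edge attribute in mm.
#' @export
mesh_graph <- function(mesh) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$node_positions) -
                                     igraph::vcount(g)))
  w <- sqrt(rowSums((mesh$node_positions[e[, 1], , drop = FALSE] -
                       mesh$node_positions[e[, 2], , drop = FALSE])^2))
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distances from a source node
#'
#' Shortest-path distance along mesh edges from `source_node` to every
#' node reachable within `max_mm`; unreachable nodes and nodes farther
#' than `max_mm` are absent from the result.
#'
#' @param mesh a `cortical_mesh` (or a prebuilt [mesh_graph()] via the
#'   `graph` argument for repeated queries).
#' @param source_node 1-based node index.
#' @param max_mm truncation radius in mm (`Inf` for no truncation).
#' @param graph optional precomputed `mesh_graph(mesh)`.
#' @return Named numeric vector: distance in mm per reachable node index.
#' @export
geodesic_distances <- function(mesh, source_node, max_mm = Inf,
                               graph = NULL) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  n <- nrow(mesh$node_positions)
  if (source_node < 1 || source_node > n) {
    stop("source node ", source_node, " out of range 1..", n)
  }
  if (is.null(graph)) graph <- mesh_graph(mesh)
  d <- as.vector(igraph::distances(graph, v = source_node,
                                   algorithm = "dijkstra"))
  keep <- which(is.finite(d) & d <= max_mm)
  stats::setNames(d[keep], keep)
}

#' Logistic distance weight
#'
#' `w(d) = 1 / (1 + exp(steepness * (d - midpoint)))`: unit amplitude,
#' weight 0.5 at the midpoint (7.5 mm by default), strictly decreasing.
#' Nodes within 5 mm are near-maximally weighted while weights between
#' 5 and 10 mm fall off gradually, avoiding edge effects at the disk rim.
#'
#' @param d_mm geodesic distance(s) in mm, >= 0.
#' @param config an [analysis_config()] supplying midpoint and steepness.
#' @return Weight(s) in `(0, 1)`.
#' @examples
#' node_weight(7.5)  # exactly 0.5
#' @export
node_weight <- function(d_mm, config = NULL) {
  config <- as_config(config)
  if (any(d_mm < 0)) stop("distance must be non-negative")
  1 / (1 + exp(config$kernel_steepness * (d_mm - config$kernel_midpoint_mm)))
}

#' Weighted geodesic neighbourhood of a node
#'
#' Member nodes are those within `map_radius_mm` geodesic distance of the
#' centre; each member carries the logistic kernel weight of its distance.
#' An isolated node's neighbourhood is itself with weight `w(0)`.
#'
#' @param mesh a `cortical_mesh`.
#' @param node centre node index.
#' @param config an [analysis_config()].
#' @param graph optional precomputed [mesh_graph()].
#' @return A list of class `"node_neighbourhood"`: `centre`, `members`
#'   (node indices), `distance_mm` and `weight`.
#' @export
build_neighbourhood <- function(mesh, node, config = NULL, graph = NULL) {
  config <- as_config(config)
  d <- geodesic_distances(mesh, node, max_mm = config$map_radius_mm,
                          graph = graph)
  structure(list(
    centre = node,
    members = as.integer(names(d)),
    distance_mm = unname(d),
    weight = unname(node_weight(d, config))
  ), class = "node_neighbourhood")
}
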