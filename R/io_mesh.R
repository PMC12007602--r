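#' Cortical surface mesh
#'
#' A triangulated surface: node positions in millimetres and triangles as
#' 1-based node index triples. An optional per-node hemisphere label is
#' carried along for lead bookkeeping.
#'
#' @param node_positions numeric `N x 3` matrix, mm.
#' @param triangles integer `M x 3` matrix of 1-based node indices.
#' @param hemisphere optional character vector of `"L"`/`"R"`, length `N`;
#'   defaults to `"L"` for x < 0, else `"R"`.
#' @return An object of class `"cortical_mesh"`.
#' @export
cortical_mesh <- function(node_positions, triangles, hemisphere = NULL) {
  node_positions <- as.matrix(node_positions)
  stopifnot(ncol(node_positions) == 3L, all(is.finite(node_positions)))
  n <- nrow(node_positions)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > n)) {
    stop("triangle node index out of range (mesh has ", n, " nodes)")
  }
  if (is.null(hemisphere)) {
    hemisphere <- ifelse(node_positions[, 1] < 0, "L", "R")
  }
  stopifnot(length(hemisphere) == n, all(hemisphere %in% c("L", "R")))
  structure(list(
    node_positions = node_positions,
    triangles = triangles,
    hemisphere = as.character(hemisphere)
  ), class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("Cortical mesh: %d nodes, %d triangles\n",
              nrow(x$node_positions), nrow(x$triangles)))
  invisible(x)
}

#' Read a triangulated surface mesh
#'
#' Supports the OFF text format and GIFTI surface files with ASCII-encoded
#' data arrays (one `NIFTI_INTENT_POINTSET` and one `NIFTI_INTENT_TRIANGLE`
#' array; GIFTI stores 0-based triangle indices, converted to 1-based on
#' read). The format is chosen by file extension (`.off`, `.gii`).
#'
#' @param path path to an `.off` or `.gii` file.
#' @return A `cortical_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = read_mesh_off(path),
         gii = read_mesh_gifti(path),
         stop("unsupported mesh file extension '.", ext,
              "' (expected .off or .gii)"))
}

read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L || toupper(lines[1]) != "OFF") {
    stop("not an OFF file: ", path)
  }
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) stop("truncated OFF file: ", path)
  verts <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                       quiet = TRUE), ncol = 3, byrow = TRUE)
  tris <- NULL
  if (nf > 0) {
    face_rows <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
      v <- scan(text = l, quiet = TRUE)
      if (v[1] != 3) stop("only triangular faces are supported (got a ",
                          v[1], "-gon)")
      v[2:4] + 1L  # OFF indices are 0-based
    })
    tris <- do.call(rbind, face_rows)
  } else {
    tris <- matrix(integer(0), ncol = 3)
  }
  cortical_mesh(verts, tris)
}

#' Write a mesh in OFF format
#'
#' @param mesh a `cortical_mesh`.
#' @param path output `.off` path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$node_positions),
                     nrow(mesh$triangles)), con)
  writeLines(apply(mesh$node_positions, 1, function(r) {
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")
  }), con)
  if (nrow(mesh$triangles) > 0) {
    writeLines(apply(mesh$triangles - 1L, 1, function(r) {
      paste(c(3L, r), collapse = " ")
    }), con)
  }
  invisible(path)
}

gifti_data_array <- function(doc, intent) {
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  hit <- arrays[vapply(arrays, function(a)
    identical(xml2::xml_attr(a, "Intent"), intent), logical(1))]
  if (length(hit) == 0) stop("GIFTI file lacks a ", intent, " data array")
  a <- hit[[1]]
  if (!identical(xml2::xml_attr(a, "Encoding"), "ASCII")) {
    stop("only ASCII-encoded GIFTI data arrays are supported")
  }
  dim0 <- as.integer(xml2::xml_attr(a, "Dim0"))
  vals <- scan(text = xml2::xml_text(xml2::xml_find_first(a, ".//Data")),
               quiet = TRUE)
  matrix(vals, nrow = dim0, byrow = TRUE)
}

read_mesh_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  verts <- gifti_data_array(doc, "NIFTI_INTENT_POINTSET")
  tris <- gifti_data_array(doc, "NIFTI_INTENT_TRIANGLE")
  cortical_mesh(verts, tris + 1L)
}

gifti_array_xml <- function(values, intent, dtype) {
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  dims <- if (ncol(values) == 1L) nrow(values) else dim(values)
  dim_attrs <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                     collapse = " ")
  rows <- apply(values, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "))
  paste0('<DataArray Intent="', intent, '" DataType="', dtype,
         '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="',
         length(dims), '" ', dim_attrs,
         ' Encoding="ASCII" Endian="LittleEndian"><Data>',
         paste(rows, collapse = "\n"),
         '</Data></DataArray>')
}

#' Write a mesh as a GIFTI surface file (ASCII encoding)
#'
#' @param mesh a `cortical_mesh`.
#' @param path output `.gii` path.
#' @return `path`, invisibly.
#' @export
write_mesh_gifti <- function(mesh, path) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  pts <- gifti_array_xml(mesh$node_positions, "NIFTI_INTENT_POINTSET",
                         "NIFTI_TYPE_FLOAT32")
  tri <- gifti_array_xml(mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                         "NIFTI_TYPE_INT32")
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
                pts, "\n", tri, "\n</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}

#' Read a node-level parcellation table
#'
#' TSV with columns `node_index` (1-based) and `region`; optional columns
#' `hemisphere` and `display_name` populate the region table. Nodes absent
#' from the file are unlabelled.
#'
#' @param path TSV path.
#' @param n_nodes number of mesh nodes the parcellation refers to.
#' @return An object of class `"parcellation"`: list with `node_labels`
#'   (character, `NA` where unlabelled) and `region_table` (data.frame
#'   `region`, `hemisphere`, `display_name`).
#' @export
read_parcellation <- function(path, n_nodes) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("node_index", "region") %in% names(df))) {
    stop("parcellation table needs columns node_index and region")
  }
  idx <- as.integer(df$node_index)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_nodes)) {
    stop("parcellation node_index out of range 1..", n_nodes)
  }
  labels <- rep(NA_character_, n_nodes)
  labels[idx] <- df$region
  regs <- unique(df$region)
  tab <- data.frame(region = regs,
                    hemisphere = NA_character_,
                    display_name = regs,
                    stringsAsFactors = FALSE)
  if ("hemisphere" %in% names(df)) {
    tab$hemisphere <- df$hemisphere[match(regs, df$region)]
  }
  if ("display_name" %in% names(df)) {
    tab$display_name <- df$display_name[match(regs, df$region)]
  }
  parcellation(labels, tab)
}

#' Parcellation constructor
#'
#' @param node_labels character vector of region names per mesh node
#'   (`NA` = unlabelled).
#' @param region_table optional data.frame with columns `region`,
#'   `hemisphere`, `display_name`; derived from `node_labels` if omitted.
#' @return A `"parcellation"` object.
#' @export
parcellation <- function(node_labels, region_table = NULL) {
  node_labels <- as.character(node_labels)
  regs <- unique(stats::na.omit(node_labels))
  if (is.null(region_table)) {
    region_table <- data.frame(region = regs,
                               hemisphere = NA_character_,
                               display_name = regs,
                               stringsAsFactors = FALSE)
  }
  missing <- setdiff(regs, region_table$region)
  if (length(missing) > 0) {
    stop("node label(s) missing from region table: ",
         paste(missing, collapse = ", "))
  }
  structure(list(node_labels = node_labels, region_table = region_table),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d nodes labelled (%d regions), %d unlabelled\n",
              sum(!is.na(x$node_labels)), nrow(x$region_table),
              sum(is.na(x$node_labels))))
  invisible(x)
}
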