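#' Connectivity-probability matrix constructor
#'
#' @param prob square numeric matrix of probabilities in `[0, 1]`, with
#'   identical row and column (region) names in the same order.
#' @param direction `"afferent"` (row receives from column) or
#'   `"efferent"` (row projects to column).
#' @return A `"connectivity_matrix"` object.
#' @export
connectivity_matrix <- function(prob, direction = c("afferent", "efferent")) {
  direction <- match.arg(direction)
  prob <- as.matrix(prob)
  if (nrow(prob) != ncol(prob)) {
    stop("connectivity matrix must be square, got ",
         nrow(prob), " x ", ncol(prob))
  }
  if (is.null(rownames(prob)) || is.null(colnames(prob))) {
    stop("connectivity matrix needs region names on rows and columns")
  }
  if (!identical(rownames(prob), colnames(prob))) {
    stop("row and column region order differ")
  }
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1)) {
    stop("connectivity probabilities must all lie in [0, 1]")
  }
  structure(list(prob = prob, regions = rownames(prob),
                 direction = direction),
            class = "connectivity_matrix")
}

#' Read a region-by-region connectivity-probability CSV
#'
#' The CSV carries region names as both the header row and the first
#' column, in identical order. Any value outside `[0, 1]` is an error
#' (never clipped).
#'
#' @param path CSV path.
#' @param direction `"afferent"` or `"efferent"`.
#' @return A `connectivity_matrix`.
#' @export
read_connectivity <- function(path, direction = c("afferent", "efferent")) {
  direction <- match.arg(direction)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  regions <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop("connectivity CSV is not square: ", nrow(m), " rows, ",
         ncol(m), " value columns")
  }
  if (!identical(colnames(m), regions)) {
    stop("header regions and first-column regions differ (order matters)")
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    bad <- m[which(!is.finite(m) | m < 0 | m > 1)][1]
    stop("connectivity value out of range [0, 1]: ", bad)
  }
  rownames(m) <- regions
  connectivity_matrix(m, direction)
}

#' Write a connectivity matrix as CSV
#'
#' @param cm a `connectivity_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- data.frame(region = cm$regions, cm$prob, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("%s connectivity: %d regions\n",
              x$direction, length(x$regions)))
  invisible(x)
}

#' Read a high-frequency stimulation outcome table
#'
#' TSV with columns `site_id`, `hemisphere` (`L`/`R`), `current_ma`,
#' `category` and optionally `body_district`. Categories (case-insensitive)
#' come from the closed clinical vocabulary; a body district is required
#' for (and only for) sensorimotor outcomes.
#'
#' @param path TSV path.
#' @return A data.frame of validated records (see [categorize_stimulation()]).
#' @export
read_stimulation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("site_id", "hemisphere", "current_ma", "category")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("stimulation table missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"body_district" %in% names(df)) {
    df$body_district <- rep(NA_character_, nrow(df))
  }
  categorize_stimulation(df)
}

#' Write a per-node surface map as TSV
#'
#' Columns: `node_index` (1-based), `value` (NA where masked), `masked`.
#'
#' @param map a `surface_map` (see [compute_map()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_surface_map <- function(map, path) {
  stopifnot(inherits(map, "surface_map"))
  df <- data.frame(node_index = seq_along(map$values),
                   value = ifelse(map$mask, map$values, NA_real_),
                   masked = !map$mask)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a per-node surface map as a GIFTI functional file (ASCII)
#'
#' Masked nodes are written as `NaN`.
#'
#' @param map a `surface_map`.
#' @param path output `.gii` path.
#' @return `path`, invisibly.
#' @export
write_surface_map_gifti <- function(map, path) {
  stopifnot(inherits(map, "surface_map"))
  v <- ifelse(map$mask, map$values, NaN)
  arr <- gifti_array_xml(v, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32")
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="1">\n',
                arr, "\n</GIFTI>\n")
  writeLines(xml, path)
  invisible(path)
}
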