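#' Read a lead (electrode contact) table
#'
#' Parses a tab-separated table of SEEG recording leads. Mandatory columns:
#' `lead_id`, `x`, `y`, `z` (millimetres, right-handed space), `hemisphere`
#' (`L`/`R`) and `grey_matter` (logical). An optional `region` column carries
#' a parcellation label. The decimal separator is `.` and a header row is
#' mandatory.
#'
#' @param path path to a TSV file.
#' @return A `lead_set`: a data.frame with columns `lead_id`, `x`, `y`, `z`,
#'   `hemisphere`, `grey_matter` and (if present in the file) `region`.
#' @seealso [grey_matter_leads()] for the view every analysis stage consumes.
#' @export
read_leads_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", colClasses = "character")
  required <- c("lead_id", "x", "y", "z", "hemisphere", "grey_matter")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("lead table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop("non-numeric or non-finite coordinate '", col,
           "' in lead table at data line ", bad[1])
    }
    df[[col]] <- v
  }
  if (!all(df$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'")
  }
  gm <- toupper(df$grey_matter) %in% c("TRUE", "T", "1", "YES")
  ngm <- toupper(df$grey_matter) %in% c("FALSE", "F", "0", "NO")
  if (!all(gm | ngm)) stop("grey_matter must be a logical column")
  df$grey_matter <- gm
  if (anyDuplicated(df$lead_id)) stop("duplicated lead_id in lead table")
  as_lead_set(df)
}

#' Write a lead table
#'
#' @param leads a `lead_set` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_leads_table <- function(leads, path) {
  stopifnot(inherits(leads, "lead_set"))
  utils::write.table(leads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

as_lead_set <- function(df) {
  class(df) <- c("lead_set", "data.frame")
  df
}

#' Grey-matter view of a lead set
#'
#' Analyses are restricted to leads located in the cortical grey matter;
#' this returns that subset.
#'
#' @param leads a `lead_set`.
#' @return The `lead_set` rows with `grey_matter == TRUE`.
#' @export
grey_matter_leads <- function(leads) {
  stopifnot(inherits(leads, "lead_set"))
  as_lead_set(leads[leads$grey_matter, , drop = FALSE])
}

#' @export
print.lead_set <- function(x, ...) {
  cat(sprintf("Lead set: %d leads (%d grey matter, L=%d R=%d)\n",
              nrow(x), sum(x$grey_matter),
              sum(x$hemisphere == "L"), sum(x$hemisphere == "R")))
  NextMethod()
}
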