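#' Epoched recording container
#'
#' Constructs the in-memory representation of epoched multi-channel SEEG
#' data: a `leads x trials x samples` numeric array plus per-trial condition
#' labels. Time is milliseconds relative to stimulus onset and the epoch
#' window is half-open `[start, end)`, so at 1000 Hz a (-200, 700) window
#' holds 900 samples at t = -200, ..., 699 ms.
#'
#' @param data numeric array `leads x trials x samples`.
#' @param lead_ids character vector, one id per lead.
#' @param conditions character vector, one label per trial, each one of
#'   `"smiling"`, `"fearful"`, `"neutral"`.
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window `(start_ms, end_ms)` relative to stimulus onset.
#' @return An object of class `"epoched_recording"`.
#' @export
epoched_recording <- function(data, lead_ids, conditions,
                              sampling_rate = 1000,
                              epoch_window = c(-200, 700)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (length(lead_ids) != dim(data)[1]) {
    stop("lead_ids length (", length(lead_ids),
         ") does not match the array's lead dimension (", dim(data)[1], ")")
  }
  if (length(conditions) != dim(data)[2]) {
    stop("conditions length (", length(conditions),
         ") does not match the array's trial dimension (", dim(data)[2], ")")
  }
  bad <- setdiff(unique(conditions), c("smiling", "fearful", "neutral"))
  if (length(bad) > 0) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(length(sampling_rate) == 1L, sampling_rate > 0,
            length(epoch_window) == 2L)
  if (!(epoch_window[1] < 0 && 0 < epoch_window[2])) {
    stop("epoch_window must straddle stimulus onset (start < 0 < end)")
  }
  expected <- diff(epoch_window) * sampling_rate / 1000
  if (!isTRUE(all.equal(expected, dim(data)[3]))) {
    stop("sample count (", dim(data)[3], ") does not match window ",
         "[", epoch_window[1], ", ", epoch_window[2], ") at ",
         sampling_rate, " Hz (expected ", expected, ")")
  }
  structure(list(
    data = data,
    lead_ids = as.character(lead_ids),
    conditions = as.character(conditions),
    sampling_rate = sampling_rate,
    epoch_window = as.numeric(epoch_window)
  ), class = "epoched_recording")
}

#' Sample times of an epoched recording
#'
#' @param rec an `epoched_recording`.
#' @return Numeric vector of sample times in ms (half-open epoch window).
#' @export
epoch_times <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  step <- 1000 / rec$sampling_rate
  seq(rec$epoch_window[1], rec$epoch_window[2] - step, by = step)
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched recording: %d leads x %d trials x %d samples @ %g Hz, window [%g, %g) ms\n",
              d[1], d[2], d[3], x$sampling_rate,
              x$epoch_window[1], x$epoch_window[2]))
  cat("  trials:", paste(sprintf("%s=%d", names(table(x$conditions)),
                                 table(x$conditions)), collapse = ", "), "\n")
  invisible(x)
}

#' Write an epoched recording to disk
#'
#' The container is a flat little-endian float64 array file (`<path>.dat`,
#' written in lead-major / column-major R order) accompanied by a JSON
#' sidecar (`<path>.json`) holding the dimensions, lead ids, per-trial
#' condition labels, sampling rate and epoch window. The pair round-trips
#' bit-exactly through [read_epochs()].
#'
#' @param rec an `epoched_recording`.
#' @param path basename (without extension) for the `.dat`/`.json` pair.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(rec, path) {
  stopifnot(inherits(rec, "epoched_recording"))
  dat <- paste0(path, ".dat")
  side <- paste0(path, ".json")
  con <- file(dat, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  meta <- list(
    dims = dim(rec$data),
    lead_ids = rec$lead_ids,
    conditions = rec$conditions,
    sampling_rate = rec$sampling_rate,
    epoch_window = rec$epoch_window,
    dtype = "float64le",
    order = "column-major"
  )
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoched recording from disk
#'
#' @param path basename (without extension) of a `.dat`/`.json` pair
#'   written by [write_epochs()].
#' @return An `epoched_recording`.
#' @export
read_epochs <- function(path) {
  dat <- paste0(path, ".dat")
  side <- paste0(path, ".json")
  if (!file.exists(dat) || !file.exists(side)) {
    stop("epoch container incomplete: need both ", dat, " and ", side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  if (length(dims) != 3L) stop("sidecar dims must have length 3")
  n <- prod(dims)
  expected_bytes <- n * 8
  actual_bytes <- file.info(dat)$size
  if (actual_bytes != expected_bytes) {
    stop("array/sidecar shape mismatch: sidecar implies ", expected_bytes,
         " bytes, file has ", actual_bytes)
  }
  if (length(meta$lead_ids) != dims[1]) {
    stop("array/sidecar shape mismatch: sidecar lists ",
         length(meta$lead_ids), " leads for a ", dims[1], "-lead array")
  }
  if (length(meta$conditions) != dims[2]) {
    stop("array/sidecar shape mismatch: sidecar lists ",
         length(meta$conditions), " condition labels for ",
         dims[2], " trials")
  }
  con <- file(dat, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  epoched_recording(array(x, dim = dims),
                    lead_ids = meta$lead_ids,
                    conditions = meta$conditions,
                    sampling_rate = meta$sampling_rate,
                    epoch_window = meta$epoch_window)
}
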