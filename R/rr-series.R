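#' RR-interval series
#'
#' Container for one record's beat-to-beat (RR) interval sequence in
#' milliseconds, the substrate of all heart-rate-variability features.
#' Onset times are derived as prefix sums of the intervals.
#'
#' @param intervals numeric vector of RR intervals in milliseconds; all
#'   values must be positive and finite, length at least 2.
#' @param record_id identifier for the record.
#' @return An object of class `rr_series` with fields `record_id`,
#'   `intervals` (ms) and `onset_times` (s, cumulative).
#' @examples
#' rr <- rr_series(c(800, 820, 790, 810))
#' rr$onset_times
#' @export
rr_series <- function(intervals, record_id = "record") {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L)
    stop("rr_series needs at least 2 intervals, got ", length(intervals))
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("RR intervals must be positive and finite")
  structure(
    list(record_id = as.character(record_id)[1L],
         intervals = intervals,
         onset_times = cumsum(intervals) / 1000),
    class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %s: %d intervals, %.1f s, mean RR %.1f ms\n",
              x$record_id, length(x$intervals),
              x$onset_times[length(x$onset_times)], mean(x$intervals)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

as_rr_series <- function(x, record_id = "record") {
  if (inherits(x, "rr_series")) x else rr_series(x, record_id)
}

#' Read RR-interval series from CSV
#'
#' Auto-detects the two supported layouts: long format with columns
#' `record_id,beat_index,rr_ms` (one row per beat) and wide format with
#' columns `record_id,rr_ms_list` where the interval list is
#' semicolon-joined.
#'
#' @param path path to a CSV file with a header row.
#' @return A named list of [rr_series()] objects, one per record.
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  if (all(c("record_id", "beat_index", "rr_ms") %in% nm)) {
    names(df) <- nm
    sp <- split(df[order(df$record_id, df$beat_index), ], df$record_id)
    out <- lapply(sp, function(d) rr_series(d$rr_ms, d$record_id[1L]))
  } else if (all(c("record_id", "rr_ms_list") %in% nm)) {
    names(df) <- nm
    out <- lapply(seq_len(nrow(df)), function(i) {
      vals <- as.numeric(strsplit(df$rr_ms_list[i], ";", fixed = TRUE)[[1L]])
      rr_series(vals, df$record_id[i])
    })
    names(out) <- df$record_id
  } else {
    stop("unrecognized RR CSV layout: need columns ",
         "(record_id, beat_index, rr_ms) or (record_id, rr_ms_list)")
  }
  out
}

#' Write RR-interval series to CSV (long format)
#'
#' @param rr_list a list of [rr_series()] objects (or one object).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr_list, path) {
  if (inherits(rr_list, "rr_series")) rr_list <- list(rr_list)
  rows <- do.call(rbind, lapply(rr_list, function(rr) {
    data.frame(record_id = rr$record_id,
               beat_index = seq_along(rr$intervals),
               rr_ms = rr$intervals)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
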