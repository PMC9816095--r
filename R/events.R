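# Event tables: detections and ground truth share one flat CSV schema with
# columns kind, onset, duration, and any number of numeric prop_* columns.

#' Construct an event table
#'
#' @param kind character vector, `"spike"` or `"ripple"`.
#' @param onset event onsets (s, experiment clock, >= 0 relative to the
#'   recording start is not required; onsets must be non-negative on the
#'   absolute clock used by the caller's files).
#' @param duration event durations (s, > 0).
#' @param ... equal-length numeric vectors stored as `prop_<name>` columns.
#' @return a `data.frame` with class `ecosyn_events`.
#' @export
events_table <- function(kind = character(), onset = numeric(),
                         duration = numeric(), ...) {
  props <- list(...)
  if (length(kind) > 0) {
    if (!all(kind %in% c("spike", "ripple")))
      abort_validation("event kind must be 'spike' or 'ripple'")
    if (any(onset < 0)) abort_validation("event onsets must be non-negative")
    if (any(duration <= 0)) abort_validation("event durations must be positive")
  }
  df <- data.frame(kind = as.character(kind), onset = as.numeric(onset),
                   duration = as.numeric(duration))
  for (nm in names(props)) df[[paste0("prop_", nm)]] <- as.numeric(props[[nm]])
  class(df) <- c("ecosyn_events", "data.frame")
  df
}

#' Write an event table to CSV
#'
#' RFC 4180 CSV with a header row; an empty table writes the header only.
#'
#' @param events an [events_table()] (or any data.frame with its columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  need <- c("kind", "onset", "duration")
  if (!all(need %in% names(events)))
    abort_validation("event table must have columns kind, onset, duration")
  write.csv(as.data.frame(events)[, c(need, setdiff(names(events), need)), drop = FALSE],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' Validates each row; a malformed row (non-numeric onset/duration, negative
#' onset, non-positive duration, unknown kind) raises a parse error naming
#' the offending line number.
#'
#' @param path CSV path as written by [write_events()].
#' @return an [events_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "onset", "duration")
  if (!all(need %in% names(df)))
    abort_format("event CSV must have columns kind, onset, duration")
  if (nrow(df) > 0) {
    onset <- suppressWarnings(as.numeric(df$onset))
    duration <- suppressWarnings(as.numeric(df$duration))
    bad <- which(!df$kind %in% c("spike", "ripple") | !is.finite(onset) |
                   !is.finite(duration) | onset < 0 | duration <= 0)
    if (length(bad) > 0)
      abort_format(sprintf("malformed event row at line %d of %s",
                           bad[1L] + 1L, path))   # +1 for the header line
    df$onset <- onset
    df$duration <- duration
  }
  class(df) <- c("ecosyn_events", "data.frame")
  df
}
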