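# Tab-separated tables: events, channel metadata, and results. Column
# conventions follow BIDS-iEEG (onset/duration in seconds, trial_type).

events_required_cols <- c("onset", "duration", "trial_type")

#' Write an events table to a BIDS-iEEG-style TSV
#'
#' @param events Events data frame (columns `onset`, `duration`,
#'   `trial_type`, plus any extras such as `block_index`,
#'   `within_block_index`, `is_oddball`, `keep`; extras round-trip).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  miss <- setdiff(events_required_cols, names(events))
  if (length(miss) > 0) {
    stop(sprintf("events table is missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read an events TSV
#'
#' @param path File path.
#' @return Events data frame; onsets are checked to be strictly
#'   increasing; unknown extra columns are preserved.
#' @export
read_events_tsv <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                          stringsAsFactors = FALSE)
  miss <- setdiff(events_required_cols, names(ev))
  if (length(miss) > 0) {
    stop(sprintf("events file %s is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  ev$trial_type <- as.character(ev$trial_type)
  if (nrow(ev) > 1 && any(diff(ev$onset) <= 0)) {
    stop(sprintf("event onsets in %s are not strictly increasing", path),
         call. = FALSE)
  }
  for (col in c("is_oddball", "keep")) {
    if (col %in% names(ev)) ev[[col]] <- as.logical(ev[[col]])
  }
  ev
}

#' Write / read a channel-metadata TSV
#'
#' Columns: `name`, `label` (anatomical site), `include` (analysis
#' inclusion flag, supplied by the user after clinical review -- never
#' computed), `kind` (`grid`/`seeg`).
#'
#' @param channels Channel data frame.
#' @param path File path.
#' @return `path` / the channel data frame.
#' @export
write_channels_tsv <- function(channels, path) {
  miss <- setdiff(c("name", "label", "include"), names(channels))
  if (length(miss) > 0) {
    stop(sprintf("channels table is missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  utils::write.table(channels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_channels_tsv
#' @export
read_channels_tsv <- function(path) {
  ch <- utils::read.delim(path, sep = "\t", na.strings = "n/a",
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "label", "include"), names(ch))
  if (length(miss) > 0) {
    stop(sprintf("channels file %s is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  ch$include <- as.logical(ch$include)
  ch
}
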