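# Reading and writing filament tracking data. All readers normalise to one
# internal representation: a tibble with columns track_id (character),
# frame (0-based integer), x, y (pixels, image convention: origin top-left,
# x rightward, y downward).

track_columns <- c("track_id", "frame", "x", "y")

#' Validate a track table
#'
#' Checks that a data frame is a valid track table: it has `track_id`,
#' `frame`, `x`, `y` columns, coordinates are finite, frames are
#' non-negative, and frames are strictly increasing within each track.
#'
#' @param tracks A data frame of track points.
#' @return The validated tracks, invisibly, as a tibble sorted by
#'   `track_id` and `frame` with `track_id` coerced to character.
#' @export
validate_tracks <- function(tracks) {
  if (!is.data.frame(tracks)) {
    abort_validation("`tracks` must be a data frame.")
  }
  missing_cols <- setdiff(track_columns, names(tracks))
  if (length(missing_cols) > 0) {
    abort_format(sprintf(
      "track table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  tracks <- tibble::as_tibble(tracks)[track_columns]
  tracks$track_id <- as.character(tracks$track_id)
  if (nrow(tracks) == 0) {
    return(invisible(tracks))
  }
  if (!is.numeric(tracks$frame) || anyNA(tracks$frame) ||
      any(tracks$frame < 0) || any(tracks$frame != floor(tracks$frame))) {
    abort_validation("`frame` must contain non-negative integers.")
  }
  tracks$frame <- as.integer(tracks$frame)
  for (col in c("x", "y")) {
    if (!is.numeric(tracks[[col]]) || any(!is.finite(tracks[[col]]))) {
      abort_validation(sprintf("column `%s` must be finite numeric.", col))
    }
  }
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  dup <- tracks |>
    dplyr::count(.data$track_id, .data$frame) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_validation(sprintf(
      "duplicate frame %d in track '%s'", dup$frame[1], dup$track_id[1]
    ))
  }
  invisible(tracks)
}

#' Read an MTrackJ MDF data file
#'
#' Parses the text-based data files written by the ImageJ plugin MTrackJ,
#' the tool commonly used for manual filament tip tracking. Only the x, y
#' and t columns of `Point` records are consumed; `Track` records delimit
#' tracks. MTrackJ time indices are 1-based and are shifted to the 0-based
#' frame convention used throughout this package.
#'
#' @param path Path to an MDF file.
#' @return A tibble with columns `track_id`, `frame`, `x`, `y`, sorted by
#'   track and frame.
#' @seealso [read_tracks_csv()], [write_tracks_csv()]
#' @export
read_mdf <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[[1]], "MTrackJ")) {
    abort_format("not an MTrackJ data file: missing 'MTrackJ' header line.")
  }
  track_id <- character(0)
  frame <- integer(0)
  x <- numeric(0)
  y <- numeric(0)
  current <- NA_character_
  for (i in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tokens) == 0) next
    kind <- tokens[[1]]
    if (kind == "Track") {
      if (length(tokens) < 2) {
        abort_parse(sprintf("line %d: 'Track' record without an id.", i))
      }
      current <- tokens[[2]]
    } else if (kind == "Point") {
      if (is.na(current)) {
        abort_format(sprintf("line %d: 'Point' record before any 'Track'.", i))
      }
      if (length(tokens) < 6) {
        abort_parse(sprintf(
          "line %d: 'Point' record needs at least 6 fields, got %d.",
          i, length(tokens)
        ))
      }
      vals <- suppressWarnings(as.numeric(tokens[3:6]))
      if (anyNA(vals)) {
        abort_parse(sprintf("line %d: non-numeric point field.", i))
      }
      track_id <- c(track_id, current)
      x <- c(x, vals[[1]])
      y <- c(y, vals[[2]])
      frame <- c(frame, as.integer(round(vals[[4]])) - 1L) # 1-based t -> 0-based
    }
    # other record kinds (Assembly, Cluster, display settings, ...) ignored
  }
  validate_tracks(tibble::tibble(track_id = track_id, frame = frame, x = x, y = y))
}

#' Write tracks to an MTrackJ MDF data file
#'
#' Inverse of [read_mdf()]: frames are written 1-based in the t column, as
#' MTrackJ expects.
#'
#' @param tracks A track table (see [validate_tracks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mdf <- function(tracks, path) {
  tracks <- validate_tracks(tracks)
  lines <- c("MTrackJ 1.5.1 Data File", "Assembly 1", "Cluster 1")
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    lines <- c(lines, paste("Track", id))
    lines <- c(lines, sprintf(
      "Point %d %.6f %.6f 1.0 %d 1", seq_len(nrow(tr)), tr$x, tr$y, tr$frame + 1L
    ))
  }
  lines <- c(lines, "End of MTrackJ Data File")
  tryCatch(
    writeLines(lines, path),
    error = function(e) abort_io(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' Read tracks from CSV
#'
#' Reads a comma-separated file with a header row containing at least the
#' columns `track_id`, `frame`, `x`, `y` (any order; extra columns are
#' ignored). Rows may appear in any order; points are sorted by frame
#' within each track.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `track_id`, `frame`, `x`, `y`.
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("file not found: %s", path))
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_parse(sprintf("cannot parse '%s': %s", path, conditionMessage(e)))
  )
  missing_cols <- setdiff(track_columns, names(df))
  if (length(missing_cols) > 0) {
    abort_format(sprintf(
      "CSV is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(df) > 0 && anyNA(df[track_columns])) {
    abort_validation("CSV contains missing or non-numeric track fields.")
  }
  validate_tracks(df[track_columns])
}

#' Write tracks to CSV
#'
#' Writes a track table in the dialect read by [read_tracks_csv()]
#' (comma-separated, header row, `.` decimal separator). Coordinates are
#' written at full precision, so `read_tracks_csv(write_tracks_csv(x))`
#' round-trips losslessly.
#'
#' @inheritParams write_mdf
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  tracks <- validate_tracks(tracks)
  tryCatch(
    readr::write_csv(tracks, path, progress = FALSE),
    error = function(e) abort_io(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}
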