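# Programmatic fixtures shared across test files.

# A minimal MTrackJ MDF file with the given tracks (list of data frames with
# x, y and 1-based t columns). Returns the path.
write_mdf_fixture <- function(tracks, path = tempfile(fileext = ".mdf")) {
  lines <- c("MTrackJ 1.5.1 Data File", "Assembly 1", "Cluster 1")
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    lines <- c(lines, paste("Track", id))
    lines <- c(lines, sprintf("Point %d %.4f %.4f 1.0 %d 1",
                              seq_len(nrow(tr)), tr$x, tr$y, tr$t))
  }
  lines <- c(lines, "End of MTrackJ Data File")
  writeLines(lines, path)
  path
}

# Straight-line constant-velocity track: dx, dy per frame.
line_track <- function(n, dx, dy, id = "a", start = c(0, 0)) {
  tibble::tibble(
    track_id = id, frame = 0:(n - 1),
    x = start[1] + dx * (0:(n - 1)),
    y = start[2] + dy * (0:(n - 1))
  )
}

# Velocity table from a plain numeric vector.
speed_series <- function(values, id = "a") {
  tibble::tibble(track_id = id, interval = seq_along(values) - 1L,
                 speed = values, variant = "raw", units = "px/frame")
}

# Track whose speed is piecewise constant (one segment per element of
# `speeds`, each `len` intervals), along a straight line, with optional
# positional noise.
piecewise_track <- function(speeds, len, noise_sd = 0, id = "a") {
  v <- rep(speeds, each = len)
  x <- cumsum(c(0, v))
  n <- length(x)
  tibble::tibble(
    track_id = id, frame = 0:(n - 1),
    x = x + stats::rnorm(n, 0, noise_sd),
    y = stats::rnorm(n, 0, noise_sd)
  )
}
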