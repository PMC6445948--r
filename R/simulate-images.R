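# Synthetic IVMA fluorescence image sequence: elliptical filaments gliding
# over a uniform background, each changing speed twice, with additive
# Gaussian intensity noise. Ground-truth tip tracks and speeds accompany the
# rendered stack so trackers and the analysis pipeline can be validated
# end to end.

#' Configuration of the synthetic image-sequence generator
#'
#' Defaults emulate a typical simulated IVMA recording: 100 frames of
#' 700 x 700 px at 8 bit, background intensity 80, 30 elliptical filaments of
#' intensity 130 (full sizes 17 x 3 px and 8 x 3 px, assigned at random),
#' speeds uniform in 2–8 px/frame with two speed changes per filament, and
#' additive Gaussian intensity noise of SD 15 grey levels.
#'
#' @param n_frames Number of frames.
#' @param width,height Image size in pixels.
#' @param bit_depth Bits per pixel (intensities clipped to `[0, 2^bit_depth - 1]`).
#' @param background_intensity,filament_intensity Grey levels before noise.
#' @param n_filaments Number of filaments.
#' @param filament_sizes List of full-length (length, width) pairs in px;
#'   each filament gets one, drawn uniformly.
#' @param speed_range Range (px/frame) of the per-epoch speeds.
#' @param n_speed_changes Speed changes per filament (default 2, giving three
#'   constant-speed epochs per filament, each at least 10 frames long).
#' @param intensity_noise_sd SD of the per-pixel Gaussian intensity noise, in
#'   grey levels.
#' @param heading_jitter_sd SD (radians/frame) of the heading random walk.
#' @param seed Integer seed.
#' @return An `image_sim_config` object.
#' @export
image_sim_config <- function(n_frames = 100, width = 700, height = 700,
                             bit_depth = 8,
                             background_intensity = 80,
                             filament_intensity = 130,
                             n_filaments = 30,
                             filament_sizes = list(c(17, 3), c(8, 3)),
                             speed_range = c(2, 8),
                             n_speed_changes = 2,
                             intensity_noise_sd = 15,
                             heading_jitter_sd = 0.03,
                             seed = NULL) {
  if (n_frames < 2) abort_config("`n_frames` must be >= 2.")
  if (width < 8 || height < 8) abort_config("image must be at least 8 x 8 px.")
  maxval <- 2^bit_depth - 1
  if (background_intensity < 0 || filament_intensity > maxval) {
    abort_config("intensities must lie within the bit-depth range before noise.")
  }
  if (any(unlist(filament_sizes) <= 0)) abort_config("filament sizes must be positive.")
  if (length(speed_range) != 2 || any(speed_range <= 0) || diff(speed_range) < 0) {
    abort_config("`speed_range` must be a positive increasing pair.")
  }
  if (intensity_noise_sd < 0) abort_config("`intensity_noise_sd` must be >= 0.")
  structure(
    list(
      n_frames = as.integer(n_frames), width = as.integer(width),
      height = as.integer(height), bit_depth = as.integer(bit_depth),
      background_intensity = background_intensity,
      filament_intensity = filament_intensity,
      n_filaments = as.integer(n_filaments),
      filament_sizes = filament_sizes,
      speed_range = speed_range,
      n_speed_changes = as.integer(n_speed_changes),
      intensity_noise_sd = intensity_noise_sd,
      heading_jitter_sd = heading_jitter_sd,
      seed = seed
    ),
    class = "image_sim_config"
  )
}

# Speed-change frames: n_changes cut points in [min_len, n_frames - 1 -
# min_len] pairwise >= min_len apart, so every epoch spans at least min_len
# intervals and can form a valid phase.
draw_change_frames <- function(n_frames, n_changes, min_len = 10L) {
  if (n_changes == 0L) return(integer(0))
  lo <- min_len
  hi <- n_frames - 1L - min_len - (n_changes - 1L) * min_len
  if (hi < lo) abort_config("sequence too short for the requested speed changes.")
  raw <- sort(sample(lo:hi, n_changes, replace = TRUE))
  as.integer(raw + (seq_len(n_changes) - 1L) * min_len)
}

# Per-pixel coverage of an oriented ellipse on a patch, 3x3 supersampling.
# cols/rows are pixel indices (1-based); centres at (col - 0.5, row - 0.5).
ellipse_coverage <- function(cols, rows, cx, cy, theta, a, b) {
  off <- c(-1, 0, 1) / 3
  grid <- expand.grid(col = cols, row = rows)
  cov <- numeric(nrow(grid))
  ct <- cos(theta)
  st <- sin(theta)
  for (ox in off) {
    for (oy in off) {
      dx <- grid$col - 0.5 + ox - cx
      dy <- grid$row - 0.5 + oy - cy
      u <- (dx * ct + dy * st) / a
      w <- (-dx * st + dy * ct) / b
      cov <- cov + (u * u + w * w <= 1)
    }
  }
  matrix(cov / 9, nrow = length(cols)) # cols index rows of this matrix
}

# Stamp one filament onto a frame matrix (rows = y, cols = x) with toroidal
# wrapping. Returns the modified frame.
stamp_ellipse <- function(frame, cx, cy, theta, a, b, fg, bg) {
  h <- nrow(frame)
  w <- ncol(frame)
  r <- ceiling(a) + 2L
  cols <- floor(cx) + (-r:r)
  rows <- floor(cy) + (-r:r)
  cov <- ellipse_coverage(cols, rows, cx, cy, theta, a, b)
  wcols <- ((cols - 1L) %% w) + 1L
  wrows <- ((rows - 1L) %% h) + 1L
  val <- bg + (fg - bg) * cov # cov[i, j] ~ (cols[i], rows[j])
  idx <- cbind(rep(wrows, each = length(wcols)), rep(wcols, times = length(wrows)))
  v <- as.vector(val) # column-major: col index fastest -> matches idx order
  frame[idx] <- pmax(frame[idx], v)
  frame
}

#' Simulate an IVMA image sequence with ground truth
#'
#' Renders `config$n_filaments` rigid elliptical filaments gliding with
#' piecewise-constant speeds (each filament changes speed
#' `config$n_speed_changes` times at random frames, every epoch at least 10
#' frames long) and slowly wandering headings. Filaments wrap toroidally at
#' the image borders so all stay visible; ground-truth tip tracks are
#' reported unwrapped so that displacement-based speeds are exact. Per-pixel
#' Gaussian intensity noise is added and values are clipped to the bit-depth
#' range and rounded.
#'
#' @param config An [image_sim_config()].
#' @param out_dir Optional directory; if given, writes `sequence.tif`
#'   (multi-page 8-bit grayscale), `truth_tracks.csv` (unwrapped tip
#'   positions in the [read_tracks_csv()] dialect, plus wrapped `x_image`,
#'   `y_image` columns), `truth_speeds.csv` and `change_points.csv`.
#' @return A list of class `ivma_image_sim` with `frames` (list of integer
#'   matrices, rows = y), `tracks` (unwrapped ground-truth tip tracks),
#'   `truth_speeds`, `change_points` (`track_id`, `change_frame`,
#'   `new_speed`) and `config`. If `out_dir` is given, file paths are
#'   attached as `files`.
#' @export
simulate_image_sequence <- function(config = image_sim_config(), out_dir = NULL) {
  if (!inherits(config, "image_sim_config")) {
    abort_config("`config` must be created with image_sim_config().")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n_int <- config$n_frames - 1L
  bg <- config$background_intensity
  fg <- config$filament_intensity
  maxval <- 2^config$bit_depth - 1

  filaments <- purrr::map(seq_len(config$n_filaments), function(i) {
    size <- config$filament_sizes[[sample.int(length(config$filament_sizes), 1)]]
    changes <- draw_change_frames(config$n_frames, config$n_speed_changes)
    epoch_speeds <- stats::runif(config$n_speed_changes + 1L,
                                 config$speed_range[1], config$speed_range[2])
    epoch_of <- findInterval(0:(n_int - 1L), changes) + 1L
    speeds <- epoch_speeds[epoch_of]
    headings <- cumsum(c(stats::runif(1, 0, 2 * pi),
                         stats::rnorm(n_int - 1L, 0, config$heading_jitter_sd)))
    origin <- c(stats::runif(1, 0, config$width), stats::runif(1, 0, config$height))
    # the tracked point is the leading tip; it travels with the assigned
    # speed along the heading (tip-first gliding), the body trails behind
    tip <- integrate_positions(speeds, headings, origin)
    head_full <- c(headings, headings[n_int]) # heading at each frame
    a <- size[1] / 2
    b <- size[2] / 2
    centre <- tip - a * cbind(cos(head_full), sin(head_full))
    list(
      id = as.character(i), a = a, b = b, centre = centre, heading = head_full,
      tip = tip, speeds = speeds, changes = changes, epoch_speeds = epoch_speeds
    )
  })

  frames <- purrr::map(seq_len(config$n_frames), function(f) {
    frame <- matrix(bg, nrow = config$height, ncol = config$width)
    for (fl in filaments) {
      cx <- fl$centre[f, 1] %% config$width
      cy <- fl$centre[f, 2] %% config$height
      frame <- stamp_ellipse(frame, cx, cy, fl$heading[f], fl$a, fl$b, fg, bg)
    }
    if (config$intensity_noise_sd > 0) {
      frame <- frame + stats::rnorm(length(frame), 0, config$intensity_noise_sd)
    }
    matrix(as.integer(round(pmin(pmax(frame, 0), maxval))),
           nrow = config$height)
  })

  tracks <- purrr::map_dfr(filaments, function(fl) {
    tibble::tibble(
      track_id = fl$id, frame = 0:(config$n_frames - 1L),
      x = fl$tip[, 1], y = fl$tip[, 2],
      x_image = fl$tip[, 1] %% config$width,
      y_image = fl$tip[, 2] %% config$height
    )
  })
  truth_speeds <- purrr::map_dfr(filaments, function(fl) {
    tibble::tibble(
      track_id = fl$id, interval = 0:(n_int - 1L), speed = fl$speeds,
      variant = "true", units = "px/frame"
    )
  })
  change_points <- purrr::map_dfr(filaments, function(fl) {
    tibble::tibble(
      track_id = fl$id, change_frame = fl$changes,
      new_speed = fl$epoch_speeds[-1]
    )
  })

  out <- structure(
    list(
      frames = frames, tracks = tracks, truth_speeds = truth_speeds,
      change_points = change_points, config = config
    ),
    class = "ivma_image_sim"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- list(
      tiff = file.path(out_dir, "sequence.tif"),
      tracks = file.path(out_dir, "truth_tracks.csv"),
      speeds = file.path(out_dir, "truth_speeds.csv"),
      changes = file.path(out_dir, "change_points.csv")
    )
    ok <- tryCatch(
      tiff::writeTIFF(purrr::map(frames, ~ .x / maxval), files$tiff,
                      bits.per.sample = config$bit_depth),
      error = function(e) abort_io(sprintf("cannot write TIFF: %s", conditionMessage(e)))
    )
    readr::write_csv(tracks, files$tracks, progress = FALSE)
    readr::write_csv(truth_speeds, files$speeds, progress = FALSE)
    readr::write_csv(change_points, files$changes, progress = FALSE)
    out$files <- files
  }
  out
}
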