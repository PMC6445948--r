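# End-to-end analysis: raw speed -> Kalman reconstruction -> phase
# identification -> pooled maximum-velocity statistic.

#' Run the full maximum-velocity pipeline on tracking data
#'
#' For every track with enough points: compute the raw speed, reconstruct the
#' velocity signal with the Kalman filter, and identify velocity phases by
#' split-and-merge. Phases of all tracks are pooled and summarised by
#' [max_velocity()]. Tracks that are too short for reconstruction or
#' phase identification are skipped and counted.
#'
#' @param tracks A track table (`track_id`, `frame`, `x`, `y`).
#' @param cal A [calibration()]; determines the velocity units and the
#'   seconds-per-frame used for phase durations.
#' @param kalman_q,kalman_r Kalman process/measurement noise (see
#'   [kalman_reconstruct()]).
#' @param params A [phase_params()]; by default built with the calibration's
#'   frame interval.
#' @param fraction Top fraction of the phase-velocity sum defining the
#'   maximum velocity (default 0.10).
#' @param weight_by_duration Passed to [max_velocity()].
#' @param verbose If `TRUE`, progress counts are reported via [message()].
#' @return A list of class `ivma_pipeline_result`:
#'   * `result`: the [max_velocity()] result,
#'   * `phases`: pooled phase table,
#'   * `speeds`: per-interval raw and Kalman-filtered speeds (long format),
#'   * `counts`: tracks read/used/skipped, phases found/dropped.
#' @examples
#' tr <- tibble::tibble(track_id = "a", frame = 0:40,
#'                      x = (0:40) * 3, y = (0:40) * 4)
#' res <- run_pipeline(tr, calibration(1, 1))
#' glance(res$result)
#' @export
run_pipeline <- function(tracks, cal = calibration(),
                         kalman_q = 0.5, kalman_r = 1,
                         params = NULL, fraction = 0.10,
                         weight_by_duration = FALSE, verbose = FALSE) {
  tracks <- validate_tracks(tracks)
  if (is.null(params)) {
    params <- phase_params(frame_interval = cal$frame_interval)
  }
  if (!inherits(params, "phase_params")) {
    abort_validation("`params` must be created with phase_params().")
  }
  min_points <- max(4L, params$min_phase_frames + 1L)
  sizes <- dplyr::count(tracks, .data$track_id)
  usable <- sizes$track_id[sizes$n >= min_points]
  n_skipped <- nrow(sizes) - length(usable)
  if (verbose) {
    message(sprintf("%d tracks read, %d usable, %d skipped (< %d points)",
                    nrow(sizes), length(usable), n_skipped, min_points))
  }
  if (length(usable) == 0) {
    abort_no_phases(sprintf(
      paste0("no track has the %d points needed for phase identification; ",
             "check the tracking data or lower min_phase_frames."),
      min_points
    ))
  }
  tracks <- tracks[tracks$track_id %in% usable, ]
  raw <- compute_speed(tracks, cal)
  filtered <- kalman_reconstruct(tracks, cal, q = kalman_q, r = kalman_r)
  all_phases <- merge_fractions(
    filtered, split_at_local_maxima(filtered, params), params
  )
  phases <- drop_short_phases(all_phases, params)
  n_dropped <- nrow(all_phases) - nrow(phases)
  if (verbose) {
    message(sprintf("%d phases found, %d dropped as shorter than %d frames",
                    nrow(all_phases), n_dropped, params$min_phase_frames))
  }
  if (nrow(phases) == 0) {
    abort_no_phases(paste0(
      "no phase reached the minimum duration of ", params$min_phase_frames,
      " frames; tracks may be too short or too fragmented - consider lowering ",
      "min_phase_frames or checking the tracking data."
    ))
  }
  result <- max_velocity(phases, fraction = fraction,
                         weight_by_duration = weight_by_duration)
  structure(
    list(
      result = result,
      phases = phases,
      speeds = dplyr::bind_rows(raw, filtered),
      counts = list(
        tracks_read = nrow(sizes), tracks_used = length(usable),
        tracks_skipped = n_skipped, phases_found = nrow(all_phases),
        phases_dropped_short = n_dropped
      )
    ),
    class = "ivma_pipeline_result"
  )
}

#' @export
print.ivma_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<ivma_pipeline_result> %d tracks -> %d phases; v_max = %.4g\n",
    x$counts$tracks_used, nrow(x$phases), x$result$v_max
  ))
  invisible(x)
}

#' Export the phase table of a pipeline run
#'
#' Writes the pooled phase table in a stable column order
#' (`track_id`, `phase_index`, `start_frame`, `end_frame`, `duration_s`,
#' `mean_velocity`, `sd_velocity`).
#'
#' @param phases A phase table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phases_csv <- function(phases, path) {
  out <- tibble::tibble(
    track_id = phases$track_id,
    phase_index = phases$phase,
    start_frame = phases$start_frame,
    end_frame = phases$end_frame,
    duration_s = phases$duration_s,
    mean_velocity = phases$mean_velocity,
    sd_velocity = phases$sd_velocity
  )
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) abort_io(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}
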