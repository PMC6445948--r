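#' Frame-to-frame speed of tracked filaments
#'
#' Computes the raw sliding speed of each track as displacement divided by
#' time: for consecutive points separated by \eqn{\Delta f} frames the speed
#' is \eqn{\sqrt{\Delta x^2 + \Delta y^2} / \Delta f} pixels per frame,
#' scaled to physical units by the calibration. Tracks with frame gaps are
#' accepted; the displacement across a gap is divided by the number of
#' elapsed frames.
#'
#' @param tracks A track table (`track_id`, `frame`, `x`, `y`); every track
#'   must have at least 2 points.
#' @param cal A [calibration()].
#' @return A tibble with one row per frame interval: `track_id`, `interval`
#'   (frame index at the start of the interval), `speed`, `variant`
#'   (`"raw"`) and `units`.
#' @examples
#' tr <- tibble::tibble(track_id = "a", frame = 0:2,
#'                      x = c(0, 3, 6), y = c(0, 4, 8))
#' compute_speed(tr)  # 3-4-5 triangle: 5 px/frame on both intervals
#' @export
compute_speed <- function(tracks, cal = calibration()) {
  tracks <- validate_tracks(tracks)
  if (!inherits(cal, "ivma_calibration")) {
    abort_validation("`cal` must be created with calibration().")
  }
  sizes <- dplyr::count(tracks, .data$track_id)
  if (nrow(sizes) == 0 || any(sizes$n < 2)) {
    abort_insufficient(
      "every track needs at least 2 points to compute a speed."
    )
  }
  scale <- cal$pixel_size / cal$frame_interval
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::reframe(
      interval = .data$frame[-dplyr::n()],
      speed = sqrt(diff(.data$x)^2 + diff(.data$y)^2) / diff(.data$frame) * scale
    ) |>
    dplyr::mutate(variant = "raw", units = speed_units(cal))
}
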