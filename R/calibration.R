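#' Spatial and temporal calibration for tracking data
#'
#' Couples the pixel size and the frame interval of an image sequence so that
#' velocities can be reported in physical units. With the defaults
#' (`pixel_size = 1`, `frame_interval = 1`) velocities stay in px/frame;
#' with `pixel_size = 1` and a frame interval in seconds they are in px/s;
#' with both set they are in \eqn{\mu}m/s. Typical IVMA recordings run at
#' 10 frames per second (`frame_interval = 0.1`).
#'
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param frame_interval Frame interval in seconds per frame (> 0).
#'
#' @return An object of class `ivma_calibration`: a list with elements
#'   `pixel_size` and `frame_interval`.
#' @examples
#' calibration()                      # uncalibrated, px/frame
#' calibration(0.16, 0.1)             # 0.16 um/px at 10 fps -> um/s
#' @export
calibration <- function(pixel_size = 1, frame_interval = 1) {
  check_scalar_positive(pixel_size, "pixel_size")
  check_scalar_positive(frame_interval, "frame_interval")
  structure(
    list(pixel_size = pixel_size, frame_interval = frame_interval),
    class = "ivma_calibration"
  )
}

speed_units <- function(cal) {
  if (cal$pixel_size == 1 && cal$frame_interval == 1) {
    "px/frame"
  } else if (cal$pixel_size == 1) {
    "px/s"
  } else {
    "um/s"
  }
}

#' @export
print.ivma_calibration <- function(x, ...) {
  cat(sprintf(
    "<ivma_calibration> %g um/px, %g s/frame (speeds in %s)\n",
    x$pixel_size, x$frame_interval, speed_units(x)
  ))
  invisible(x)
}
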