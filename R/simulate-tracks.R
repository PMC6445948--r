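# Synthetic 2D filament tracks with known true velocity, emulating manually
# tracked IVMA tip trajectories: constant or sinusoidally modulated speed,
# slowly wandering heading, Gaussian positional noise and sparse impulsive
# outliers (tracking blunders).

#' Configuration of the synthetic track generator
#'
#' Defaults reproduce the conditions of the signal-reconstruction benchmark:
#' 330 tracks of 100 frames, base speeds uniform in 2–8 px/frame, a mix of
#' constant and periodic (sinusoidal) speed profiles with relative amplitude
#' 0.45 and periods of 10–30 frames, Gaussian positional noise of 1.75 px and
#' 3-px impulsive outliers on 3% of the points.
#'
#' @param n_tracks Number of tracks (datasets) to generate.
#' @param n_frames Points per track (one position per frame).
#' @param profile `"mixed"` (each track constant or periodic with equal
#'   probability), `"constant"`, or `"periodic"`.
#' @param base_speed_range Range (px/frame) from which each track's base
#'   speed is drawn uniformly.
#' @param periodic_amplitude_frac Relative amplitude of the sinusoidal speed
#'   modulation of periodic tracks.
#' @param periodic_period_range Range (frames) of the modulation period,
#'   drawn uniformly per track.
#' @param heading_jitter_sd SD (radians/frame) of the random walk on the
#'   movement direction.
#' @param gaussian_pos_noise_sd SD (px, per axis) of the Gaussian positional
#'   noise added to every point.
#' @param impulse_prob Probability that a point's noise is replaced by a
#'   large impulse.
#' @param impulse_sd SD (px, per axis) of impulsive outliers.
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return A `track_sim_config` object.
#' @export
track_sim_config <- function(n_tracks = 330, n_frames = 100,
                             profile = c("mixed", "constant", "periodic"),
                             base_speed_range = c(2, 8),
                             periodic_amplitude_frac = 0.45,
                             periodic_period_range = c(10, 30),
                             heading_jitter_sd = 0.05,
                             gaussian_pos_noise_sd = 1.75,
                             impulse_prob = 0.03,
                             impulse_sd = 3.0,
                             seed = NULL) {
  profile <- match.arg(profile)
  if (!is.numeric(n_tracks) || n_tracks < 1) abort_config("`n_tracks` must be >= 1.")
  if (!is.numeric(n_frames) || n_frames < 2) abort_config("`n_frames` must be >= 2.")
  if (length(base_speed_range) != 2 || any(base_speed_range <= 0) ||
      diff(base_speed_range) < 0) {
    abort_config("`base_speed_range` must be a positive increasing pair.")
  }
  if (periodic_amplitude_frac < 0 || periodic_amplitude_frac >= 1) {
    abort_config("`periodic_amplitude_frac` must be in [0, 1).")
  }
  if (impulse_prob < 0 || impulse_prob > 1) {
    abort_config("`impulse_prob` must be in [0, 1].")
  }
  for (nm in c("heading_jitter_sd", "gaussian_pos_noise_sd", "impulse_sd")) {
    if (get(nm) < 0) abort_config(sprintf("`%s` must be >= 0.", nm))
  }
  structure(
    list(
      n_tracks = as.integer(n_tracks), n_frames = as.integer(n_frames),
      profile = profile, base_speed_range = base_speed_range,
      periodic_amplitude_frac = periodic_amplitude_frac,
      periodic_period_range = periodic_period_range,
      heading_jitter_sd = heading_jitter_sd,
      gaussian_pos_noise_sd = gaussian_pos_noise_sd,
      impulse_prob = impulse_prob, impulse_sd = impulse_sd,
      seed = seed
    ),
    class = "track_sim_config"
  )
}

# True positions of one track given its per-interval speeds and headings.
integrate_positions <- function(speeds, headings, origin = c(0, 0)) {
  x <- origin[1] + cumsum(c(0, speeds * cos(headings)))
  y <- origin[2] + cumsum(c(0, speeds * sin(headings)))
  cbind(x, y)
}

#' Simulate noisy filament tracks with ground truth
#'
#' Generates `config$n_tracks` independent 2D tracks. Per track, a base speed
#' and (for periodic tracks) a modulation period and phase are drawn; the
#' true trajectory is integrated with a slowly wandering heading, so the true
#' per-interval speed equals the assigned speed profile exactly. Measured
#' positions add per-axis Gaussian noise; with probability
#' `config$impulse_prob` a point's noise is replaced by a large-SD impulse.
#'
#' @param config A [track_sim_config()].
#' @return A list of class `ivma_track_sim` with elements
#'   * `tracks`: noisy track table (`track_id`, `frame`, `x`, `y`),
#'   * `truth_tracks`: noise-free positions in the same layout,
#'   * `truth_speeds`: per-interval true speed (`track_id`, `interval`,
#'     `speed`, `variant = "true"`, `units = "px/frame"`),
#'   * `config`.
#' @examples
#' sim <- simulate_tracks(track_sim_config(n_tracks = 2, seed = 1))
#' sim$truth_speeds
#' @export
simulate_tracks <- function(config = track_sim_config()) {
  if (!inherits(config, "track_sim_config")) {
    abort_config("`config` must be created with track_sim_config().")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n_int <- config$n_frames - 1L
  one_track <- function(i) {
    base <- stats::runif(1, config$base_speed_range[1], config$base_speed_range[2])
    prof <- switch(config$profile,
      mixed = sample(c("constant", "periodic"), 1),
      config$profile
    )
    speeds <- if (prof == "constant") {
      rep(base, n_int)
    } else {
      period <- stats::runif(1, config$periodic_period_range[1],
                             config$periodic_period_range[2])
      phi <- stats::runif(1, 0, 2 * pi)
      base * (1 + config$periodic_amplitude_frac *
                sin(2 * pi * seq_len(n_int) / period + phi))
    }
    headings <- cumsum(c(stats::runif(1, 0, 2 * pi),
                         stats::rnorm(n_int - 1L, 0, config$heading_jitter_sd)))
    pos <- integrate_positions(speeds, headings)
    noise <- matrix(stats::rnorm(2L * config$n_frames, 0, config$gaussian_pos_noise_sd),
                    ncol = 2)
    impulse <- stats::runif(config$n_frames) < config$impulse_prob
    if (any(impulse)) {
      noise[impulse, ] <- stats::rnorm(2L * sum(impulse), 0, config$impulse_sd)
    }
    list(
      tracks = tibble::tibble(
        track_id = as.character(i), frame = 0:(config$n_frames - 1L),
        x = pos[, 1] + noise[, 1], y = pos[, 2] + noise[, 2]
      ),
      truth_tracks = tibble::tibble(
        track_id = as.character(i), frame = 0:(config$n_frames - 1L),
        x = pos[, 1], y = pos[, 2]
      ),
      truth_speeds = tibble::tibble(
        track_id = as.character(i), interval = 0:(n_int - 1L),
        speed = speeds, variant = "true", units = "px/frame"
      )
    )
  }
  parts <- purrr::map(seq_len(config$n_tracks), one_track)
  structure(
    list(
      tracks = purrr::map_dfr(parts, "tracks"),
      truth_tracks = purrr::map_dfr(parts, "truth_tracks"),
      truth_speeds = purrr::map_dfr(parts, "truth_speeds"),
      config = config
    ),
    class = "ivma_track_sim"
  )
}
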