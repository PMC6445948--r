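# Split-and-merge phase identification: partition a reconstructed velocity
# series into phases of statistically homogeneous velocity.
#
# The series is first smoothed with a 1D Gaussian and split at all local
# maxima of the smoothed signal; adjacent fractions are then merged
# left-to-right whenever a Welch t-test on the *reconstructed* (unsmoothed)
# values finds no significant difference; finally phases shorter than a
# minimum length are discarded as outliers.

#' Parameters of the split-and-merge phase identification
#'
#' @param smooth_sigma Standard deviation, in frame intervals, of the 1D
#'   Gaussian used to smooth the velocity signal before locating split
#'   points (default 3). The smoothed signal is used *only* for splitting;
#'   all tests and phase statistics use the unsmoothed input values.
#' @param alpha Significance level of the sequential Welch t-tests: adjacent
#'   fractions with p > `alpha` are merged (default 0.05).
#' @param min_phase_frames Minimum phase duration in frame intervals; shorter
#'   phases are discarded (default 10, i.e. one second at 10 frames/s).
#' @param frame_interval Seconds per frame, used to report phase durations in
#'   seconds (default 0.1).
#' @return A `phase_params` object.
#' @export
phase_params <- function(smooth_sigma = 3, alpha = 0.05, min_phase_frames = 10,
                         frame_interval = 0.1) {
  check_scalar_positive(smooth_sigma, "smooth_sigma")
  check_scalar_positive(frame_interval, "frame_interval")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort_validation("`alpha` must be in (0, 1].")
  }
  if (!is.numeric(min_phase_frames) || min_phase_frames < 1) {
    abort_validation("`min_phase_frames` must be >= 1.")
  }
  structure(
    list(
      smooth_sigma = smooth_sigma, alpha = alpha,
      min_phase_frames = as.integer(min_phase_frames),
      frame_interval = frame_interval
    ),
    class = "phase_params"
  )
}

# Non-maximum suppression: keep an extremum only if no stronger one lies
# within `w` indices. The smoothing kernel cannot resolve two events closer
# than its own support, so nearby extrema are one event; ties keep both.
suppress_non_max <- function(idx, strength, w) {
  if (length(idx) < 2L) return(idx)
  keep <- vapply(seq_along(idx), function(k) {
    near <- abs(idx - idx[k]) <= w & seq_along(idx) != k
    all(strength[k] >= strength[near])
  }, logical(1))
  idx[keep]
}

# Local maxima (0-based interior indices) of the smoothed values of one
# series; plateaus contribute their first index only.
local_maxima_indices <- function(smoothed) {
  n <- length(smoothed)
  i <- 2:(n - 1L)
  i[smoothed[i - 1L] < smoothed[i] & smoothed[i] >= smoothed[i + 1L]] - 1L
}

# Steepest-change ridge points: strict local maxima of |diff(smoothed)|,
# mapped to the index of the first value after the change. Local maxima of
# the signal delimit decelerations well, but an acceleration has no maximum
# at its onset; the gradient ridge supplies that boundary. Ties (exact
# plateaus of the gradient, e.g. straight ramps) contribute nothing, so a
# strictly monotone or triangular signal gains no extra split points.
gradient_ridge_indices <- function(smoothed) {
  d <- abs(diff(smoothed))
  m <- length(d)
  if (m < 3L) return(integer(0))
  # strictness up to float rounding, so exactly linear ramps contribute nothing
  tol <- 1e-8 * max(d, 0)
  j <- 2:(m - 1L)
  j[d[j - 1L] < d[j] - tol & d[j] > d[j + 1L] + tol]
}

split_indices <- function(smoothed, sigma) {
  w <- max(1L, floor(4 * sigma)) # the truncation radius of the kernel
  mx <- local_maxima_indices(smoothed)
  mx <- suppress_non_max(mx, smoothed[mx + 1L], w)
  rg <- gradient_ridge_indices(smoothed)
  rg <- suppress_non_max(rg, abs(diff(smoothed))[rg], w)
  sort(unique(c(mx, rg)))
}

#' Split a velocity series at local maxima of its smoothed signal
#'
#' Smooths each track's speed signal with a Gaussian of SD
#' `params$smooth_sigma` intervals (kernel truncated at 4 sigma, reflect
#' padding) and returns split points of two kinds: interior indices where the
#' smoothed signal has a local maximum (`s[i-1] < s[i] >= s[i+1]`; a plateau
#' counts once, at its first index), and steepest-change points, the strict
#' local maxima of the absolute first difference of the smoothed signal.
#' Maxima delimit decelerations; the steepest-change points place a boundary
#' at the onset of accelerations, which have no local maximum of their own.
#' Within each family, an extremum is kept only if no stronger one lies
#' within the kernel truncation radius (4 sigma): the smoothing cannot
#' resolve two events closer than its own support. Over-splitting is
#' harmless: [merge_fractions()] reabsorbs adjacent fractions with
#' indistinguishable velocity. The boundaries partition each series of
#' length n into fractions covering `[0, n)`.
#'
#' @inheritParams apply_filter
#' @param params A [phase_params()].
#' @return A tibble with columns `track_id` and `boundary` (0-based index
#'   into that track's velocity series).
#' @export
split_at_local_maxima <- function(speeds, params = phase_params()) {
  speeds <- validate_speeds(speeds)
  if (!inherits(params, "phase_params")) {
    abort_validation("`params` must be created with phase_params().")
  }
  sizes <- dplyr::count(speeds, .data$track_id)
  if (nrow(sizes) == 0 || any(sizes$n < 3)) {
    abort_insufficient("every series needs at least 3 values to be split.")
  }
  speeds |>
    dplyr::group_by(.data$track_id) |>
    dplyr::reframe(
      boundary = split_indices(gaussian_smooth(.data$speed, params$smooth_sigma),
                               params$smooth_sigma)
    )
}

# One left-to-right sequential merge pass over cut points (0-based, including
# 0 and n). Returns the surviving cut points.
merge_pass <- function(values, cuts, alpha) {
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1]
  kept <- cuts[1]
  cur_start <- starts[1]
  cur_end <- ends[1]
  for (k in seq_along(starts)[-1]) {
    cur_vals <- values[(cur_start + 1L):cur_end]
    nxt_vals <- values[(starts[k] + 1L):ends[k]]
    p <- welch_p(cur_vals, nxt_vals)
    # fractions too short to test carry no variance information: merge
    if (is.na(p) || p > alpha) {
      cur_end <- ends[k]
    } else {
      kept <- c(kept, cur_end)
      cur_start <- starts[k]
      cur_end <- ends[k]
    }
  }
  c(kept, cur_end)
}

# Merging of one track's fractions: the sequential pass is iterated until no
# boundary disappears. A single pass can close a segment early (a small,
# locally atypical fraction rejects against a long homogeneous segment); the
# next pass re-tests the resulting adjacent segments with their full samples
# and absorbs such splits, while genuinely different phases keep p below
# alpha. Returns a list of c(start, end) half-open 0-based index pairs.
merge_segments <- function(values, bounds, alpha) {
  n <- length(values)
  cuts <- unique(c(0L, sort(unique(as.integer(bounds))), n))
  if (any(cuts < 0L) || any(cuts > n)) {
    abort_validation("boundary indices must lie in (0, n).")
  }
  repeat {
    new_cuts <- merge_pass(values, cuts, alpha)
    if (length(new_cuts) == length(cuts)) break
    cuts <- new_cuts
  }
  purrr::map(seq_len(length(cuts) - 1L), function(k) c(cuts[k], cuts[k + 1L]))
}

phase_row <- function(track_speeds, start, end, params) {
  vals <- track_speeds$speed[(start + 1L):end]
  tibble::tibble(
    start = start,
    end = end,
    start_frame = track_speeds$interval[start + 1L],
    end_frame = track_speeds$interval[end] + 1L,
    duration_frames = end - start,
    duration_s = (end - start) * params$frame_interval,
    mean_velocity = mean(vals),
    sd_velocity = stats::sd(vals)
  )
}

#' Merge adjacent fractions into velocity phases
#'
#' Starting from the first fraction, a Welch two-sample t-test compares the
#' values of the current segment with those of the next fraction; if they are
#' not significantly different (p > `alpha`) the fraction is absorbed and
#' testing continues, otherwise the segment is closed as a phase and the next
#' fraction starts a new segment. Fractions with fewer than 2 values cannot
#' be tested and are absorbed unconditionally. The test uses the (typically
#' Kalman-reconstructed) values in `speeds`, not the smoothed signal used for
#' splitting.
#'
#' @inheritParams split_at_local_maxima
#' @param boundaries A tibble of split points as returned by
#'   [split_at_local_maxima()].
#' @return A phase table: one row per phase with columns `track_id`, `phase`
#'   (1-based index within track), `start`, `end` (half-open 0-based interval
#'   indices), `start_frame`, `end_frame`, `duration_frames`, `duration_s`,
#'   `mean_velocity`, `sd_velocity`.
#' @export
merge_fractions <- function(speeds, boundaries, params = phase_params()) {
  speeds <- validate_speeds(speeds)
  if (!inherits(params, "phase_params")) {
    abort_validation("`params` must be created with phase_params().")
  }
  ids <- unique(speeds$track_id)
  purrr::map_dfr(ids, function(id) {
    tr <- speeds[speeds$track_id == id, ]
    b <- boundaries$boundary[boundaries$track_id == id]
    segs <- merge_segments(tr$speed, b, params$alpha)
    rows <- purrr::map_dfr(segs, function(se) phase_row(tr, se[1], se[2], params))
    dplyr::bind_cols(
      tibble::tibble(track_id = id, phase = seq_len(nrow(rows))), rows
    )
  })
}

#' Discard phases shorter than the minimum duration
#'
#' Removes phases with `duration_frames < params$min_phase_frames` (default
#' 10 intervals, one second at 10 frames/s). Remaining phases are unchanged;
#' no re-merging happens across removed phases.
#'
#' @param phases A phase table from [merge_fractions()] or
#'   [identify_phases()].
#' @inheritParams split_at_local_maxima
#' @return The filtered phase table (possibly empty).
#' @export
drop_short_phases <- function(phases, params = phase_params()) {
  if (!inherits(params, "phase_params")) {
    abort_validation("`params` must be created with phase_params().")
  }
  dplyr::filter(phases, .data$duration_frames >= params$min_phase_frames)
}

#' Identify velocity phases by split-and-merge
#'
#' Composition of [split_at_local_maxima()], [merge_fractions()] and
#' [drop_short_phases()]: partitions each track's velocity signal into
#' contiguous phases of statistically homogeneous velocity, then discards
#' phases shorter than the minimum length.
#'
#' @inheritParams split_at_local_maxima
#' @return A phase table (see [merge_fractions()]); may be empty if no phase
#'   reaches the minimum duration.
#' @examples
#' tr <- tibble::tibble(track_id = "a", frame = 0:60,
#'                      x = cumsum(c(0, rep(c(5, 2), each = 30))), y = 0)
#' identify_phases(compute_speed(tr), phase_params(min_phase_frames = 5))
#' @export
identify_phases <- function(speeds, params = phase_params()) {
  boundaries <- split_at_local_maxima(speeds, params)
  phases <- merge_fractions(speeds, boundaries, params)
  drop_short_phases(phases, params)
}
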