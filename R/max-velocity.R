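# The top-fraction phase-velocity statistic: the maximum sliding velocity is
# the mean of the fastest phase velocities whose sum reaches a fixed fraction
# (default 10%) of the total sum of all phase velocities.

#' Maximum velocity from a set of phases
#'
#' Sorts the phase mean velocities in decreasing order and accumulates them
#' from the fastest until the running sum reaches `fraction` of the total sum
#' \eqn{v_{sum} = \sum_i v_i}; the phase that crosses the threshold is
#' included. The maximum velocity is the mean of the selected phase
#' velocities. Phases are pooled across tracks, so applying this to all
#' tracks of an image sequence summarises the sequence. Ties in velocity are
#' broken by earlier start frame, then track id.
#'
#' @param phases A non-empty phase table (see [identify_phases()]) with at
#'   least one positive `mean_velocity`.
#' @param fraction Selection threshold in (0, 1]; default 0.10.
#' @param weight_by_duration If `TRUE`, the selected velocities are averaged
#'   weighted by `duration_frames` instead of the default unweighted mean.
#' @return A `max_velocity_result`: a list with `v_max`, `v_sum`, `fraction`,
#'   `n_selected`, `n_phases_total` and the tibble of `selected` phases.
#'   Use [tidy()] for the selected phases and [glance()] for the one-row
#'   summary.
#' @examples
#' phases <- tibble::tibble(
#'   track_id = "a", phase = 1:4, start_frame = c(0, 20, 40, 60),
#'   duration_frames = 20, mean_velocity = c(10, 5, 3, 2)
#' )
#' max_velocity(phases)  # v_sum = 20, threshold 2 -> one phase, v_max = 10
#' @export
max_velocity <- function(phases, fraction = 0.10, weight_by_duration = FALSE) {
  if (!is.data.frame(phases)) {
    abort_validation("`phases` must be a data frame of phases.")
  }
  if (nrow(phases) == 0) {
    abort_no_phases("no phases to summarise; was every phase shorter than the minimum length?")
  }
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort_validation("`fraction` must be in (0, 1].")
  }
  v <- phases$mean_velocity
  if (any(!is.finite(v)) || any(v < 0)) {
    abort_validation("phase mean velocities must be finite and >= 0.")
  }
  if (all(v == 0)) {
    abort_degenerate("all phase velocities are zero; maximum velocity is undefined.")
  }
  ord <- order(-v, phases$start_frame, phases$track_id)
  sorted <- phases[ord, ]
  v_sum <- sum(v)
  threshold <- fraction * v_sum
  csum <- cumsum(sorted$mean_velocity)
  n_sel <- which(csum >= threshold - 1e-12)[1]
  selected <- sorted[seq_len(n_sel), ]
  v_max <- if (weight_by_duration) {
    stats::weighted.mean(selected$mean_velocity, selected$duration_frames)
  } else {
    mean(selected$mean_velocity)
  }
  structure(
    list(
      v_max = v_max,
      v_sum = v_sum,
      fraction = fraction,
      n_selected = n_sel,
      n_phases_total = nrow(phases),
      weight_by_duration = weight_by_duration,
      selected = tibble::as_tibble(selected)
    ),
    class = "max_velocity_result"
  )
}

#' Phase-velocity distribution
#'
#' Orders a phase table by decreasing mean velocity — the distribution of
#' phase velocities of an image sequence, suitable for histogram export.
#'
#' @inheritParams max_velocity
#' @return The phase table sorted by decreasing `mean_velocity` (ties broken
#'   by start frame, then track id).
#' @export
phase_velocity_distribution <- function(phases) {
  if (!is.data.frame(phases)) {
    abort_validation("`phases` must be a data frame of phases.")
  }
  phases <- tibble::as_tibble(phases)
  if (nrow(phases) == 0) return(phases)
  phases[order(-phases$mean_velocity, phases$start_frame, phases$track_id), ]
}

#' @export
print.max_velocity_result <- function(x, ...) {
  cat(sprintf(
    "<max_velocity_result> v_max = %.4g (%d of %d phases; fraction %.2g of v_sum = %.4g)\n",
    x$v_max, x$n_selected, x$n_phases_total, x$fraction, x$v_sum
  ))
  invisible(x)
}

#' @rdname max_velocity
#' @param x A `max_velocity_result`.
#' @param ... Unused.
#' @method tidy max_velocity_result
#' @export
tidy.max_velocity_result <- function(x, ...) {
  x$selected
}

#' @rdname max_velocity
#' @method glance max_velocity_result
#' @export
glance.max_velocity_result <- function(x, ...) {
  tibble::tibble(
    v_max = x$v_max,
    v_sum = x$v_sum,
    fraction = x$fraction,
    n_selected = x$n_selected,
    n_phases_total = x$n_phases_total
  )
}
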