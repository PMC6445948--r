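# Reconstruction performance measure and the seven-filter benchmark.

#' Coefficient of determination of a reconstructed velocity signal
#'
#' Measures how much a filter reduces the deviation from the true signal
#' relative to the unfiltered signal:
#' \deqn{R^2 = 1 - SSE_{filter} / SSE_{total}}
#' with \eqn{SSE_{total} = \sum_i (v_i - v_{i,true})^2} for the raw signal
#' and \eqn{SSE_{filter} = \sum_i (v_{i,filtered} - v_{i,true})^2}. A perfect
#' reconstruction gives 1; an identity "filter" gives 0; a filter that makes
#' things worse gives a negative value.
#'
#' @param raw,filtered,truth Numeric vectors of equal length (or velocity
#'   tables with a `speed` column, from which the values are taken in order).
#' @return An `r2_result`: list with `r2`, `sse_total`, `sse_filter`.
#' @examples
#' r_squared(raw = c(1, 3), filtered = c(1.5, 2.5), truth = c(2, 2))$r2 # 0.75
#' @export
r_squared <- function(raw, filtered, truth) {
  as_values <- function(v, name) {
    if (is.data.frame(v)) v <- v$speed
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort_validation(sprintf("`%s` must be finite numeric.", name))
    }
    v
  }
  raw <- as_values(raw, "raw")
  filtered <- as_values(filtered, "filtered")
  truth <- as_values(truth, "truth")
  n <- length(raw)
  if (n < 1 || length(filtered) != n || length(truth) != n) {
    abort_validation("`raw`, `filtered` and `truth` must have equal length >= 1.")
  }
  sse_total <- sum((raw - truth)^2)
  sse_filter <- sum((filtered - truth)^2)
  if (sse_total == 0) {
    abort_degenerate("raw signal equals the true signal; R^2 is undefined.")
  }
  structure(
    list(r2 = 1 - sse_filter / sse_total, sse_total = sse_total,
         sse_filter = sse_filter),
    class = "r2_result"
  )
}

#' @export
print.r2_result <- function(x, ...) {
  cat(sprintf("<r2_result> R^2 = %.4f (SSE_filter %.4g / SSE_total %.4g)\n",
              x$r2, x$sse_filter, x$sse_total))
  invisible(x)
}

#' The seven benchmark filters with their default parameters
#'
#' @return A named list of [filter_spec()] objects: `kalman`, `mean`,
#'   `gaussian`, `median`, `kz`, `sg`, `spencer`.
#' @export
default_filter_specs <- function() {
  kinds <- c("kalman", "mean", "gaussian", "median", "kz", "sg", "spencer")
  stats::setNames(lapply(kinds, filter_spec), kinds)
}

# R^2 of one filter on one simulated dataset; NA if the series is too short
# for the filter's window.
benchmark_one <- function(noisy_track, raw, truth, spec, cal) {
  filtered <- if (spec$kind == "kalman") {
    kalman_reconstruct(noisy_track, cal,
                       q = spec$params$q, r = spec$params$r)$speed
  } else {
    tryCatch(
      apply_filter_values(raw, spec),
      ivmax_insufficient_data = function(e) NULL
    )
  }
  if (is.null(filtered)) return(NA_real_)
  r_squared(raw, filtered, truth)$r2
}

#' Benchmark signal-reconstruction filters on simulated tracks
#'
#' Generates `config$n_tracks` synthetic tracks with known true speed and
#' evaluates each filter's reconstruction quality by the mean
#' [r_squared()] across datasets. The Kalman filter consumes the noisy
#' positions; all other filters are 1D filters applied to the raw speed
#' series. Datasets shorter than a filter's window are skipped for that
#' filter (with a warning) and counted in `n_skipped`.
#'
#' @param config A [track_sim_config()]; set `config$seed` for
#'   reproducibility.
#' @param specs A named list of [filter_spec()]s (default: the seven
#'   benchmark filters).
#' @return A tibble of class `filter_benchmark`, one row per filter:
#'   `kind`, `mean_r2`, `sd_r2`, `n_datasets`, `n_skipped`, sorted by
#'   decreasing `mean_r2`.
#' @examples
#' \donttest{
#' benchmark_filters(track_sim_config(n_tracks = 20, seed = 1))
#' }
#' @export
benchmark_filters <- function(config = track_sim_config(),
                              specs = default_filter_specs()) {
  if (length(specs) == 0) abort_config("`specs` must be non-empty.")
  if (config$n_tracks < 2) {
    abort_config("need at least 2 datasets for a mean and SD.")
  }
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "filter_spec")) abort_spec("all specs must be filter_spec objects.")
    s
  })
  if (is.null(names(specs)) || anyNA(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, `[[`, character(1), "kind")
  }
  sim <- simulate_tracks(config)
  cal <- calibration(1, 1)
  ids <- unique(sim$tracks$track_id)
  r2 <- matrix(NA_real_, nrow = length(ids), ncol = length(specs),
               dimnames = list(ids, names(specs)))
  for (i in seq_along(ids)) {
    noisy <- sim$tracks[sim$tracks$track_id == ids[i], ]
    raw <- compute_speed(noisy, cal)$speed
    truth <- sim$truth_speeds$speed[sim$truth_speeds$track_id == ids[i]]
    for (j in seq_along(specs)) {
      r2[i, j] <- benchmark_one(noisy, raw, truth, specs[[j]], cal)
    }
  }
  skipped <- colSums(is.na(r2))
  if (any(skipped > 0)) {
    rlang::warn(sprintf(
      "%d dataset/filter combinations skipped (series shorter than window).",
      sum(skipped)
    ))
  }
  out <- tibble::tibble(
    kind = names(specs),
    mean_r2 = unname(colMeans(r2, na.rm = TRUE)),
    sd_r2 = unname(apply(r2, 2, stats::sd, na.rm = TRUE)),
    n_datasets = as.integer(unname(colSums(!is.na(r2)))),
    n_skipped = as.integer(unname(skipped))
  )
  out <- out[order(-out$mean_r2), ]
  class(out) <- c("filter_benchmark", class(out))
  out
}
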