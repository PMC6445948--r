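# The scalar signal filters of the reconstruction benchmark. All windowed
# filters use odd symmetric windows and reflect padding, so outputs have the
# same length as inputs and every linear kernel has unit DC gain.

filter_kinds <- c("mean", "gaussian", "median", "kz", "sg", "spencer", "kalman")

# Classic 15-point Spencer smoothing weights (sum to 1).
spencer_weights <- c(-3, -6, -5, 3, 21, 46, 67, 74, 67, 46, 21, 3, -5, -6, -3) / 320

#' Specify a velocity-signal filter
#'
#' Builds the description of one of the seven filters compared in the
#' reconstruction benchmark. Parameters not supplied take the benchmark
#' defaults (windows of about one second at 10 frames/s):
#'
#' * `mean`: centered moving average, `window = 9`
#' * `gaussian`: discrete Gaussian kernel, `sigma = 2` intervals, truncated
#'   at 4 sigma
#' * `median`: centered running median, `window = 9`
#' * `kz`: Kolmogorov-Zurbenko filter, `window = 5` iterated
#'   `iterations = 3` times
#' * `sg`: Savitzky-Golay local polynomial, `window = 9`, `order = 2`
#' * `spencer`: the fixed 15-point Spencer smoother
#' * `kalman`: constant-velocity Kalman filter on positions, `q = 0.5`,
#'   `r = 1` (consumed by [kalman_reconstruct()], not [apply_filter()])
#'
#' @param kind One of `"mean"`, `"gaussian"`, `"median"`, `"kz"`, `"sg"`,
#'   `"spencer"`, `"kalman"`.
#' @param window Odd window length (>= 3) for windowed filters.
#' @param sigma Kernel standard deviation, in intervals, for the Gaussian.
#' @param order Polynomial order for Savitzky-Golay (< `window`).
#' @param iterations Number of moving-average passes for Kolmogorov-Zurbenko.
#' @param q,r Kalman process/measurement noise (see [kalman_reconstruct()]).
#' @return A `filter_spec` object.
#' @examples
#' filter_spec("mean", window = 5)
#' filter_spec("kalman", q = 0.1)
#' @export
filter_spec <- function(kind, window = NULL, sigma = NULL, order = NULL,
                        iterations = NULL, q = NULL, r = NULL) {
  if (length(kind) != 1L || !kind %in% filter_kinds) {
    abort_spec(sprintf(
      "unknown filter kind '%s'; must be one of %s",
      paste(kind, collapse = ","), paste(filter_kinds, collapse = ", ")
    ))
  }
  params <- switch(kind,
    mean = list(window = window %||% 9L),
    gaussian = list(sigma = sigma %||% 2),
    median = list(window = window %||% 9L),
    kz = list(window = window %||% 5L, iterations = iterations %||% 3L),
    sg = list(window = window %||% 9L, order = order %||% 2L),
    spencer = list(window = 15L),
    kalman = list(q = q %||% 0.5, r = r %||% 1)
  )
  if (!is.null(params$window)) {
    w <- params$window
    if (!is.numeric(w) || w < 3 || w %% 2 != 1) {
      abort_spec("`window` must be an odd integer >= 3.")
    }
    params$window <- as.integer(w)
  }
  if (!is.null(params$sigma) && (!is.numeric(params$sigma) || params$sigma <= 0)) {
    abort_spec("`sigma` must be > 0.")
  }
  if (!is.null(params$iterations)) {
    if (!is.numeric(params$iterations) || params$iterations < 1) {
      abort_spec("`iterations` must be >= 1.")
    }
    params$iterations <- as.integer(params$iterations)
  }
  if (kind == "sg" && params$order >= params$window) {
    abort_spec("Savitzky-Golay `order` must be smaller than `window`.")
  }
  structure(list(kind = kind, params = params), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  pars <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<filter_spec> %s (%s)\n", x$kind, pars))
  invisible(x)
}

# Effective window length a series must reach for a spec to be applicable.
filter_window <- function(spec) {
  switch(spec$kind,
    gaussian = 2L * floor(4 * spec$params$sigma) + 1L,
    kalman = 4L, # minimum track points, handled by kalman_reconstruct
    spec$params$window
  )
}

# Symmetric convolution kernel of a linear spec (mean/gaussian/sg/spencer).
filter_kernel <- function(spec) {
  switch(spec$kind,
    mean = rep(1 / spec$params$window, spec$params$window),
    gaussian = gaussian_kernel(spec$params$sigma),
    sg = {
      w <- spec$params$window
      as.numeric(signal::sgolay(p = spec$params$order, n = w)[(w + 1L) %/% 2L, ])
    },
    spencer = spencer_weights,
    abort_spec(sprintf("'%s' has no convolution kernel.", spec$kind))
  )
}

running_median <- function(v, window) {
  r <- (window - 1L) %/% 2L
  p <- reflect_pad(v, r)
  vapply(seq_along(v), function(i) stats::median(p[i:(i + 2L * r)]), numeric(1))
}

apply_filter_values <- function(v, spec) {
  if (length(v) < filter_window(spec)) {
    abort_insufficient(sprintf(
      "series of length %d is shorter than the %s filter window (%d).",
      length(v), spec$kind, filter_window(spec)
    ))
  }
  switch(spec$kind,
    median = running_median(v, spec$params$window),
    kz = {
      k <- rep(1 / spec$params$window, spec$params$window)
      for (i in seq_len(spec$params$iterations)) v <- convolve_centered(v, k)
      v
    },
    convolve_centered(v, filter_kernel(spec))
  )
}

#' Apply a scalar signal filter to a velocity series
#'
#' Filters the per-interval speed signal of each track with one of the
#' benchmark's 1D filters. All filters return a series of the same length as
#' the input (reflect padding at the edges). The Kalman filter is not a
#' scalar filter — it consumes positions; use [kalman_reconstruct()].
#'
#' @param speeds A velocity table as returned by [compute_speed()]
#'   (columns `track_id`, `interval`, `speed`, ...).
#' @param spec A [filter_spec()] with `kind != "kalman"`.
#' @return The velocity table with filtered `speed` and
#'   `variant = "filtered"`.
#' @export
apply_filter <- function(speeds, spec) {
  if (!inherits(spec, "filter_spec")) {
    abort_spec("`spec` must be created with filter_spec().")
  }
  if (spec$kind == "kalman") {
    abort_spec(
      "the Kalman filter consumes positions, not speeds; use kalman_reconstruct()."
    )
  }
  speeds <- validate_speeds(speeds)
  speeds |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(speed = apply_filter_values(.data$speed, spec)) |>
    dplyr::ungroup() |>
    dplyr::mutate(variant = "filtered")
}

# Minimal structural validation of a velocity table.
validate_speeds <- function(speeds) {
  if (!is.data.frame(speeds)) {
    abort_validation("`speeds` must be a data frame.")
  }
  need <- c("track_id", "interval", "speed")
  missing_cols <- setdiff(need, names(speeds))
  if (length(missing_cols) > 0) {
    abort_format(sprintf(
      "velocity table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(speeds) > 0 && any(!is.finite(speeds$speed))) {
    abort_validation("`speed` must be finite.")
  }
  tibble::as_tibble(speeds)
}
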