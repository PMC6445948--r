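# Internal helpers: classed conditions and small numerical utilities.

ivmax_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ivmax_error"), ...)
}

abort_format <- function(msg, ...) ivmax_abort(msg, "ivmax_format_error", ...)
abort_parse <- function(msg, ...) ivmax_abort(msg, "ivmax_parse_error", ...)
abort_validation <- function(msg, ...) ivmax_abort(msg, "ivmax_validation_error", ...)
abort_insufficient <- function(msg, ...) ivmax_abort(msg, "ivmax_insufficient_data", ...)
abort_spec <- function(msg, ...) ivmax_abort(msg, "ivmax_spec_error", ...)
abort_config <- function(msg, ...) ivmax_abort(msg, "ivmax_config_error", ...)
abort_model <- function(msg, ...) ivmax_abort(msg, "ivmax_model_error", ...)
abort_io <- function(msg, ...) ivmax_abort(msg, "ivmax_io_error", ...)
abort_degenerate <- function(msg, ...) ivmax_abort(msg, "ivmax_degenerate_input", ...)
abort_no_phases <- function(msg, ...) ivmax_abort(msg, "ivmax_no_phases_error", ...)

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_validation(sprintf("`%s` must be a single finite number > 0.", name))
  }
  invisible(x)
}

# Mirror (reflect-without-repeat) padding: needs r <= length(v) - 1.
reflect_pad <- function(v, r) {
  n <- length(v)
  if (r == 0L) return(v)
  if (r > n - 1L) {
    abort_insufficient(sprintf(
      "series of length %d too short for padding radius %d", n, r
    ))
  }
  c(v[(r + 1L):2L], v, v[(n - 1L):(n - r)])
}

# Centered convolution with a symmetric odd-length kernel, reflect padding,
# same-length output.
convolve_centered <- function(v, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  p <- reflect_pad(v, r)
  vapply(seq_along(v), function(i) sum(kernel * p[i:(i + 2L * r)]), numeric(1))
}

# Discrete Gaussian kernel truncated at 4*sigma (radius clamped so reflect
# padding remains valid for short series).
gaussian_kernel <- function(sigma, max_radius = Inf) {
  r <- min(floor(4 * sigma), max_radius)
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w / sum(w)
}

gaussian_smooth <- function(v, sigma) {
  k <- gaussian_kernel(sigma, max_radius = length(v) - 1L)
  convolve_centered(v, k)
}

# Welch two-sample t-test p-value with degenerate-data fallbacks.
# Returns NA when either sample has < 2 values (caller decides the policy).
welch_p <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if ((vx + vy) < 1e-24) {
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  }
  tryCatch(
    stats::t.test(x, y)$p.value,
    error = function(e) if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0
  )
}
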