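# Split-and-merge phase identification.

# Independent smoothing + neighbour-scan oracle used by the split tests:
# direct Gaussian convolution with mirror padding, exhaustive scans for local
# maxima of the signal and strict local maxima of |diff(signal)|, and an
# exhaustive strongest-within-radius filter per family.
oracle_split <- function(v, sigma) {
  r <- min(floor(4 * sigma), length(v) - 1)
  w <- dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  p <- c(v[(r + 1):2], v, v[(length(v) - 1):(length(v) - r)])
  s <- vapply(seq_along(v), function(i) sum(w * p[i:(i + 2 * r)]), numeric(1))
  strongest <- function(idx, str, rad) {
    ok <- rep(TRUE, length(idx))
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a != b && abs(idx[a] - idx[b]) <= rad && str[a] < str[b]) ok[a] <- FALSE
      }
    }
    idx[ok]
  }
  mx <- integer(0)
  for (i in 2:(length(s) - 1)) {
    if (s[i - 1] < s[i] && s[i] >= s[i + 1]) mx <- c(mx, i - 1L) # 0-based
  }
  d <- abs(diff(s))
  tol <- 1e-8 * max(d)
  rg <- integer(0)
  for (j in 2:(length(d) - 1)) {
    if (d[j - 1] < d[j] - tol && d[j] > d[j + 1] + tol) rg <- c(rg, j) # onset
  }
  rad <- max(1, floor(4 * sigma))
  sort(unique(c(strongest(mx, s[mx + 1], rad), strongest(rg, d[rg], rad))))
}

test_that("splitting finds local maxima of the smoothed signal", {
  p <- phase_params(smooth_sigma = 1)
  # strictly monotone series: no interior maxima, a single fraction
  mono <- speed_series(seq(1, 5, length.out = 40))
  expect_equal(nrow(split_at_local_maxima(mono, p)), 0L)

  # symmetric triangle peaking at index 20 (small sigma keeps the peak put)
  tri <- speed_series(c(seq(0, 2, length.out = 21), seq(1.9, 0, length.out = 20)))
  b <- split_at_local_maxima(tri, phase_params(smooth_sigma = 0.5))
  expect_equal(b$boundary, 20L)

  # noisy fixture: boundary set equals the exhaustive scan
  set.seed(7)
  v <- 5 + rnorm(100, 0, 0.5)
  got <- split_at_local_maxima(speed_series(v), phase_params(smooth_sigma = 3))
  expect_equal(got$boundary, oracle_split(v, 3))

  expect_error(split_at_local_maxima(speed_series(c(1, 2)), p),
               class = "ivmax_insufficient_data")
})

test_that("fractions merge when a Welch t-test finds no difference", {
  pars <- phase_params(min_phase_frames = 1)
  # equal means, tiny noise: p >> 0.05 -> one phase
  set.seed(1)
  same <- speed_series(c(5 + rnorm(20, 0, 0.01), 5 + rnorm(20, 0, 0.01)))
  merged <- merge_fractions(same, tibble::tibble(track_id = "a", boundary = 20L), pars)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 0L)
  expect_equal(merged$end, 40L)

  # well separated means stay apart, statistics recomputable
  set.seed(2)
  vals <- c(2 + rnorm(20, 0, 0.5), 8 + rnorm(20, 0, 0.5))
  apart <- merge_fractions(speed_series(vals),
                           tibble::tibble(track_id = "a", boundary = 20L), pars)
  expect_equal(nrow(apart), 2L)
  expect_equal(apart$mean_velocity, c(mean(vals[1:20]), mean(vals[21:40])))
  expect_equal(apart$sd_velocity, c(sd(vals[1:20]), sd(vals[21:40])))

  # alpha = 1: p <= 1 always, so nothing merges
  pars1 <- phase_params(alpha = 1, min_phase_frames = 1)
  bounds <- tibble::tibble(track_id = "a", boundary = c(10L, 20L, 30L))
  nomerge <- merge_fractions(same, bounds, pars1)
  expect_equal(nrow(nomerge), 4L)
})

test_that("short phases are dropped without re-merging", {
  pars <- phase_params(min_phase_frames = 10)
  phases <- tibble::tibble(
    track_id = "a", phase = 1:3,
    start = c(0L, 12L, 16L), end = c(12L, 16L, 46L),
    start_frame = c(0L, 12L, 16L), end_frame = c(12L, 16L, 46L),
    duration_frames = c(12L, 4L, 30L), duration_s = c(1.2, 0.4, 3),
    mean_velocity = c(5, 9, 2), sd_velocity = c(0.1, 0.1, 0.1)
  )
  kept <- drop_short_phases(phases, pars)
  expect_equal(kept$duration_frames, c(12L, 30L))
  expect_equal(kept$mean_velocity, c(5, 2)) # rows untouched

  expect_equal(nrow(drop_short_phases(phases, phase_params(min_phase_frames = 40))), 0L)
  expect_identical(drop_short_phases(phases, phase_params(min_phase_frames = 1)), phases)
})

test_that("identify_phases recovers piecewise-constant velocity epochs", {
  # noise added to the speed signal directly (iid across intervals)
  set.seed(11)
  tr <- piecewise_track(c(5, 2, 8), len = 40, noise_sd = 0) # speeds in x only
  sp <- compute_speed(tr, calibration(1, 1))
  sp$speed <- sp$speed + rnorm(nrow(sp), 0, 0.3)
  ph <- identify_phases(sp, phase_params())
  expect_equal(nrow(ph), 3L)
  expect_lte(max(abs(ph$start[2:3] - c(40, 80))), 3)
  expect_lt(max(abs(ph$mean_velocity - c(5, 2, 8))), 0.2)
  # durations are consistent
  expect_equal(ph$duration_frames, ph$end - ph$start)

  # noise on the positions (the tracking-error route): recovery holds across
  # seeds, not just on one fixture
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    tr2 <- piecewise_track(c(5, 2, 8), len = 40, noise_sd = 0.3)
    ph2 <- identify_phases(compute_speed(tr2, calibration(1, 1)), phase_params())
    hits <- hits + (nrow(ph2) == 3 &&
                      max(abs(ph2$start[2:3] - c(40, 80))) <= 3 &&
                      max(abs(ph2$mean_velocity - c(5, 2, 8))) <= 0.2)
  }
  expect_gte(hits, 9L)

  # a homogeneous noisy series usually collapses to a single phase; every
  # retained phase has a mean near the true level regardless
  collapsed <- 0L
  for (seed in 21:30) {
    set.seed(seed)
    one <- speed_series(5 + rnorm(80, 0, 0.3))
    ph1 <- identify_phases(one, phase_params())
    collapsed <- collapsed + (nrow(ph1) == 1L)
    expect_lt(max(abs(ph1$mean_velocity - 5)), 0.3)
  }
  expect_gte(collapsed, 6L)

  # series shorter than the minimum phase length yields an empty set
  short <- speed_series(c(1, 5, 2, 4, 3))
  expect_equal(nrow(identify_phases(short, phase_params(min_phase_frames = 10))), 0L)
})

test_that("phases partition the series and alpha only adds boundaries", {
  set.seed(33)
  for (rep in 1:5) {
    v <- as.numeric(arima.sim(list(ar = 0.8), 120)) + 6
    sp <- speed_series(v)
    pars0 <- phase_params(min_phase_frames = 1)
    b <- split_at_local_maxima(sp, pars0)
    merged <- merge_fractions(sp, b, pars0)
    # union of phases before the length filter is [0, n)
    expect_equal(merged$start, c(0L, merged$end[-nrow(merged)]))
    expect_equal(merged$end[nrow(merged)], 120L)
    # stored statistics equal recomputation from the series
    for (k in seq_len(nrow(merged))) {
      vals <- v[(merged$start[k] + 1):merged$end[k]]
      expect_equal(merged$mean_velocity[k], mean(vals), tolerance = 1e-10)
    }
    # phase count is monotone in alpha
    alphas <- c(0.001, 0.05, 0.5, 1)
    counts <- vapply(alphas, function(a) {
      nrow(merge_fractions(sp, b, phase_params(alpha = a, min_phase_frames = 1)))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
    # alpha = 1 gives the maximal count: one phase per fraction
    expect_equal(counts[4], nrow(b) + 1)
  }
})
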