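# Reading, writing and validation of filament tracking data.

test_that("MDF files parse into 0-based, frame-sorted tracks", {
  path <- write_mdf_fixture(list(
    "1" = data.frame(x = c(10, 13, 16), y = c(5, 9, 13), t = 1:3),
    "2" = data.frame(x = c(0, 1, 2), y = c(0, 0, 0), t = 1:3)
  ))
  tracks <- read_mdf(path)
  expect_equal(sort(unique(tracks$track_id)), c("1", "2"))
  expect_equal(nrow(tracks), 6L)
  expect_equal(tracks$frame[tracks$track_id == "1"], 0:2)
  expect_equal(tracks$x[tracks$track_id == "1"], c(10, 13, 16))

  # a single-point track is accepted at read time ...
  p1 <- write_mdf_fixture(list("1" = data.frame(x = 1, y = 2, t = 5)))
  single <- read_mdf(p1)
  expect_equal(nrow(single), 1L)
  expect_equal(single$frame, 4L)
  # ... but rejected by velocity computations
  expect_error(compute_speed(single), class = "ivmax_insufficient_data")
})

test_that("malformed MDF input raises classed errors", {
  bad_header <- tempfile()
  writeLines(c("NotAnMdf", "Track 1", "Point 1 0 0 1 1 1"), bad_header)
  expect_error(read_mdf(bad_header), class = "ivmax_format_error")

  bad_point <- write_mdf_fixture(list("1" = data.frame(x = 1, y = 2, t = 1)))
  txt <- readLines(bad_point)
  txt[grep("^Point", txt)[1]] <- "Point 1 oops 2.0 1.0 1 1"
  writeLines(txt, bad_point)
  expect_error(read_mdf(bad_point), class = "ivmax_parse_error")
  expect_error(read_mdf(bad_point), "line 5") # the offending line is named

  dup <- write_mdf_fixture(list("1" = data.frame(x = c(1, 2), y = c(1, 2), t = c(3, 3))))
  expect_error(read_mdf(dup), class = "ivmax_validation_error")

  expect_error(read_mdf(tempfile()), class = "ivmax_io_error")
})

test_that("CSV round-trips are lossless and order-insensitive", {
  # MDF -> CSV -> CSV reader gives identical tracks
  mdf <- write_mdf_fixture(list(
    "7" = data.frame(x = c(1.25, 2.5, 3.125), y = c(4.0625, 5, 6), t = 1:3)
  ))
  tracks <- read_mdf(mdf)
  csv <- tempfile(fileext = ".csv")
  write_tracks_csv(tracks, csv)
  expect_equal(read_tracks_csv(csv), tracks)

  # shuffled row order is restored by sorting
  set.seed(1)
  shuffled <- tracks[sample.int(nrow(tracks)), ]
  write_tracks_csv(shuffled, csv)
  expect_equal(read_tracks_csv(csv), tracks)

  # property: random many-track collections survive a round trip to 1e-6 px
  set.seed(99)
  big <- purrr::map_dfr(1:50, function(i) {
    n <- sample(2:12, 1)
    tibble::tibble(
      track_id = as.character(i),
      frame = sort(sample(0:30, n)),
      x = runif(n, -500, 500), y = runif(n, -500, 500)
    )
  })
  big <- big[order(big$track_id, big$frame), ] # readers sort by id, then frame
  write_tracks_csv(big, csv)
  back <- read_tracks_csv(csv)
  expect_equal(back$x, big$x, tolerance = 1e-6)
  expect_equal(back$y, big$y, tolerance = 1e-6)
  expect_equal(back$frame, big$frame)
})

test_that("CSV reader enforces columns and finite coordinates", {
  p <- tempfile(fileext = ".csv")
  writeLines("track_id,frame,x\n1,0,1.0", p)
  expect_error(read_tracks_csv(p), class = "ivmax_format_error")

  writeLines("track_id,frame,x,y\n1,0,NaN,2", p)
  expect_error(read_tracks_csv(p), class = "ivmax_validation_error")

  # header-only file -> empty collection
  writeLines("track_id,frame,x,y", p)
  empty <- read_tracks_csv(p)
  expect_s3_class(empty, "tbl_df")
  expect_equal(nrow(empty), 0L)

  # column order is irrelevant
  writeLines(c("y,x,frame,track_id", "4,3,1,a", "0,0,0,a"), p)
  tr <- read_tracks_csv(p)
  expect_equal(tr$x, c(0, 3))
  expect_equal(tr$frame, 0:1)
})

test_that("writing an empty collection produces a header-only file", {
  empty <- tibble::tibble(track_id = character(), frame = integer(),
                          x = numeric(), y = numeric())
  p <- tempfile(fileext = ".csv")
  write_tracks_csv(empty, p)
  expect_equal(readLines(p), "track_id,frame,x,y")
  expect_equal(nrow(read_tracks_csv(p)), 0L)
})

test_that("MDF writer round-trips through read_mdf with 1-based t", {
  tracks <- line_track(5, 3, 4)
  p <- tempfile(fileext = ".mdf")
  write_mdf(tracks, p)
  txt <- readLines(p)
  expect_match(txt[1], "^MTrackJ")
  # t column (6th field) is 1-based
  pts <- strsplit(grep("^Point", txt, value = TRUE), "\\s+")
  expect_equal(as.integer(vapply(pts, `[[`, "", 6L)), 1:5)
  expect_equal(read_mdf(p), tracks)
})
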