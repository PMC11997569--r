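test_that("a toy wide CSV parses into a stream", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,EDA,HR,label",
               "0,1.5,70,1", "1,1.6,71,1", "2,1.7,72,1"), p)
  st <- read_wide_csv(p)
  expect_s3_class(st, "recording_stream")
  expect_setequal(names(st$channels), c("EDA", "HR"))
  expect_length(st$channels$EDA$values, 3L)
  expect_equal(st$channels$HR$values, c(70, 71, 72))
  expect_equal(st$channels$EDA$labels, c(1L, 1L, 1L))
})

test_that("wide CSV write -> read round trip is lossless to 1e-9", {
  st <- generate_recording(synth_spec(session_lengths_s = 30, seed = 8),
                           "S1", 1L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_wide_csv(st, p)
  back <- read_wide_csv(p)
  for (nm in names(st$channels)) {
    expect_equal(back$channels[[nm]]$timestamps, st$channels[[nm]]$timestamps,
                 tolerance = 1e-9)
    expect_lt(max(abs(back$channels[[nm]]$values - st$channels[[nm]]$values)),
              1e-9)
  }
})

test_that("corrupted cells are interpolated within sessions only", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,EDA", "0,1.0", "1,NaN", "2,3.0"), p)
  expect_equal(read_wide_csv(p)$channels$EDA$values, c(1, 2, 3))
  # a corrupted sample right after a >900 s gap is not bridged from before
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,EDA", "0,1.0", "1,1.0", "2000,NaN", "2001,5.0"), p2)
  v <- read_wide_csv(p2)$channels$EDA$values
  expect_equal(v[3], 5)  # filled from its own session, not from value 1.0
})

test_that("empty cells mean not-sampled, not missing", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,EDA,HR", "0,1.0,70", "0.25,1.1,", "0.5,1.2,"), p)
  st <- read_wide_csv(p)
  expect_length(st$channels$EDA$values, 3L)
  expect_length(st$channels$HR$values, 1L)
})

test_that("long CSV reader agrees with the wide reader", {
  pw <- withr::local_tempfile(fileext = ".csv")
  pl <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,EDA,HR", "0,1.5,70", "1,1.6,71"), pw)
  writeLines(c("id,datetime,channel,value,label",
               "S1,0,EDA,1.5,0", "S1,1,EDA,1.6,0",
               "S1,0,HR,70,0", "S1,1,HR,71,0"), pl)
  w <- read_wide_csv(pw)
  l <- read_long_csv(pl)
  expect_equal(l$channels$EDA$values, w$channels$EDA$values)
  expect_equal(l$channels$HR$values, w$channels$HR$values)
})

test_that("files without channels or timestamps are rejected", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("datetime,foo", "0,1"), p)
  expect_error(read_wide_csv(p), "no recognizable channel")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("foo,EDA", "0,1"), p2)
  expect_error(read_wide_csv(p2), "timestamp")
})

test_that("min-max scaling maps endpoints and round-trips", {
  st <- ts_stream(0:2, values = c(2, 4, 6))
  sc <- minmax_scale(st)
  expect_equal(sc$channels$HR$values, c(0, 0.5, 1))
  back <- invert_minmax(sc)
  expect_lt(max(abs(back$channels$HR$values - c(2, 4, 6))), 1e-12)
})

test_that("constant channels scale to 0.5 with a warning", {
  st <- ts_stream(0:2, values = c(5, 5, 5))
  expect_warning(sc <- minmax_scale(st), "constant")
  expect_equal(sc$channels$HR$values, rep(0.5, 3))
  expect_equal(invert_minmax(sc)$channels$HR$values, rep(5, 3))
})

test_that("min-max scaling is order-preserving and lands in [0,1]", {
  set.seed(31)
  for (i in 1:10) {
    v <- rnorm(50)
    st <- minmax_scale(ts_stream(seq_along(v), values = v))
    out <- st$channels$HR$values
    expect_true(all(out >= 0 & out <= 1))
    expect_identical(order(out), order(v))
  }
})

test_that("resampling matches small hand-worked cases", {
  up <- resample_channel(c(0, 1), c(0, 2), 2, "linear_interp")
  expect_equal(up$values, c(0, 1, 2))
  down <- resample_channel(seq(0, 1 - 1 / 32, by = 1 / 32), rep(7, 32), 4,
                           "block_mean")
  expect_true(all(abs(down$values - 7) < 1e-12))
})

test_that("block means of a zero-mean tone over whole periods vanish", {
  rate <- 32
  t <- seq(0, 8 - 1 / rate, by = 1 / rate)
  x <- sin(2 * pi * 1 * t)  # 1 Hz tone, 1 s blocks hold exactly one period
  got <- resample_channel(t, x, 1, "block_mean")
  # the last grid point owns a truncated block; all full blocks average to ~0
  expect_lt(max(abs(got$values[-length(got$values)])), 1e-9)
})

test_that("stream invariants are enforced", {
  expect_error(recording_stream("S", list(HR = list(
    timestamps = c(0, 1), values = 1))), "length")
  expect_error(recording_stream("S", list(HR = list(
    timestamps = c(1, 0), values = c(1, 2)))), "increasing")
  expect_error(resample_channel(0, 1, 4), "at least 2")
})
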