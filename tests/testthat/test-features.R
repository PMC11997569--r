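test_that("time statistics match hand calculations", {
  s <- time_stats(rep(3.5, 10))
  expect_equal(unname(s[c("mean", "sd", "min", "max")]), c(3.5, 0, 3.5, 3.5))
  s2 <- time_stats(c(1, 2, 3, 4))
  expect_equal(s2[["mean"]], 2.5)
  expect_equal(s2[["sd"]], sqrt(1.25))  # population form, 1/n
  expect_equal(time_stats(c(1, 2, 3), percentiles = 50)[["p50"]], 2)
  expect_error(time_stats(numeric(0)), "at least one")
})

test_that("the fast transform equals the direct summation definition", {
  expect_equal(dft(rep(2, 4)), c(8 + 0i, 0i, 0i, 0i))
  expect_equal(Mod(dft(c(1, 0, -1, 0))), c(0, 2, 0, 2))
  set.seed(13)
  for (N in c(7, 17, 32, 61)) {
    x <- rnorm(N)
    expect_lt(max(Mod(dft(x) - direct_dft(x))), 1e-9)
    # Parseval
    X <- dft(x)
    expect_lt(abs(sum(x^2) - sum(Mod(X)^2) / N), 1e-9)
  }
})

test_that("band powers localize tones and conserve energy", {
  N <- 64
  t <- 0:(N - 1)
  x <- sin(2 * pi * 10 * t / N)  # bin 10 of 32 -> band 3 of 8
  X <- dft(x)
  bp <- band_powers(X, rate = 4, n_bands = 8)
  expect_identical(which.max(bp), 3L)
  expect_gt(bp[3] / sum(bp), 0.999)
  expect_equal(sum(bp), sum(Mod(X[2:(N / 2 + 1)])^2))
  expect_equal(band_powers(dft(rep(0, 16)), 4, 4), rep(0, 4),
               ignore_attr = TRUE)
  expect_error(band_powers(X, 4, 33), "exceeds")
})

test_that("feature tensors have the contracted shapes and orderings", {
  chans <- list(ACC_X = rnorm(1920), ACC_Y = rnorm(1920), ACC_Z = rnorm(1920),
                EDA = rnorm(240), HR = rnorm(60), TEMP = rnorm(240))
  w <- toy_window(chans, label = 1L)
  ds <- build_feature_dataset(list(w), feature_config(hrv = FALSE))
  expect_equal(dim(ds$X_t), c(1, 12, 24))  # 6 channels x 4 stats
  expect_equal(dim(ds$X_f), c(1, 64, 6))
  ds2 <- build_feature_dataset(list(w), feature_config(hrv = TRUE))
  expect_equal(dim(ds2$X_t), c(1, 12, 26))  # + HR hrv_sd, rmssd
  expect_identical(ds2$meta$channels, names(chans))
})

test_that("a constant window gives constant time stats and a zero spectrum", {
  w <- toy_window(list(EDA = rep(2, 240), HR = rep(70, 60)), label = 0L)
  ds <- build_feature_dataset(list(w), feature_config(hrv = FALSE))
  cols <- ds$meta$time_cols
  expect_true(all(ds$X_t[1, , cols == "EDA.mean"] == 2))
  expect_true(all(ds$X_t[1, , cols == "EDA.sd"] == 0))
  expect_lt(max(abs(ds$X_f)), 1e-9)  # DC excluded, no other content
})

test_that("the frequency-separable pair differs only in the spectrum", {
  spec <- synth_spec(session_lengths_s = 150, seed = 21,
                     noise_sd = c(ACC_X = 0, ACC_Y = 0, ACC_Z = 0, EDA = 0,
                                  HR = 0, TEMP = 0))
  for (k in names(spec$class_params))
    for (ch in names(spec$class_params[[k]]))
      spec$class_params[[k]][[ch]]$sd <- 0
  mk <- function(cl) {
    ws <- unlist(lapply(sprintf("S%d", 1:4), function(s)
      windows_from_streams(generate_recording(spec, s, cl))),
      recursive = FALSE)
    build_feature_dataset(ws)
  }
  d1 <- mk(1L); d2 <- mk(2L)
  mt1 <- apply(d1$X_t, c(2, 3), mean); mt2 <- apply(d2$X_t, c(2, 3), mean)
  mf1 <- apply(d1$X_f, c(2, 3), mean); mf2 <- apply(d2$X_f, c(2, 3), mean)
  expect_lt(max(abs(mt1 - mt2)) / max(abs(mt1)), 0.02)
  expect_gt(max(abs(mf1 - mf2)), 1)  # distinct tone bins
})

test_that("standardization zeroes fit-row means and units fit-row sds", {
  set.seed(37)
  ws <- toy_windows(10)
  ds <- build_feature_dataset(ws)
  fit <- 1:12
  z <- standardize_features(ds, fit)
  # per feature (column of the time block / channel of the freq block),
  # pooled over fit rows and the sub-frame/bin axis
  check <- function(A) {
    for (j in seq_len(dim(A)[3])) {
      v <- as.vector(A[fit, , j])
      if (sd(v) > 1e-12) {
        expect_lt(abs(mean(v)), 1e-9)
        expect_lt(abs(sd(v) - 1), 1e-6)
      } else {
        expect_true(all(v == 0))  # constant feature rule
      }
    }
  }
  check(z$X_t)
  check(z$X_f)
})

test_that("held-out rows use the training constants", {
  X <- matrix(c(1, 2, 3, 10), 4, 1)
  ds <- list(X_t = array(X, c(4, 1, 1)), X_f = array(0, c(4, 1, 1)),
             y = rep(0L, 4), synthetic = rep(FALSE, 4),
             subject = rep("s", 4), meta = list(), scaler = NULL)
  class(ds) <- "feature_dataset"
  z <- standardize_features(ds, fit_rows = 1:3)
  # fit rows: mean 2, sd 1 -> c(-1, 0, 1); held-out row: (10 - 2) / 1 = 8
  expect_equal(as.vector(z$X_t), c(-1, 0, 1, 8))
  expect_true(all(z$X_f == 0))  # constant feature rule
})

test_that("feature extraction preserves row order", {
  ws <- toy_windows(4, seed = 2)
  ds <- build_feature_dataset(ws)
  perm <- rev(seq_along(ws))
  dsp <- build_feature_dataset(ws[perm])
  expect_equal(dsp$X_t, ds$X_t[perm, , , drop = FALSE])
  expect_equal(dsp$y, ds$y[perm])
})

test_that("a window too short for the sub-frame count errors", {
  w <- toy_window(list(HR = rnorm(5)), label = 0L)
  expect_error(build_feature_dataset(list(w), feature_config(n_subframes = 12,
                                                             hrv = FALSE)),
               "sub-frames")
})
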