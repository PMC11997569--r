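test_that("degenerate noise-free, amplitude-free spec yields constant signals", {
  spec <- tone_spec(freqs = c(EDA = 0.5, HR = 0.1), amp = 0)
  st <- generate_recording(spec, "A", 1L)
  for (nm in names(st$channels))
    expect_true(all(st$channels[[nm]]$values == 0))
  # with a nonzero class mean the constant moves with it
  spec$class_params[["2"]]$EDA$mean <- 7
  st2 <- generate_recording(spec, "A", 2L)
  expect_true(all(st2$channels$EDA$values == 7))
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- synth_spec(seed = 99)
  a <- generate_recording(spec, "S1", 1L)
  b <- generate_recording(spec, "S1", 1L)
  expect_identical(a, b)
  # a different subject or label changes the draw
  expect_false(identical(a$channels$EDA$values,
                         generate_recording(spec, "S2", 1L)$channels$EDA$values))
})

test_that("observation noise follows the stated law", {
  spec <- tone_spec(freqs = c(EDA = 0.5), amp = 0, session_s = 2500)
  spec$noise_sd <- c(EDA = 0.1)
  st <- generate_recording(spec, "A", 0L)  # mean 0, amp 0 => pure noise
  v <- st$channels$EDA$values
  expect_gte(length(v), 1e4)
  expect_gte(sd(v), 0.08)
  expect_lte(sd(v), 0.12)
})

test_that("generated sessions are separated by exactly one large gap", {
  spec <- synth_spec(session_lengths_s = c(120, 120, 120),
                     inter_session_gap_s = 1200, seed = 3)
  st <- generate_recording(spec, "S1", 0L)
  for (nm in names(st$channels)) {
    gaps <- diff(st$channels[[nm]]$timestamps)
    expect_identical(sum(gaps > 900), 2L)  # one per session boundary
    # no gap inside a session: all other spacings equal the sampling period
    expect_true(all(abs(gaps[gaps <= 900] - 1 / st$rates[[nm]]) < 1e-9))
  }
})

test_that("every sample carries the class label", {
  st <- generate_recording(synth_spec(seed = 4), "S1", 2L)
  for (nm in names(st$channels))
    expect_true(all(st$channels[[nm]]$labels == 2L))
})

test_that("generate_dataset is balanced and validates the design", {
  spec <- synth_spec(seed = 5)
  ds <- generate_dataset(spec, n_per_class = 5)
  expect_length(ds, 15L)
  expect_identical(as.vector(table(attr(ds, "labels"))), rep(5L, 3))
  # a spec whose freq pair differs in amplitude violates the design
  bad <- spec
  bad$class_params[["2"]]$EDA$amp <- 0.9
  expect_error(generate_dataset(bad, n_per_class = 2), "differs in amp")
})

test_that("noise-free frequency-separable pair has identical window means", {
  spec <- synth_spec(seed = 6,
                     noise_sd = c(ACC_X = 0, ACC_Y = 0, ACC_Z = 0, EDA = 0,
                                  HR = 0, TEMP = 0))
  for (k in names(spec$class_params))  # kill between-subject baseline spread
    for (ch in names(spec$class_params[[k]]))
      spec$class_params[[k]][[ch]]$sd <- 0
  w1 <- windows_from_streams(generate_recording(spec, "A", 1L))
  w2 <- windows_from_streams(generate_recording(spec, "A", 2L))
  m1 <- vapply(w1, function(w) mean(w$samples$EDA), 0)
  m2 <- vapply(w2, function(w) mean(w$samples$EDA), 0)
  pooled <- sd(c(m1 - mean(m1), m2 - mean(m2)))
  expect_lt(abs(mean(m1) - mean(m2)), 0.05 * max(pooled, 1e-12) + 1e-9)
  # both tones average out exactly over full windows at these frequencies
  expect_lt(max(abs(c(m1, m2) - 6)), 1e-9)
})

test_that("noise-free tone channels have the predicted dominant DFT bin", {
  spec <- tone_spec(freqs = c(EDA = 0.5, HR = 0.125), amp = 1, session_s = 64)
  st <- generate_recording(spec, "A", 1L)
  for (nm in names(st$channels)) {
    x <- st$channels[[nm]]$values
    N <- length(x)
    rate <- st$rates[[nm]]
    f <- spec$class_params[["1"]][[nm]]$freq
    mag <- Mod(dft(x))[2:(N %/% 2 + 1)]
    expect_identical(which.max(mag), as.integer(round(f * N / rate)))
  }
})

test_that("unknown channels and bad rates are rejected", {
  expect_error(synth_spec(class_params = list(
    "0" = list(BOGUS = list(mean = 0, sd = 0, amp = 0, freq = 1)),
    "1" = list(), "2" = list())), "unknown channel")
  expect_error(synth_spec(channel_rates = c(EDA = -4)), "positive")
  expect_error(synth_spec(inter_session_gap_s = 100), "900")
  expect_error(generate_recording(synth_spec(), "S", 5L), "class_label")
})
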