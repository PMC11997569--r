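#' Time-domain summary statistics of a sample array
#'
#' Mean `mu = (1/n) sum(x_i)` and population standard deviation
#' `sigma = sqrt((1/n) sum((x_i - mu)^2))` (the 1/n form, deliberately not the
#' n-1 sample estimator), plus min, max and optional percentiles computed by
#' linear interpolation.
#'
#' @param samples non-empty numeric vector.
#' @param percentiles optional probabilities in \[0, 100\].
#' @return Named numeric vector.
#' @export
time_stats <- function(samples, percentiles = NULL) {
  n <- length(samples)
  assert_that(n >= 1, "time_stats needs at least one sample")
  mu <- mean(samples)
  sig <- sqrt(sum((samples - mu)^2) / n)
  out <- c(mean = mu, sd = sig, min = min(samples), max = max(samples))
  if (!is.null(percentiles)) {
    q <- stats::quantile(samples, probs = percentiles / 100, type = 7,
                         names = FALSE)
    names(q) <- paste0("p", percentiles)
    out <- c(out, q)
  }
  out
}

#' Discrete Fourier transform
#'
#' `X_k = sum_n x_n exp(-i 2 pi k n / N)`, `k = 0..N-1`. Computed with a fast
#' transform but contracted to the direct-summation definition (the test
#' suite holds it to an O(N^2) oracle at 1e-9).
#'
#' @param samples numeric (or complex) vector, length >= 1.
#' @return Complex spectrum of the same length.
#' @export
dft <- function(samples) {
  assert_that(length(samples) >= 1, "dft needs at least one sample")
  stats::fft(samples)
}

#' Band powers of a one-sided spectrum
#'
#' Bins `k = 1..floor(N/2)` (DC excluded) are partitioned into `n_bands`
#' equal normalized-frequency bands of `(0, Nyquist]`; the band power is the
#' sum of `|X_k|^2` within each band, so the bands conserve the one-sided
#' non-DC energy exactly.
#'
#' @param spectrum complex spectrum from [dft()].
#' @param rate sampling rate in Hz (used only to label band edges).
#' @param n_bands number of bands, `1 <= n_bands <= floor(N/2)`.
#' @return Numeric vector of band powers with a `band_edges_hz` attribute.
#' @export
band_powers <- function(spectrum, rate, n_bands) {
  N <- length(spectrum)
  K <- N %/% 2
  assert_that(n_bands >= 1, "n_bands must be >= 1")
  assert_that(n_bands <= K, "n_bands exceeds the %d available bins", K)
  k <- seq_len(K)
  band <- pmin(ceiling(n_bands * k / K), n_bands)
  p <- Mod(spectrum[k + 1L])^2
  out <- as.numeric(tapply(p, factor(band, levels = seq_len(n_bands)), sum))
  out[is.na(out)] <- 0
  attr(out, "band_edges_hz") <- rate / 2 * (0:n_bands) / n_bands
  out
}

#' Feature extraction settings
#'
#' @param n_subframes sub-frames per window for the time branch (default 12,
#'   i.e. 5 s sub-frames in a 60 s window).
#' @param stats statistic names from [time_stats()] (default mean, sd, min, max).
#' @param n_bins common spectral bins for the frequency branch (default 64).
#' @param hrv add heart-rate-variability style columns (per-sub-frame sd and
#'   RMSSD of the 1 Hz HR series) when an HR channel exists.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_subframes = 12L,
                           stats = c("mean", "sd", "min", "max"),
                           n_bins = 64L, hrv = TRUE) {
  assert_that(n_subframes >= 1 && n_bins >= 1, "invalid feature config")
  structure(list(n_subframes = as.integer(n_subframes), stats = stats,
                 n_bins = as.integer(n_bins), hrv = isTRUE(hrv)),
            class = "feature_config")
}

.subframe_index <- function(n, T) {
  # contiguous partition of 1..n into T runs of near-equal length
  lo <- floor((seq_len(T) - 1) * n / T) + 1L
  hi <- floor(seq_len(T) * n / T)
  Map(function(a, b) a:b, lo, hi)
}

.rmssd <- function(x) if (length(x) < 2) 0 else sqrt(mean(diff(x)^2))

# One window -> list(time = T x F_t matrix, freq = F x F_f matrix)
.window_features <- function(window, cfg, channels) {
  T <- cfg$n_subframes
  S <- cfg$stats
  tmat <- matrix(0, T, 0)
  for (nm in channels) {
    x <- window$samples[[nm]]
    assert_that(length(x) >= T,
                "channel %s: %d samples < %d sub-frames", nm, length(x), T)
    idx <- .subframe_index(length(x), T)
    st <- t(vapply(idx, function(i) time_stats(x[i])[S], numeric(length(S))))
    colnames(st) <- paste(nm, S, sep = ".")
    tmat <- cbind(tmat, st)
  }
  if (cfg$hrv && "HR" %in% channels) {
    x <- window$samples[["HR"]]
    idx <- .subframe_index(length(x), T)
    hrv <- cbind(
      HR.hrv_sd = vapply(idx, function(i) time_stats(x[i])[["sd"]], 0),
      HR.rmssd = vapply(idx, function(i) .rmssd(x[i]), 0))
    tmat <- cbind(tmat, hrv)
  }
  fmat <- matrix(0, cfg$n_bins, length(channels),
                 dimnames = list(NULL, channels))
  grid <- seq_len(cfg$n_bins) / cfg$n_bins
  for (nm in channels) {
    x <- window$samples[[nm]]
    N <- length(x)
    K <- N %/% 2
    X <- dft(x)
    mag <- log1p(Mod(X[seq_len(K) + 1L]))
    fk <- seq_len(K) / (N / 2)  # fraction of this channel's Nyquist, (0, 1]
    fmat[, nm] <- if (K == 1) rep(mag, cfg$n_bins)
                  else stats::approx(fk, mag, xout = grid, rule = 2)$y
  }
  list(time = tmat, freq = fmat)
}

#' Build the dual-branch feature dataset from windows
#'
#' The time branch splits each window into `n_subframes` contiguous
#' sub-frames and computes per-channel statistics in each, yielding a tensor
#' `X_t` of shape `B x T x F_t`. The frequency branch takes each channel's
#' log-magnitude spectrum `log(1 + |X_k|)` with the DC bin excluded (window
#' means belong to the time branch) and linearly interpolates it onto
#' `n_bins` common points of the channel's normalized-frequency axis
#' `(0, Nyquist]`, yielding `X_f` of shape `B x F x F_f`. Channel and
#' statistic ordering is recorded in the metadata.
#'
#' @param windows list of labelled `window` objects sharing a channel set.
#' @param config a [feature_config()].
#' @return An object of class `feature_dataset` with fields `X_t`, `X_f`,
#'   `y`, `synthetic`, `subject`, `meta` and (once fitted) `scaler`.
#' @export
build_feature_dataset <- function(windows, config = feature_config()) {
  assert_that(length(windows) >= 1, "no windows")
  channels <- names(windows[[1]]$samples)
  for (w in windows)
    assert_that(identical(names(w$samples), channels),
                "windows do not share a channel set")
  feats <- lapply(windows, .window_features, cfg = config, channels = channels)
  B <- length(windows)
  Ft <- ncol(feats[[1]]$time)
  X_t <- array(0, c(B, config$n_subframes, Ft))
  X_f <- array(0, c(B, config$n_bins, length(channels)))
  for (i in seq_len(B)) {
    X_t[i, , ] <- feats[[i]]$time
    X_f[i, , ] <- feats[[i]]$freq
  }
  structure(list(
    X_t = X_t, X_f = X_f,
    y = vapply(windows, function(w) as.integer(w$label), integer(1)),
    synthetic = vapply(windows, function(w) isTRUE(w$synthetic), logical(1)),
    subject = vapply(windows, function(w) as.character(w$subject), character(1)),
    meta = list(channels = channels, time_cols = colnames(feats[[1]]$time),
                n_subframes = config$n_subframes, n_bins = config$n_bins),
    scaler = NULL), class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> B=%d  X_t %s  X_f %s  classes: %s\n",
              length(x$y), paste(dim(x$X_t)[-1], collapse = "x"),
              paste(dim(x$X_f)[-1], collapse = "x"),
              paste(sort(unique(x$y)), collapse = ",")))
  invisible(x)
}

.flat <- function(A) matrix(A, nrow = dim(A)[1])
.unflat <- function(M, d) array(M, d)

# Fit a per-feature scaler on a B x L x C tensor: one (mu, sd) per feature
# (third axis), pooled over rows and the temporal/spectral axis. Pooling over
# the axis — rather than z-scoring each (position, feature) cell separately —
# preserves the shape along the axis: per-cell scaling would blow every
# pure-noise spectral bin up to unit variance and bury the peaks the
# convolutional branches read.
.fit_scaler <- function(A, fit_rows) {
  sub <- A[fit_rows, , , drop = FALSE]
  C <- dim(A)[3]
  mu <- numeric(C); sd <- numeric(C)
  for (j in seq_len(C)) {
    v <- as.vector(sub[, , j])
    mu[j] <- mean(v)
    sd[j] <- stats::sd(v)
  }
  sd[!is.finite(sd)] <- 0
  list(mu = mu, sd = sd)
}

.apply_scaler <- function(A, sc) {
  for (j in seq_len(dim(A)[3])) {
    A[, , j] <- if (sc$sd[j] > 0) (A[, , j] - sc$mu[j]) / sc$sd[j] else 0
  }
  A
}

#' Standardize features (z-scoring fitted on training rows only)
#'
#' Each feature — a time-branch statistic column or a frequency-branch
#' channel — is centred by its fit-row mean and divided by its fit-row
#' standard deviation, pooled over the sub-frame/bin axis; features constant
#' over the fit rows map to 0. All rows (fit and held-out) are transformed
#' with the fit-row constants, which are stored in `$scaler` for reuse on
#' external datasets via [apply_feature_scaler()].
#'
#' @param dataset a [build_feature_dataset()] result.
#' @param fit_rows non-empty integer row indices (the training rows).
#' @return The transformed dataset with `$scaler` set.
#' @export
standardize_features <- function(dataset, fit_rows) {
  assert_that(length(fit_rows) >= 1, "fit_rows must be non-empty")
  sc <- list(time = .fit_scaler(dataset$X_t, fit_rows),
             freq = .fit_scaler(dataset$X_f, fit_rows))
  dataset$X_t <- .apply_scaler(dataset$X_t, sc$time)
  dataset$X_f <- .apply_scaler(dataset$X_f, sc$freq)
  dataset$scaler <- sc
  dataset
}

#' Apply a previously fitted feature scaler to another dataset
#'
#' @param dataset a `feature_dataset` on the raw feature scale.
#' @param scaler the `$scaler` of a standardized training dataset.
#' @return The transformed dataset.
#' @export
apply_feature_scaler <- function(dataset, scaler) {
  dataset$X_t <- .apply_scaler(dataset$X_t, scaler$time)
  dataset$X_f <- .apply_scaler(dataset$X_f, scaler$freq)
  dataset$scaler <- scaler
  dataset
}

# Row subset of a feature dataset.
#' Subset the rows of a feature dataset
#' @param dataset a `feature_dataset`.
#' @param rows integer row indices.
#' @return The row-subset dataset.
#' @export
subset_rows <- function(dataset, rows) {
  dataset$X_t <- dataset$X_t[rows, , , drop = FALSE]
  dataset$X_f <- dataset$X_f[rows, , , drop = FALSE]
  dataset$y <- dataset$y[rows]
  dataset$synthetic <- dataset$synthetic[rows]
  dataset$subject <- dataset$subject[rows]
  dataset
}
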