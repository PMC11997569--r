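# Independent oracles and small fixture builders, kept deliberately naive.

# O(N^2) direct-summation DFT: X_k = sum_n x_n exp(-i 2 pi k n / N).
direct_dft <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  W <- exp(-2i * pi * outer(n, n) / N)
  as.vector(W %*% x)
}

# Exhaustive k-nearest-neighbour oracle (Euclidean, ties by lower index).
brute_knn <- function(rows, query, k) {
  d <- sqrt(rowSums(sweep(rows, 2, rows[query, ])^2))
  d[query] <- Inf
  order(d, seq_len(nrow(rows)))[seq_len(k)]
}

# Linear-scan session oracle: indices split wherever diff(ts) > delta.
scan_sessions <- function(ts, delta) {
  cuts <- which(diff(ts) > delta)
  bounds <- c(0L, cuts, length(ts))
  lapply(seq_len(length(bounds) - 1L),
         function(i) ts[(bounds[i] + 1L):bounds[i + 1L]])
}

# Brute-force one-vs-rest metrics from raw label vectors.
brute_metrics <- function(truth, pred, K) {
  per <- lapply(0:(K - 1), function(c) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f, support = sum(truth == c))
  })
  m <- do.call(rbind, per)
  list(per_class = m, accuracy = mean(truth == pred))
}

# A single-channel stream with the given timestamps (plus optional extras).
ts_stream <- function(ts, values = seq_along(ts), label = 0L) {
  recording_stream("T1", list(
    HR = list(timestamps = ts, values = values,
              labels = rep(label, length(ts)))), rates = c(HR = 1))
}

# Fully sampled one-session stream of the given duration (seconds).
uniform_stream <- function(duration, rates = c(EDA = 4, HR = 1), label = 1L) {
  chans <- lapply(names(rates), function(nm) {
    n <- round(duration * rates[[nm]])
    ts <- (seq_len(n) - 1) / rates[[nm]]
    list(timestamps = ts, values = sin(ts) + as.numeric(nm == "EDA"),
         labels = rep(label, n))
  })
  names(chans) <- names(rates)
  recording_stream("U1", chans, rates = rates)
}

# A labelled multichannel window built directly from sample arrays.
toy_window <- function(samples, label = 0L, subject = "W1",
                       rates = NULL) {
  if (is.null(rates))
    rates <- stats::setNames(vapply(samples, length, 0) / 60, names(samples))
  structure(list(subject = subject, start_s = 0, length_s = 60,
                 samples = samples, rates = rates, label = label,
                 synthetic = FALSE), class = "window")
}

# Window set with a planted linear class signal, for quick model tests.
toy_windows <- function(n_per_class, n_hr = 60, seed = 1) {
  set.seed(seed)
  out <- list()
  for (cl in 0:1) {
    for (i in seq_len(n_per_class)) {
      hr <- rnorm(n_hr, 70 + 10 * cl, 1)
      eda <- rnorm(4 * n_hr, 2 + 2 * cl, 0.2)
      out[[length(out) + 1L]] <- toy_window(
        list(EDA = eda, HR = hr), label = cl,
        subject = sprintf("c%d_%d", cl, i))
    }
  }
  out
}

# A small noise-free synth spec where every channel is a pure tone.
tone_spec <- function(freqs = c(EDA = 0.5), amp = 1, session_s = 120,
                      seed = 5L) {
  chs <- names(freqs)
  mkp <- function() {
    p <- lapply(chs, function(nm) list(mean = 0, sd = 0, amp = amp,
                                       freq = freqs[[nm]]))
    names(p) <- chs
    p
  }
  synth_spec(session_lengths_s = session_s, inter_session_gap_s = 1000,
             channel_rates = c(EDA = 4, HR = 1, TEMP = 4, ACC_X = 32,
                               ACC_Y = 32, ACC_Z = 32)[chs],
             class_params = list("0" = mkp(), "1" = mkp(), "2" = mkp()),
             noise_sd = stats::setNames(rep(0, length(chs)), chs),
             seed = seed)
}
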