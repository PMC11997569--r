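#' Canonical wearable channel registry
#'
#' The six channels emitted by a wrist-worn physiological monitor, with the
#' sampling rates expected for each: tri-axial accelerometer at 32 Hz,
#' electrodermal activity at 4 Hz, heart rate at 1 Hz and skin temperature at
#' 4 Hz. Readers treat these rates as defaults only; the rate actually stored
#' in a stream is always estimated from the data.
#'
#' @param rates optional named numeric vector overriding expected rates (Hz).
#' @return A named numeric vector of expected rates, class `channel_registry`.
#' @export
channel_registry <- function(rates = NULL) {
  reg <- c(ACC_X = 32, ACC_Y = 32, ACC_Z = 32, EDA = 4, HR = 1, TEMP = 4)
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), names(reg))
    if (length(bad)) stopf("unknown channel name(s): %s", paste(bad, collapse = ", "))
    reg[names(rates)] <- rates
  }
  assert_that(all(reg > 0), "channel rates must be positive")
  structure(reg, class = "channel_registry")
}

# Aliases used by the wide CSV dialect (accelerometer axes are plain X/Y/Z).
.channel_aliases <- c(X = "ACC_X", Y = "ACC_Y", Z = "ACC_Z")

#' Construct a multirate recording stream
#'
#' A recording stream holds one subject's raw multichannel signal: per channel,
#' a strictly increasing timestamp vector (seconds since recording start), a
#' value vector of equal length, an optional per-sample stress label in
#' \{0, 1, 2\}, and the channel's sampling rate in Hz.
#'
#' @param subject subject identifier.
#' @param channels named list; each element a list with `timestamps`, `values`
#'   and optionally `labels`.
#' @param rates named numeric vector of sampling rates (Hz); estimated from
#'   median timestamp spacing when omitted.
#' @return An object of class `recording_stream`.
#' @export
recording_stream <- function(subject, channels, rates = NULL) {
  assert_that(length(channels) >= 1, "a stream needs at least one channel")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    assert_that(length(ch$timestamps) == length(ch$values),
                "channel %s: timestamps and values differ in length", nm)
    if (length(ch$timestamps) > 1)
      assert_that(all(diff(ch$timestamps) > 0),
                  "channel %s: timestamps must be strictly increasing", nm)
    if (!is.null(ch$labels))
      assert_that(length(ch$labels) == length(ch$values),
                  "channel %s: labels length mismatch", nm)
  }
  if (is.null(rates)) {
    rates <- vapply(channels, function(ch) {
      if (length(ch$timestamps) > 1) 1 / stats::median(diff(ch$timestamps)) else 1
    }, numeric(1))
  }
  assert_that(all(rates > 0), "rates must be positive")
  structure(list(subject = subject, channels = channels,
                 rates = rates[names(channels)]),
            class = "recording_stream")
}

#' @export
print.recording_stream <- function(x, ...) {
  cat(sprintf("<recording_stream> subject %s, %d channel(s)\n",
              x$subject, length(x$channels)))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-6s %8.2f Hz  %6d samples  [%.2f, %.2f] s\n", nm,
                x$rates[[nm]], length(ch$values),
                min(ch$timestamps), max(ch$timestamps)))
  }
  invisible(x)
}

.parse_time_column <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  t <- as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y/%m/%d %H:%M:%OS"))
  if (anyNA(t)) stopf("unparseable timestamps (first bad: %s)", x[which(is.na(t))[1]])
  as.numeric(t)
}

#' Read a wide multirate CSV into recording streams
#'
#' The wide dialect has a `datetime` (or `timestamp`) column, one column per
#' channel (`X,Y,Z,EDA,HR,TEMP` or canonical names), and optional `label` and
#' `id` columns. Because channels run at different rates most cells are empty:
#' an empty cell means "this channel was not sampled at this instant" and is
#' skipped, while a present-but-unparseable or NaN cell is a corrupted native
#' sample and is linearly interpolated — within a session only, never across
#' gaps longer than `delta` seconds.
#'
#' Timestamps are converted to seconds since the recording start. Returns one
#' stream when the file holds a single subject, otherwise a named list of
#' streams.
#'
#' @param path CSV path (gzip-transparent via R connections).
#' @param registry a [channel_registry()] naming recognized channels.
#' @param delta session gap threshold in seconds used to bound interpolation.
#' @return A `recording_stream` or a named list of them.
#' @export
read_wide_csv <- function(path, registry = channel_registry(), delta = 900) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  tcol <- intersect(c("datetime", "timestamp", "time"), names(df))
  assert_that(length(tcol) >= 1, "no datetime/timestamp column in %s", path)
  secs <- .parse_time_column(df[[tcol[1]]])

  cols <- names(df)
  canon <- ifelse(cols %in% names(.channel_aliases), .channel_aliases[cols], cols)
  keep <- which(canon %in% names(registry))
  assert_that(length(keep) >= 1, "no recognizable channel columns in %s", path)

  labels <- if ("label" %in% cols)
    suppressWarnings(as.integer(df[["label"]])) else NULL
  ids <- if ("id" %in% cols) df[["id"]] else rep("S1", nrow(df))

  build_one <- function(rows) {
    t0 <- min(secs[rows])
    chans <- list()
    for (j in keep) {
      raw <- df[rows, j]
      present <- !is.na(raw) & nzchar(trimws(raw))
      if (!any(present)) next
      ts <- secs[rows][present] - t0
      v <- suppressWarnings(as.numeric(raw[present]))
      lb <- if (!is.null(labels)) labels[rows][present] else NULL
      o <- order(ts)
      ts <- ts[o]; v <- v[o]; if (!is.null(lb)) lb <- lb[o]
      v <- .interpolate_within_sessions(ts, v, delta)
      chans[[canon[j]]] <- list(timestamps = ts, values = v, labels = lb)
    }
    recording_stream(ids[rows][1], chans)
  }

  uid <- unique(ids)
  if (length(uid) == 1) return(build_one(seq_len(nrow(df))))
  out <- lapply(uid, function(u) build_one(which(ids == u)))
  stats::setNames(out, uid)
}

# Linear interpolation of non-finite values, restricted to runs of samples
# whose inter-sample gaps never exceed delta. Edge missings are carried.
.interpolate_within_sessions <- function(ts, v, delta) {
  if (!anyNA(v) && all(is.finite(v))) return(v)
  bounds <- c(0L, which(diff(ts) > delta), length(ts))
  for (s in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    vi <- v[idx]
    ok <- is.finite(vi)
    if (all(ok) || !any(ok)) next
    v[idx] <- if (sum(ok) == 1) vi[ok]
              else stats::approx(ts[idx][ok], vi[ok], xout = ts[idx], rule = 2)$y
  }
  v
}

#' Read a long-format CSV (`id,datetime,channel,value,label`)
#'
#' @inheritParams read_wide_csv
#' @return A `recording_stream` or a named list of them.
#' @export
read_long_csv <- function(path, registry = channel_registry(), delta = 900) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("datetime", "channel", "value")
  assert_that(all(need %in% names(df)), "long CSV needs columns %s",
              paste(need, collapse = ","))
  secs <- .parse_time_column(df[["datetime"]])
  canon <- ifelse(df$channel %in% names(.channel_aliases),
                  .channel_aliases[df$channel], df$channel)
  assert_that(any(canon %in% names(registry)), "no recognizable channel rows in %s", path)
  ids <- if ("id" %in% names(df)) df$id else rep("S1", nrow(df))
  labels <- if ("label" %in% names(df))
    suppressWarnings(as.integer(df$label)) else NULL

  build_one <- function(rows) {
    t0 <- min(secs[rows])
    chans <- list()
    for (cn in intersect(unique(canon[rows]), names(registry))) {
      r <- rows[canon[rows] == cn]
      ts <- secs[r] - t0
      v <- suppressWarnings(as.numeric(df$value[r]))
      lb <- if (!is.null(labels)) labels[r] else NULL
      o <- order(ts)
      ts <- ts[o]; v <- v[o]; if (!is.null(lb)) lb <- lb[o]
      v <- .interpolate_within_sessions(ts, v, delta)
      chans[[cn]] <- list(timestamps = ts, values = v, labels = lb)
    }
    recording_stream(ids[rows][1], chans)
  }
  uid <- unique(ids)
  if (length(uid) == 1) return(build_one(seq_len(nrow(df))))
  stats::setNames(lapply(uid, function(u) build_one(which(ids == u))), uid)
}

#' Write recording streams to the wide CSV dialect
#'
#' Inverse of [read_wide_csv()]: one row per distinct timestamp, channels not
#' sampled at that instant left empty. Values are printed with enough digits
#' for a lossless (1e-9) round trip.
#'
#' @param streams a `recording_stream` or list of them.
#' @param path output CSV path.
#' @export
write_wide_csv <- function(streams, path) {
  if (inherits(streams, "recording_stream")) streams <- list(streams)
  rows <- list()
  for (st in streams) {
    all_ts <- sort(unique(unlist(lapply(st$channels, `[[`, "timestamps"))))
    m <- matrix("", length(all_ts), length(st$channels),
                dimnames = list(NULL, names(st$channels)))
    lab <- rep(NA_integer_, length(all_ts))
    for (nm in names(st$channels)) {
      ch <- st$channels[[nm]]
      i <- match(ch$timestamps, all_ts)
      m[i, nm] <- formatC(ch$values, format = "g", digits = 15)
      if (!is.null(ch$labels)) lab[i] <- ch$labels
    }
    rows[[length(rows) + 1L]] <- data.frame(
      datetime = formatC(all_ts, format = "f", digits = 6), m,
      label = lab, id = st$subject, check.names = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-channel min-max scaling of a stream
#'
#' Maps each channel of one subject's stream onto \[0, 1\] by
#' `(x - min) / (max - min)`. A constant channel is mapped to 0.5 with a
#' warning (a symmetric neutral value that avoids division by zero). The
#' fitted constants are stored in the `scaling` attribute so the map can be
#' inverted with [invert_minmax()].
#'
#' @param stream a `recording_stream`.
#' @return The scaled stream, with attribute `scaling`.
#' @export
minmax_scale <- function(stream) {
  scaling <- list()
  for (nm in names(stream$channels)) {
    v <- stream$channels[[nm]]$values
    lo <- min(v); hi <- max(v)
    if (hi - lo <= 0) {
      warning(sprintf("channel %s is constant; emitting 0.5", nm), call. = FALSE)
      stream$channels[[nm]]$values <- rep(0.5, length(v))
    } else {
      stream$channels[[nm]]$values <- (v - lo) / (hi - lo)
    }
    scaling[[nm]] <- c(min = lo, max = hi)
  }
  attr(stream, "scaling") <- scaling
  stream
}

#' Invert a min-max scaled stream
#'
#' @param stream a stream previously returned by [minmax_scale()].
#' @return The stream on its original scale.
#' @export
invert_minmax <- function(stream) {
  scaling <- attr(stream, "scaling")
  assert_that(!is.null(scaling), "stream carries no scaling attribute")
  for (nm in names(stream$channels)) {
    sc <- scaling[[nm]]
    v <- stream$channels[[nm]]$values
    stream$channels[[nm]]$values <-
      if (sc["max"] - sc["min"] <= 0) rep(sc[["min"]], length(v))
      else v * (sc[["max"]] - sc[["min"]]) + sc[["min"]]
  }
  attr(stream, "scaling") <- NULL
  stream
}

#' Resample one channel onto a uniform grid
#'
#' `linear_interp` evaluates the piecewise-linear signal at the grid points;
#' `block_mean` averages the native samples falling in each half-open target
#' interval (empty blocks are filled by linear interpolation from neighbouring
#' blocks). The grid spans `[t_first, t_last]` at spacing `1/target_rate`.
#'
#' @param timestamps,values native samples (>= 2 of them).
#' @param target_rate target rate in Hz (> 0).
#' @param method `"linear_interp"` or `"block_mean"`.
#' @return A list with `timestamps` (uniform grid) and `values`.
#' @export
resample_channel <- function(timestamps, values,
                             target_rate,
                             method = c("linear_interp", "block_mean")) {
  method <- match.arg(method)
  assert_that(length(timestamps) >= 2, "need at least 2 samples to resample")
  assert_that(target_rate > 0, "target_rate must be positive")
  dt <- 1 / target_rate
  grid <- seq(timestamps[1], timestamps[length(timestamps)], by = dt)
  v <- if (method == "linear_interp") {
    stats::approx(timestamps, values, xout = grid)$y
  } else {
    idx <- findInterval(timestamps, c(grid, grid[length(grid)] + dt),
                        rightmost.closed = FALSE)
    means <- tapply(values, factor(idx, levels = seq_along(grid)), mean)
    out <- as.numeric(means)
    if (anyNA(out)) {
      ok <- !is.na(out)
      out <- stats::approx(grid[ok], out[ok], xout = grid, rule = 2)$y
    }
    out
  }
  list(timestamps = grid, values = v)
}
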