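#' Split a stream into work sessions at large time gaps
#'
#' A new session begins wherever the interval between consecutive samples on
#' the reference channel exceeds `delta` seconds (default 900 s = 15 min,
#' absorbing short breaks in data collection). The reference channel is the
#' slowest-rate channel present — the most conservative choice, since it
#' cannot see gaps shorter than its own sampling period. All channels are cut
#' at the same wall-clock boundaries (the midpoints of the reference gaps),
#' so the union of sessions is the original stream in order.
#'
#' @param stream a [recording_stream()].
#' @param delta gap threshold in seconds.
#' @param reference_channel channel used for gap detection; default slowest.
#' @return A list of `session` objects (subject, channels, rates, label).
#' @export
segment_sessions <- function(stream, delta = 900, reference_channel = NULL) {
  assert_that(inherits(stream, "recording_stream"), "need a recording_stream")
  assert_that(length(stream$channels) > 0 &&
                all(vapply(stream$channels, function(ch)
                  length(ch$timestamps) > 0, logical(1))),
              "empty stream")
  ref <- reference_channel %||% names(which.min(stream$rates))
  assert_that(ref %in% names(stream$channels), "reference channel %s absent", ref)
  rts <- stream$channels[[ref]]$timestamps
  gap_at <- which(diff(rts) > delta)
  # wall-clock cut points at gap midpoints; sessions are the cells between
  cuts <- c(-Inf, (rts[gap_at] + rts[gap_at + 1L]) / 2, Inf)
  out <- vector("list", length(cuts) - 1L)
  for (s in seq_len(length(cuts) - 1L)) {
    chans <- list()
    for (nm in names(stream$channels)) {
      ch <- stream$channels[[nm]]
      i <- which(ch$timestamps > cuts[s] & ch$timestamps <= cuts[s + 1L])
      if (!length(i)) next
      chans[[nm]] <- list(timestamps = ch$timestamps[i], values = ch$values[i],
                          labels = if (!is.null(ch$labels)) ch$labels[i])
    }
    lab <- NA_integer_
    lv <- unlist(lapply(chans, `[[`, "labels"))
    if (length(lv)) {
      tab <- table(lv)
      lab <- as.integer(names(tab)[which.max(tab)])
    }
    out[[s]] <- structure(list(subject = stream$subject, channels = chans,
                               rates = stream$rates[names(chans)], label = lab),
                          class = "session")
  }
  out
}

#' Cut fixed-length overlapping windows from a session
#'
#' Window starts are `0, (1-overlap)*length_s, 2*(1-overlap)*length_s, ...`
#' relative to the session start, in half-open `[start, start+length_s)`
#' second coordinates. A window is emitted only if `start + length_s` fits
#' inside the session span and every channel contributes at least
#' `completeness_fraction * rate * length_s` samples.
#'
#' @param session a session from [segment_sessions()].
#' @param length_s window length in seconds (default 60).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @param completeness_fraction minimum per-channel fill fraction.
#' @return A list of `window` objects (subject, start_s, length_s, per-channel
#'   sample arrays, rates, label).
#' @export
make_windows <- function(session, length_s = 60, overlap = 0.5,
                         completeness_fraction = 0.95) {
  assert_that(length_s > 0, "length_s must be positive")
  assert_that(overlap >= 0 && overlap < 1, "overlap must be in [0,1)")
  chans <- session$channels
  assert_that(length(chans) > 0, "session has no channels")
  t0 <- min(vapply(chans, function(ch) ch$timestamps[1], numeric(1)))
  span <- max(vapply(names(chans), function(nm) {
    ch <- chans[[nm]]
    ch$timestamps[length(ch$timestamps)] + 1 / session$rates[[nm]]
  }, numeric(1))) - t0
  step <- (1 - overlap) * length_s
  out <- list()
  start <- 0
  eps <- 1e-9
  while (start + length_s <= span + eps) {
    w <- list()
    ok <- TRUE
    for (nm in names(chans)) {
      ch <- chans[[nm]]
      rel <- ch$timestamps - t0
      i <- which(rel >= start - eps & rel < start + length_s - eps)
      need <- completeness_fraction * session$rates[[nm]] * length_s
      if (length(i) < need) { ok <- FALSE; break }
      w[[nm]] <- ch$values[i]
    }
    if (ok) {
      out[[length(out) + 1L]] <- structure(
        list(subject = session$subject, start_s = start, length_s = length_s,
             samples = w, rates = session$rates, label = session$label,
             synthetic = FALSE),
        class = "window")
    }
    start <- start + step
  }
  out
}

#' Segment a set of streams and window every session
#'
#' Convenience wrapper: [segment_sessions()] then [make_windows()] over a
#' list of streams, concatenating all emitted windows.
#'
#' @param streams list of [recording_stream()] (or a single one).
#' @inheritParams segment_sessions
#' @inheritParams make_windows
#' @return A flat list of windows.
#' @export
windows_from_streams <- function(streams, delta = 900, length_s = 60,
                                 overlap = 0.5, completeness_fraction = 0.95) {
  if (inherits(streams, "recording_stream")) streams <- list(streams)
  out <- list()
  for (st in streams) {
    for (sess in segment_sessions(st, delta = delta)) {
      out <- c(out, make_windows(sess, length_s = length_s, overlap = overlap,
                                 completeness_fraction = completeness_fraction))
    }
  }
  out
}
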