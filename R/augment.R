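#' Sliding sub-segments of a sample array
#'
#' For a segment of `n` samples, windows of `w` samples start at 1-based
#' indices `1, 1+s, 1+2s, ...` up to `n - w + 1`, giving
#' `floor((n - w) / s) + 1` windows. Returns an empty list when `w > n`.
#'
#' @param segment numeric sample array.
#' @param w window size in samples.
#' @param s step size in samples, `1 <= s <= w` not enforced beyond `s >= 1`.
#' @return List of length-`w` numeric vectors.
#' @export
sliding_windows <- function(segment, w, s) {
  assert_that(w >= 1 && s >= 1, "w and s must be >= 1")
  n <- length(segment)
  if (w > n) return(list())
  starts <- seq.int(1L, n - w + 1L, by = s)
  lapply(starts, function(j) segment[j:(j + w - 1L)])
}

#' Gaussian jitter of a window
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to every sample of every channel,
#' preserving the label and geometry. `sigma = 0` returns the input
#' unchanged. Deterministic under a fixed seed.
#'
#' @param window a `window` object (or a bare numeric vector).
#' @param sigma noise standard deviation, in units of the (scaled) signal.
#' @param seed integer seed.
#' @return The perturbed window, flagged `synthetic`.
#' @export
jitter_window <- function(window, sigma, seed) {
  assert_that(sigma >= 0, "sigma must be >= 0")
  if (is.numeric(window)) {
    if (sigma == 0) return(window)
    return(with_seed(seed, window + stats::rnorm(length(window), 0, sigma)))
  }
  assert_that(inherits(window, "window"), "window must be a window object")
  if (sigma == 0) return(window)
  with_seed(seed, {
    for (nm in names(window$samples)) {
      v <- window$samples[[nm]]
      window$samples[[nm]] <- v + stats::rnorm(length(v), 0, sigma)
    }
    window$synthetic <- TRUE
    window
  })
}

#' Augmentation settings
#'
#' @param sigma jitter standard deviation (default 0.02 — small relative to a
#'   min-max scaled \[0,1\] signal).
#' @param n_jitter_copies jittered copies per original window (default 1).
#' @param w,s optional sample-domain re-windowing parameters for
#'   [sliding_windows()]; kept for raw segments, not applied to cut windows.
#' @param seed integer seed.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(sigma = 0.02, n_jitter_copies = 1L,
                         w = NULL, s = NULL, seed = 1L) {
  assert_that(sigma >= 0, "sigma must be >= 0")
  assert_that(n_jitter_copies >= 0, "n_jitter_copies must be >= 0")
  if (!is.null(w) && !is.null(s))
    assert_that(s >= 1 && s <= w, "need 1 <= s <= w")
  structure(list(sigma = sigma, n_jitter_copies = as.integer(n_jitter_copies),
                 w = w, s = s, seed = as.integer(seed)),
            class = "augment_spec")
}

#' Augment a training window set
#'
#' Output = originals plus `n_jitter_copies` jittered copies of each, copies
#' flagged `synthetic = TRUE`. Jitter preserves labels, so class proportions
#' are unchanged. Refuses to run on a window list marked as an evaluation or
#' test split (attribute `split`): augmentation is a training-only operation.
#'
#' @param windows list of labelled `window` objects.
#' @param spec an [augment_spec()].
#' @return The augmented window list.
#' @export
augment_training_set <- function(windows, spec = augment_spec()) {
  split <- attr(windows, "split")
  if (!is.null(split) && split %in% c("eval", "test", "validation"))
    stopf("refusing to augment a '%s' split", split)
  assert_that(all(vapply(windows, function(w) !is.na(w$label %||% NA),
                         logical(1))),
              "all windows must carry labels")
  out <- windows
  if (spec$n_jitter_copies > 0) {
    for (copy in seq_len(spec$n_jitter_copies)) {
      for (i in seq_along(windows)) {
        out[[length(out) + 1L]] <- jitter_window(
          windows[[i]], spec$sigma, derive_seed(spec$seed, "jitter", copy, i))
      }
    }
  }
  attr(out, "split") <- split
  out
}
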