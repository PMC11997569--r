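#' k-nearest neighbours of one row (Euclidean, deterministic ties)
#'
#' Returns the indices of the `k` rows closest to `rows[query, ]`, excluding
#' the query itself; distance ties are broken by the lower row index.
#'
#' @param rows numeric matrix, one point per row.
#' @param query row index of the query point.
#' @param k number of neighbours, `1 <= k < nrow(rows)`.
#' @return Integer vector of length `k`.
#' @export
nearest_neighbors <- function(rows, query, k) {
  n <- nrow(rows)
  assert_that(k >= 1, "k must be positive")
  assert_that(k < n, "k must be < number of rows")
  d2 <- colSums((t(rows) - rows[query, ])^2)
  d2[query] <- Inf
  order(d2, seq_len(n))[seq_len(k)]
}

#' SMOTE settings
#'
#' @param k neighbour count (default 5; clipped with a warning when a class
#'   has fewer than `k + 1` members).
#' @param target per-class row count after oversampling; default the majority
#'   class count.
#' @param seed integer seed.
#' @return An object of class `smote_spec`.
#' @export
smote_spec <- function(k = 5L, target = NULL, seed = 1L) {
  assert_that(k >= 1, "k must be >= 1")
  structure(list(k = as.integer(k), target = target, seed = as.integer(seed)),
            class = "smote_spec")
}

#' SMOTE oversampling of minority classes
#'
#' Classic synthetic minority oversampling in feature space: each synthetic
#' point is `x_new = x_i + lambda * (x_zi - x_i)` where `x_i` is a minority
#' row visited round-robin, `x_zi` is drawn uniformly among its `k` nearest
#' same-class neighbours (Euclidean on the supplied — typically standardized
#' — features), and `lambda ~ U[0, 1)`. Every class is brought up to the
#' target count; majority rows are untouched; synthetic rows are flagged.
#'
#' @param rows numeric feature matrix (flattened feature vectors).
#' @param labels integer class labels, one per row.
#' @param spec a [smote_spec()].
#' @return List with `rows`, `labels`, `synthetic` (logical flag per output
#'   row) and `parents` (2-column matrix of parent indices, NA for originals).
#' @export
smote <- function(rows, labels, spec = smote_spec()) {
  assert_that(nrow(rows) == length(labels), "rows/labels length mismatch")
  counts <- table(labels)
  target <- spec$target %||% max(counts)
  new_rows <- list()
  new_labs <- integer(0)
  parents <- list()
  with_seed(spec$seed, {
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need <= 0) next
      idx <- which(labels == as.integer(cl))
      assert_that(length(idx) >= 2,
                  "class %s has < 2 members; cannot interpolate", cl)
      k <- spec$k
      if (k >= length(idx)) {
        k <- length(idx) - 1L
        warning(sprintf("class %s: k clipped to %d (class size %d)",
                        cl, k, length(idx)), call. = FALSE)
      }
      sub <- rows[idx, , drop = FALSE]
      nn <- lapply(seq_along(idx), function(i) nearest_neighbors(sub, i, k))
      for (j in seq_len(need)) {
        i <- (j - 1L) %% length(idx) + 1L        # round-robin over the class
        zi <- nn[[i]][sample.int(k, 1L)]
        lambda <- stats::runif(1)                 # U[0, 1)
        x <- sub[i, ] + lambda * (sub[zi, ] - sub[i, ])
        new_rows[[length(new_rows) + 1L]] <- x
        new_labs <- c(new_labs, as.integer(cl))
        parents[[length(parents) + 1L]] <- c(idx[i], idx[zi])
      }
    }
  })
  n_new <- length(new_rows)
  out_rows <- if (n_new) rbind(rows, do.call(rbind, new_rows)) else rows
  list(rows = out_rows,
       labels = c(as.integer(labels), new_labs),
       synthetic = c(rep(FALSE, nrow(rows)), rep(TRUE, n_new)),
       parents = rbind(matrix(NA_integer_, nrow(rows), 2),
                       if (n_new) do.call(rbind, parents)))
}

#' SMOTE a feature dataset in place
#'
#' Flattens `X_t` and `X_f` into one vector per row for the neighbour search,
#' oversamples with [smote()], and unflattens the synthetic rows back into
#' both tensors. Intended for the (standardized) training split only.
#'
#' @param dataset a standardized `feature_dataset`.
#' @param spec a [smote_spec()].
#' @return The balanced dataset; synthetic rows have `synthetic = TRUE`.
#' @export
smote_dataset <- function(dataset, spec = smote_spec()) {
  dt <- dim(dataset$X_t); df <- dim(dataset$X_f)
  nt <- prod(dt[-1])
  M <- cbind(.flat(dataset$X_t), .flat(dataset$X_f))
  res <- smote(M, dataset$y, spec)
  B2 <- nrow(res$rows)
  dataset$X_t <- array(res$rows[, seq_len(nt)], c(B2, dt[-1]))
  dataset$X_f <- array(res$rows[, -seq_len(nt)], c(B2, df[-1]))
  add <- B2 - length(dataset$y)
  dataset$synthetic <- c(dataset$synthetic, rep(TRUE, add))
  dataset$subject <- c(dataset$subject, rep("smote", add))
  dataset$y <- res$labels
  dataset
}
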