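#' Default hyperparameter grid
#'
#' Three learning rates (1e-3, 1e-4, 1e-5), three dropout rates (0.3, 0.5,
#' 0.7) and three batch sizes (32, 64, 128): 27 combinations, evaluated with
#' a stratified 80/20 split.
#'
#' @param learning_rate,dropout,batch_size grid axes.
#' @return A data frame with one row per combination, class `tune_grid`.
#' @export
tune_grid <- function(learning_rate = c(1e-3, 1e-4, 1e-5),
                      dropout = c(0.3, 0.5, 0.7),
                      batch_size = c(32L, 64L, 128L)) {
  assert_that(length(learning_rate) > 0 && length(dropout) > 0 &&
                length(batch_size) > 0, "empty grid axis")
  g <- expand.grid(batch_size = batch_size, dropout = dropout,
                   learning_rate = learning_rate,
                   KEEP.OUT.ATTRS = FALSE)[, c("learning_rate", "dropout",
                                               "batch_size")]
  class(g) <- c("tune_grid", class(g))
  g
}

#' Exhaustive grid search
#'
#' Evaluates `objective(learning_rate, dropout, batch_size)` once per grid
#' cell. A failing cell is recorded as `NA`, excluded from the argmax, and
#' the sweep continues. Score ties resolve to the first cell in axis order.
#'
#' @param grid a [tune_grid()].
#' @param objective function of `(learning_rate, dropout, batch_size)`
#'   returning a scalar score (higher is better).
#' @return List with `table` (grid plus `score`, sorted by decreasing score,
#'   stable) and `best` (the argmax row on the original axis order).
#' @export
grid_search <- function(grid, objective) {
  scores <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    scores[i] <- tryCatch(
      as.numeric(objective(grid$learning_rate[i], grid$dropout[i],
                           grid$batch_size[i])),
      error = function(e) {
        warning(sprintf("grid cell %d failed: %s", i, conditionMessage(e)),
                call. = FALSE)
        NA_real_
      })
  }
  tab <- cbind(grid, score = scores)
  assert_that(any(!is.na(scores)), "objective failed on every grid cell")
  best_i <- which(scores == max(scores, na.rm = TRUE))[1]
  ord <- order(-scores, seq_len(nrow(tab)), na.last = TRUE)
  list(table = tab[ord, , drop = FALSE], best = tab[best_i, , drop = FALSE])
}

#' Expected Improvement acquisition value
#'
#' `EI(x) = E[max(f(x) - f_best, 0)]` under a Gaussian predictive
#' `f(x) ~ N(mu, s^2)`: with `d = mu - f_best` and `u = d/s`,
#' `EI = d * pnorm(u) + s * dnorm(u)` for `s > 0`, and `max(d, 0)` in the
#' deterministic limit `s = 0`.
#'
#' @param mu predictive mean.
#' @param s predictive standard deviation (>= 0); vectorized with `mu`.
#' @param f_best incumbent (best observed) value.
#' @return EI value(s), non-negative.
#' @export
expected_improvement <- function(mu, s, f_best) {
  assert_that(all(s >= 0), "predictive sd must be >= 0")
  n <- max(length(mu), length(s))
  mu <- rep_len(mu, n)
  s <- rep_len(s, n)
  d <- mu - f_best
  out <- pmax(d, 0)
  pos <- s > 0
  u <- d[pos] / s[pos]
  out[pos] <- d[pos] * stats::pnorm(u) + s[pos] * stats::dnorm(u)
  out
}

# GP regression with a squared-exponential kernel (unit signal variance,
# length-scale 1) on standardized log-scaled hyperparameters.
.gp_features <- function(grid) {
  M <- cbind(log10(grid$learning_rate), grid$dropout, log2(grid$batch_size))
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[sd == 0] <- 1
  scale(M, center = mu, scale = sd)
}

.gp_predict <- function(X_obs, y_obs, X_new, noise = 1e-8) {
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-0.5 * pmax(d2, 0))
  }
  Kn <- k(X_obs, X_obs) + diag(noise, nrow(X_obs))
  Ks <- k(X_new, X_obs)
  ym <- mean(y_obs)
  alpha <- solve(Kn, y_obs - ym)
  mu <- ym + as.numeric(Ks %*% alpha)
  v <- 1 - rowSums(Ks * t(solve(Kn, t(Ks))))
  list(mu = mu, sd = sqrt(pmax(v, 0)))
}

#' Bayesian hyperparameter search over a grid
#'
#' Gaussian-process surrogate (squared-exponential kernel on standardized
#' log-scaled hyperparameters) with the Expected Improvement acquisition:
#' after a seeded random initial design, each step evaluates the
#' un-evaluated cell with the largest EI. Returns early when the grid is
#' exhausted.
#'
#' @param grid a [tune_grid()].
#' @param objective as in [grid_search()].
#' @param n_iter total evaluations (>= 1).
#' @param seed integer seed.
#' @param n_init random cells evaluated before the surrogate starts.
#' @return List with `best` (row of grid plus score) and `trace` (data frame
#'   of candidate, EI at selection, and score).
#' @export
bayes_search <- function(grid, objective, n_iter = 10L, seed = 1L,
                         n_init = 3L) {
  assert_that(n_iter >= 1, "n_iter must be >= 1")
  n <- nrow(grid)
  X <- .gp_features(grid)
  evaluated <- integer(0)
  scores <- numeric(0)
  ei_at_pick <- numeric(0)
  with_seed(derive_seed(seed, "bayes"), {
    init <- sample.int(n, min(n_init, n_iter, n))
    for (i in init) {
      evaluated <- c(evaluated, i)
      scores <- c(scores, objective(grid$learning_rate[i], grid$dropout[i],
                                    grid$batch_size[i]))
      ei_at_pick <- c(ei_at_pick, NA_real_)
    }
    while (length(evaluated) < min(n_iter, n)) {
      cand <- setdiff(seq_len(n), evaluated)
      gp <- .gp_predict(X[evaluated, , drop = FALSE], scores,
                        X[cand, , drop = FALSE])
      ei <- expected_improvement(gp$mu, gp$sd, max(scores))
      pick <- cand[which.max(ei)]
      evaluated <- c(evaluated, pick)
      ei_at_pick <- c(ei_at_pick, max(ei))
      scores <- c(scores, objective(grid$learning_rate[pick],
                                    grid$dropout[pick],
                                    grid$batch_size[pick]))
    }
  })
  trace <- cbind(grid[evaluated, , drop = FALSE],
                 ei = ei_at_pick, score = scores)
  rownames(trace) <- NULL
  best_i <- evaluated[which.max(scores)]
  best <- cbind(grid[best_i, , drop = FALSE], score = max(scores))
  list(best = best, trace = trace)
}

#' Sensitivity views of a grid-search table
#'
#' Three aggregations of the `(learning_rate, dropout, batch_size) -> score`
#' table: score-by-dropout lines per learning rate, a dropout-by-batch
#' heatmap (mean over learning rates — the aggregation must be declared
#' since the heatmap axes omit it), and score-by-batch bars per learning
#' rate.
#'
#' @param table the `table` element of a [grid_search()] result.
#' @return List of data frames `by_dropout`, `heatmap`, `by_batch`.
#' @export
sensitivity_report <- function(table) {
  assert_that(nrow(table) > 0, "empty results table")
  agg <- function(fm) stats::aggregate(fm, data = table, FUN = mean,
                                       na.rm = TRUE)
  list(by_dropout = agg(score ~ dropout + learning_rate),
       heatmap = agg(score ~ dropout + batch_size),
       by_batch = agg(score ~ batch_size + learning_rate))
}
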