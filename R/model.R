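#' Network architecture settings
#'
#' The dual-branch classifier: each branch is `L` blocks of 1D convolution
#' (kernel `kernel`, 'same' padding) -> batch normalization -> ReLU -> max
#' pooling (`pool`) -> dropout, ending in global average pooling; the fusion
#' head is `FC(m) + ReLU -> dropout -> FC(n) + ReLU -> FC(K) + softmax`.
#'
#' @param n_blocks conv blocks per branch (default 3).
#' @param filters filters per block (default 32, 64, 128).
#' @param kernel kernel size (default 3).
#' @param pool max-pool size/stride (default 2).
#' @param dropout dropout rate in `[0, 1)` after each block and after FC(m).
#' @param fc_m,fc_n fusion hidden sizes (default 128, 64).
#' @param n_classes number of classes K (default 3).
#' @param freq_coord append a fixed normalized-frequency coordinate channel
#'   to the spectral input inside the frequency branch (default `TRUE`).
#'   Convolution followed by global average pooling is translation-invariant
#'   along the spectral axis, but the physiological information of a
#'   spectrum lies in *absolute* band position; the coordinate channel lets
#'   filters bind magnitude patterns to their frequency.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_blocks = 3L, filters = c(32L, 64L, 128L),
                         kernel = 3L, pool = 2L, dropout = 0.3,
                         fc_m = 128L, fc_n = 64L, n_classes = 3L,
                         freq_coord = TRUE) {
  assert_that(n_blocks >= 1, "need at least one conv block")
  assert_that(n_classes >= 2, "need at least two classes")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0,1)")
  assert_that(length(filters) == n_blocks, "filters must have one entry per block")
  structure(list(n_blocks = as.integer(n_blocks), filters = as.integer(filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dropout = dropout, fc_m = as.integer(fc_m),
                 fc_n = as.integer(fc_n), n_classes = as.integer(n_classes),
                 freq_coord = isTRUE(freq_coord)),
            class = "model_config")
}

.branch_names <- function(variant) {
  switch(variant,
         full = c("t", "f"),
         no_freq = "t",
         no_time = "f",
         stopf("unknown variant %s", variant))
}

.init_branch <- function(prefix, cfg, Cin, Lin) {
  params <- list(); running <- list()
  L <- Lin
  for (l in seq_len(cfg$n_blocks)) {
    Cout <- cfg$filters[l]
    fan_in <- cfg$kernel * Cin
    params[[sprintf("%s.conv%d.W", prefix, l)]] <-
      array(stats::rnorm(cfg$kernel * Cin * Cout, 0, sqrt(2 / fan_in)),
            c(cfg$kernel, Cin, Cout))
    params[[sprintf("%s.conv%d.b", prefix, l)]] <- numeric(Cout)
    params[[sprintf("%s.bn%d.gamma", prefix, l)]] <- rep(1, Cout)
    params[[sprintf("%s.bn%d.beta", prefix, l)]] <- numeric(Cout)
    running[[sprintf("%s.bn%d.mean", prefix, l)]] <- numeric(Cout)
    running[[sprintf("%s.bn%d.var", prefix, l)]] <- rep(1, Cout)
    L <- L %/% cfg$pool
    assert_that(L >= 1,
                "branch %s: input length too short after %d pooling(s)",
                prefix, l)
    Cin <- Cout
  }
  list(params = params, running = running, out_dim = Cin)
}

#' Build an untrained dual-branch model
#'
#' @param config a [model_config()].
#' @param input_shape list with `time = c(T, F_t)` and/or `freq = c(F, F_f)`,
#'   the per-window tensor shapes. [input_shape_of()] extracts it from a
#'   feature dataset.
#' @param variant `"full"` (both branches), `"no_freq"` (time branch only) or
#'   `"no_time"` (frequency branch only).
#' @param seed seed for the random parameter initialization.
#' @return An object of class `stress_model`.
#' @export
build_model <- function(config = model_config(), input_shape,
                        variant = c("full", "no_freq", "no_time"),
                        seed = 1L) {
  variant <- match.arg(variant)
  branches <- .branch_names(variant)
  with_seed(derive_seed(seed, "init", variant), {
    params <- list(); running <- list(); d_total <- 0L
    for (br in branches) {
      shp <- if (br == "t") input_shape$time else input_shape$freq
      assert_that(!is.null(shp), "input_shape lacks the %s branch shape",
                  if (br == "t") "time" else "freq")
      extra <- if (br == "f" && config$freq_coord) 1L else 0L
      ini <- .init_branch(br, config, Cin = shp[2] + extra, Lin = shp[1])
      params <- c(params, ini$params)
      running <- c(running, ini$running)
      d_total <- d_total + ini$out_dim
    }
    he <- function(n_in, n_out)
      matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
    params$fc1.W <- he(d_total, config$fc_m)
    params$fc1.b <- numeric(config$fc_m)
    params$fc2.W <- he(config$fc_m, config$fc_n)
    params$fc2.b <- numeric(config$fc_n)
    params$out.W <- he(config$fc_n, config$n_classes)
    params$out.b <- numeric(config$n_classes)
    structure(list(config = config, variant = variant,
                   input_shape = input_shape, params = params,
                   running = running, trained = FALSE, history = NULL),
              class = "stress_model")
  })
}

#' Extract the per-window input shape of a feature dataset
#' @param dataset a `feature_dataset`.
#' @return List with `time` and `freq` shape vectors.
#' @export
input_shape_of <- function(dataset) {
  list(time = dim(dataset$X_t)[-1], freq = dim(dataset$X_f)[-1])
}

#' Count trainable parameters
#' @param model a `stress_model`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) sum(vapply(model$params, length, integer(1)))

# Forward through one branch; returns z (B x C), caches, updated running.
.branch_pass <- function(br, X, model, train) {
  cfg <- model$config
  params <- model$params
  running <- model$running
  caches <- list()
  if (br == "f" && isTRUE(cfg$freq_coord)) {
    d <- dim(X)
    Xa <- array(0, c(d[1], d[2], d[3] + 1L))
    Xa[, , seq_len(d[3])] <- X
    Xa[, , d[3] + 1L] <- matrix(seq_len(d[2]) / d[2], d[1], d[2], byrow = TRUE)
    X <- Xa
  }
  H <- X
  for (l in seq_len(cfg$n_blocks)) {
    nm <- function(part) sprintf("%s.%s%d", br, part, l)
    cv <- conv1d_forward(H, params[[paste0(nm("conv"), ".W")]],
                         params[[paste0(nm("conv"), ".b")]])
    bn <- bn_forward(cv$out, params[[paste0(nm("bn"), ".gamma")]],
                     params[[paste0(nm("bn"), ".beta")]],
                     running[[paste0(nm("bn"), ".mean")]],
                     running[[paste0(nm("bn"), ".var")]], train)
    running[[paste0(nm("bn"), ".mean")]] <- bn$run_mean
    running[[paste0(nm("bn"), ".var")]] <- bn$run_var
    rl <- relu_forward(bn$out)
    mp <- maxpool_forward(rl$out, cfg$pool)
    dp <- dropout_forward(mp$out, cfg$dropout, train)
    caches[[l]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache,
                        pool = mp$cache, drop = dp$cache)
    H <- dp$out
  }
  gp <- gap_forward(H)
  list(z = gp$out, caches = caches, gap_dim = gp$cache, running = running)
}

.branch_backward <- function(br, dz, model, pass) {
  cfg <- model$config
  params <- model$params
  grads <- list()
  dH <- gap_backward(dz, pass$gap_dim)
  for (l in rev(seq_len(cfg$n_blocks))) {
    nm <- function(part) sprintf("%s.%s%d", br, part, l)
    cc <- pass$caches[[l]]
    dH <- dropout_backward(dH, cc$drop)
    dH <- maxpool_backward(dH, cc$pool)
    dH <- relu_backward(dH, cc$relu)
    bb <- bn_backward(dH, params[[paste0(nm("bn"), ".gamma")]], cc$bn)
    grads[[paste0(nm("bn"), ".gamma")]] <- bb$dgamma
    grads[[paste0(nm("bn"), ".beta")]] <- bb$dbeta
    cb <- conv1d_backward(bb$dX, params[[paste0(nm("conv"), ".W")]], cc$conv)
    grads[[paste0(nm("conv"), ".W")]] <- cb$dW
    grads[[paste0(nm("conv"), ".b")]] <- cb$db
    dH <- cb$dX
  }
  grads
}

# Full forward (and optionally backward) pass. Returns probs, loss, grads.
.model_pass <- function(model, X_t, X_f, y = NULL, train = FALSE,
                        lambda = 0, backward = FALSE) {
  branches <- .branch_names(model$variant)
  zs <- list(); passes <- list()
  for (br in branches) {
    X <- if (br == "t") X_t else X_f
    assert_that(!is.null(X), "missing input tensor for branch %s", br)
    shp <- if (br == "t") model$input_shape$time else model$input_shape$freq
    assert_that(all(dim(X)[-1] == shp), "input shape mismatch on branch %s", br)
    passes[[br]] <- .branch_pass(br, X, model, train)
    model$running <- passes[[br]]$running
    zs[[br]] <- passes[[br]]$z
  }
  z <- do.call(cbind, zs)
  f1 <- dense_forward(z, model$params$fc1.W, model$params$fc1.b)
  r1 <- relu_forward(f1$out)
  d1 <- dropout_forward(r1$out, model$config$dropout, train)
  f2 <- dense_forward(d1$out, model$params$fc2.W, model$params$fc2.b)
  r2 <- relu_forward(f2$out)
  f3 <- dense_forward(r2$out, model$params$out.W, model$params$out.b)
  probs <- softmax(f3$out)

  loss <- NULL; grads <- NULL
  if (!is.null(y)) {
    sx <- softmax_xent(f3$out, y)
    wkeys <- grep("(conv[0-9]+\\.W|fc1\\.W|fc2\\.W|out\\.W)$",
                  names(model$params), value = TRUE)
    loss <- sx$loss + lambda * sum(vapply(
      model$params[wkeys], function(w) sum(w^2), numeric(1)))
    if (backward) {
      grads <- list()
      b3 <- dense_backward(sx$dlogits, model$params$out.W, f3$cache)
      grads$out.W <- b3$dW; grads$out.b <- b3$db
      dh2 <- relu_backward(b3$dX, r2$cache)
      b2 <- dense_backward(dh2, model$params$fc2.W, f2$cache)
      grads$fc2.W <- b2$dW; grads$fc2.b <- b2$db
      dd1 <- dropout_backward(b2$dX, d1$cache)
      dh1 <- relu_backward(dd1, r1$cache)
      b1 <- dense_backward(dh1, model$params$fc1.W, f1$cache)
      grads$fc1.W <- b1$dW; grads$fc1.b <- b1$db
      dz <- b1$dX
      off <- 0L
      for (br in branches) {
        w <- ncol(zs[[br]])
        grads <- c(grads, .branch_backward(
          br, dz[, (off + 1L):(off + w), drop = FALSE], model, passes[[br]]))
        off <- off + w
      }
      for (nm in wkeys) grads[[nm]] <- grads[[nm]] + 2 * lambda * model$params[[nm]]
    }
  }
  list(probs = probs, loss = loss, grads = grads, running = model$running)
}

#' Forward pass: class probabilities
#'
#' Deterministic in eval mode: dropout is off and batch normalization uses
#' the running statistics. Rows are non-negative and sum to one.
#'
#' @param model a `stress_model`.
#' @param X_t,X_f input tensors `B x T x F_t` and `B x F x F_f` (the branch a
#'   variant lacks may be `NULL`).
#' @return A `B x K` probability matrix.
#' @export
forward <- function(model, X_t = NULL, X_f = NULL) {
  .model_pass(model, X_t, X_f, train = FALSE)$probs
}

#' Training settings
#'
#' @param eta Adam learning rate (default 1e-3).
#' @param lambda L2 coefficient on weights — not biases or batch-norm
#'   parameters (default 1e-4).
#' @param epochs maximum epochs E (default 50).
#' @param batch_size mini-batch size B (default 64).
#' @param patience early-stopping patience in epochs, monitoring validation
#'   loss with best-weights restore (default 10).
#' @param seed integer seed covering initialization order, shuffling and
#'   dropout masks.
#' @return An object of class `train_config`.
#' @export
train_config <- function(eta = 1e-3, lambda = 1e-4, epochs = 50L,
                         batch_size = 64L, patience = 10L, seed = 1L) {
  assert_that(eta > 0, "eta must be positive")
  assert_that(lambda >= 0, "lambda must be >= 0")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  structure(list(eta = eta, lambda = lambda, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Train a model with Adam, mini-batches and early stopping
#'
#' Minimizes cross-entropy plus `lambda * sum(||W||^2)` over weight matrices.
#' Data are reshuffled every epoch (seeded); training stops when the
#' validation loss fails to improve for `patience` consecutive epochs, and
#' the best-validation parameters are restored. The per-epoch history
#' (train loss, validation loss, validation accuracy) is stored on the model.
#'
#' @param model an untrained `stress_model` from [build_model()].
#' @param train_set,val_set `feature_dataset`s (disjoint; both must contain
#'   every class).
#' @param tc a [train_config()].
#' @return The trained `stress_model` with `$history`.
#' @export
train_model <- function(model, train_set, val_set, tc = train_config()) {
  B <- length(train_set$y)
  assert_that(B >= 1 && length(val_set$y) >= 1, "empty split")
  with_seed(derive_seed(tc$seed, "fit", model$variant), {
    opt <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params, running = model$running,
                 epoch = 0L)
    wait <- 0L
    hist <- list()
    for (epoch in seq_len(tc$epochs)) {
      perm <- sample.int(B)
      starts <- seq.int(1L, B, by = tc$batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + tc$batch_size - 1L, B)]
        res <- .model_pass(model,
                           train_set$X_t[idx, , , drop = FALSE],
                           train_set$X_f[idx, , , drop = FALSE],
                           y = train_set$y[idx], train = TRUE,
                           lambda = tc$lambda, backward = TRUE)
        if (!is.finite(res$loss))
          stopf("NaN/Inf loss at epoch %d (lr=%g): try a smaller learning rate",
                epoch, tc$eta)
        model$running <- res$running
        upd <- adam_step(model$params, res$grads, opt, tc$eta)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + res$loss * length(idx)
        ep_n <- ep_n + length(idx)
      }
      ev <- .model_pass(model, val_set$X_t, val_set$X_f, y = val_set$y,
                        train = FALSE, lambda = tc$lambda)
      val_acc <- mean(max.col(ev$probs, ties.method = "first") - 1L == val_set$y)
      hist[[epoch]] <- c(train_loss = ep_loss / ep_n, val_loss = ev$loss,
                         val_acc = val_acc)
      if (ev$loss < best$loss - 1e-12) {
        best <- list(loss = ev$loss, params = model$params,
                     running = model$running, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) break
      }
    }
    model$params <- best$params
    model$running <- best$running
    model$trained <- TRUE
    h <- as.data.frame(do.call(rbind, hist))
    h$epoch <- seq_len(nrow(h))
    model$history <- h[, c("epoch", "train_loss", "val_loss", "val_acc")]
    model$best_epoch <- best$epoch
    model
  })
}

#' Predict class labels
#'
#' Argmax of the forward probabilities; ties resolve to the lowest class
#' index. Labels are on the 0-based scale used throughout.
#'
#' @param model a trained `stress_model`.
#' @param dataset a `feature_dataset` (or a list with `X_t`/`X_f`).
#' @return Integer labels in `0..K-1`.
#' @export
predict_labels <- function(model, dataset) {
  p <- forward(model, dataset$X_t, dataset$X_f)
  max.col(p, ties.method = "first") - 1L
}

#' @export
print.stress_model <- function(x, ...) {
  cat(sprintf("<stress_model> variant=%s  params=%d  trained=%s\n",
              x$variant, count_params(x), x$trained))
  if (!is.null(x$history))
    cat(sprintf("  epochs run: %d (best %d), final val_acc %.3f\n",
                nrow(x$history), x$best_epoch,
                x$history$val_acc[nrow(x$history)]))
  invisible(x)
}
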