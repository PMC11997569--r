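# Native neural-network primitives on B x L x C arrays (batch, length,
# channels), im2col matrix formulation. No autodiff stack exists in the
# target environment, so forward and backward passes are written out and
# verified against finite differences in the test suite.

.bn_eps <- 1e-5

# ---- conv1d, 'same' padding, stride 1 --------------------------------------

conv1d_forward <- function(X, W, b) {
  d <- dim(X); B <- d[1]; L <- d[2]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  p <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, L + 2L * p, Cin))
  Xp[, (p + 1L):(p + L), ] <- X
  cols <- matrix(0, B * L, k * Cin)
  for (j in seq_len(k)) {
    cols[, ((j - 1L) * Cin + 1L):(j * Cin)] <-
      matrix(Xp[, j:(j + L - 1L), , drop = FALSE], B * L, Cin)
  }
  Wmat <- matrix(aperm(W, c(2, 1, 3)), k * Cin, Cout)
  Y <- cols %*% Wmat
  Y <- sweep(Y, 2, b, "+")
  list(out = array(Y, c(B, L, Cout)), cache = list(cols = cols, dim = d, k = k))
}

conv1d_backward <- function(dY, W, cache) {
  d <- cache$dim; B <- d[1]; L <- d[2]; Cin <- d[3]
  k <- cache$k; Cout <- dim(W)[3]
  p <- (k - 1L) %/% 2L
  dYm <- matrix(dY, B * L, Cout)
  Wmat <- matrix(aperm(W, c(2, 1, 3)), k * Cin, Cout)
  dW <- aperm(array(crossprod(cache$cols, dYm), c(Cin, k, Cout)), c(2, 1, 3))
  db <- colSums(dYm)
  dcols <- tcrossprod(dYm, Wmat)
  dXp <- array(0, c(B, L + 2L * p, Cin))
  for (j in seq_len(k)) {
    dXp[, j:(j + L - 1L), ] <- dXp[, j:(j + L - 1L), , drop = FALSE] +
      array(dcols[, ((j - 1L) * Cin + 1L):(j * Cin)], c(B, L, Cin))
  }
  list(dX = dXp[, (p + 1L):(p + L), , drop = FALSE], dW = dW, db = db)
}

# ---- batch normalization per channel over (batch, length) ------------------

bn_forward <- function(X, gamma, beta, run_mean, run_var, train,
                       momentum = 0.9) {
  d <- dim(X)
  M <- matrix(X, d[1] * d[2], d[3])
  if (train) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    v <- pmax(v, 0)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  istd <- 1 / sqrt(v + .bn_eps)
  xhat <- sweep(sweep(M, 2, mu, "-"), 2, istd, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = array(Y, d),
       cache = list(xhat = xhat, istd = istd, dim = d),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dY, gamma, cache) {
  d <- cache$dim
  N <- d[1] * d[2]
  dYm <- matrix(dY, N, d[3])
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, gamma, "*")
  dM <- sweep(dxhat, 2, colMeans(dxhat), "-") -
    sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dM <- sweep(dM, 2, cache$istd, "*")
  list(dX = array(dM, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- ReLU ------------------------------------------------------------------

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

relu_backward <- function(dY, mask) dY * mask

# ---- max pooling (size = stride = pool) along the length axis --------------

maxpool_forward <- function(X, pool = 2L) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Lout <- L %/% pool
  assert_that(Lout >= 1, "input length %d shorter than pool size %d", L, pool)
  Y <- array(-Inf, c(B, Lout, C))
  arg <- array(1L, c(B, Lout, C))
  for (j in seq_len(pool)) {
    slice <- X[, seq.int(j, by = pool, length.out = Lout), , drop = FALSE]
    upd <- slice > Y
    Y[upd] <- slice[upd]
    arg[upd] <- j
  }
  list(out = Y, cache = list(arg = arg, dim = d, pool = pool, Lout = Lout))
}

maxpool_backward <- function(dY, cache) {
  d <- cache$dim
  dX <- array(0, d)
  for (j in seq_len(cache$pool)) {
    sel <- cache$arg == j
    idx <- seq.int(j, by = cache$pool, length.out = cache$Lout)
    slice <- array(0, c(d[1], cache$Lout, d[3]))
    slice[sel] <- dY[sel]
    dX[, idx, ] <- slice
  }
  dX
}

# ---- inverted dropout ------------------------------------------------------

dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, cache = NULL))
  keep <- 1 - rate
  mask <- array(stats::rbinom(length(X), 1L, keep), dim(X)) / keep
  list(out = X * mask, cache = mask)
}

dropout_backward <- function(dY, mask) {
  if (is.null(mask)) return(dY)
  dY * mask
}

# ---- global average pooling over the length axis ---------------------------

gap_forward <- function(X) {
  d <- dim(X)
  list(out = colMeans(aperm(X, c(2, 1, 3))), cache = d)
}

gap_backward <- function(dZ, d) {
  aperm(array(rep(dZ, each = d[2]) / d[2], c(d[2], d[1], d[3])), c(2, 1, 3))
}

# ---- dense -----------------------------------------------------------------

dense_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, "+"), cache = X)
}

dense_backward <- function(dY, W, X) {
  list(dX = tcrossprod(dY, W), dW = crossprod(X, dY), db = colSums(dY))
}

# ---- softmax cross-entropy -------------------------------------------------

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer labels 0..K-1. Returns mean cross-entropy and dlogits.
softmax_xent <- function(logits, y) {
  B <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(z)))
  idx <- cbind(seq_len(B), y + 1L)
  loss <- mean(lse - z[idx])
  p <- exp(z - lse)
  p[idx] <- p[idx] - 1
  list(loss = loss, dlogits = p / B, probs = exp(z - lse) )
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, eta, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      eta * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
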