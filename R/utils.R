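#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a per-stage child seed from a global seed. Keeps results < 2^31 and
# avoids collisions between stages that consume different amounts of RNG.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  fnv1a32(key) %% 2147483581L + 1L
}

# 32-bit FNV-1a over a UTF-8 string, in double arithmetic (exact below 2^53).
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- bitwXor32(h, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:32) {
    r <- r + p * ((a %% 2 + b %% 2) %% 2)
    a <- a %/% 2
    b <- b %/% 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}
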