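# internal helpers: validation, seeded evaluation, tiny linear algebra

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, positive = FALSE, nonneg = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop_bad(field, "must be a finite numeric value")
  if (positive && any(x <= 0)) stop_bad(field, "must be > 0")
  if (nonneg && any(x < 0)) stop_bad(field, "must be >= 0")
  x
}

check_count <- function(x, field, min = 1L) {
  x <- check_num(x, field)
  if (x != round(x) || x < min)
    stop_bad(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic child seed derived from a root seed and a stream id, so that
# per-trajectory streams are reproducible independently of batch order.
# Two rounds of multiplicative mixing modulo the Mersenne prime 2^31 - 1.
child_seed <- function(root, id) {
  m <- 2147483647
  h <- (as.numeric(root) %% m) * 48271 %% m
  h <- (h + as.numeric(id) * 8193 + 1) %% m
  h <- (h * 69621) %% m
  as.integer(h %% (m - 1)) + 1L
}

# slope/intercept of unweighted OLS y ~ x (closed form; avoids lm() overhead
# in per-trajectory loops)
ols_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  slope <- sum(dx * (y - my)) / sum(dx * dx)
  c(intercept = my - slope * mx, slope = slope)
}

ols_r2 <- function(x, y, fit) {
  res <- y - (fit[1] + fit[2] * x)
  tot <- sum((y - mean(y))^2)
  if (tot <= 0) return(1)
  1 - sum(res^2) / tot
}

# FNV-1a hash of a character string, reported as 8 hex digits; used to
# fingerprint configurations in pipeline reports.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
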