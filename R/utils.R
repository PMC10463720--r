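# internal helpers shared across modules

# Deterministic sub-seed derivation: one user-facing seed is expanded into
# per-stage / per-gene seeds. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + offset) %%
               2147483629) + 1L
}

# Evaluate expr with a temporary RNG state; the caller's stream is restored.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Gauss-Hermite nodes/weights (physicists' convention, weight exp(-x^2))
# via the Golub-Welsch eigenvalue construction.
gauss_hermite <- function(k) {
  stopifnot(k >= 1)
  if (k == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- sqrt(pi) * e$vectors[1L, ]^2
  ord <- order(x)
  list(nodes = x[ord], weights = w[ord])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Central-difference Hessian of a scalar function.
num_hessian <- function(fn, x, h = 1e-4 * (1 + abs(x))) {
  q <- length(x)
  H <- matrix(NA_real_, q, q)
  f0 <- fn(x)
  for (a in seq_len(q)) {
    for (b in a:q) {
      if (a == b) {
        xp <- x; xp[a] <- x[a] + h[a]
        xm <- x; xm[a] <- x[a] - h[a]
        H[a, a] <- (fn(xp) - 2 * f0 + fn(xm)) / h[a]^2
      } else {
        xpp <- x; xpp[a] <- x[a] + h[a]; xpp[b] <- x[b] + h[b]
        xpm <- x; xpm[a] <- x[a] + h[a]; xpm[b] <- x[b] - h[b]
        xmp <- x; xmp[a] <- x[a] - h[a]; xmp[b] <- x[b] + h[b]
        xmm <- x; xmm[a] <- x[a] - h[a]; xmm[b] <- x[b] - h[b]
        H[a, b] <- H[b, a] <-
          (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h[a] * h[b])
      }
    }
  }
  H
}
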