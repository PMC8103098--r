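# internal helpers

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Otsu's threshold for a numeric vector: maximize between-class variance on a
# fixed-bin histogram spanning the data range. Bin edges scale with the data,
# so the classification is exactly invariant to multiplication by c > 0.
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  edges <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv[-levels])
  edges[k + 1L]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
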