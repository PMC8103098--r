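# Shared fixtures and independent oracles for the test suite.

noiseless_camera <- function(bit_depth = 12L, exposure = 0.05, gain = 1) {
  list(bit_depth = bit_depth, exposure_time = exposure, gain = gain,
       binning_area = 1L, read_noise_sd = 0, shot_noise = FALSE)
}

noiseless_config <- function(seed = 11, ...) {
  sim_config(camera = noiseless_camera(), seed = seed, ...)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

marker_names_of <- function(cfg) vapply(cfg$markers, function(m) m$name, "")

# Brute-force NNLS oracle: enumerate every active set, solve the
# unconstrained least squares on the passive columns, keep feasible
# candidates, return the one with the smallest residual.
nnls_enumerate <- function(S, b) {
  K <- ncol(S)
  best <- rep(0, K)
  best_res <- sum(b^2)
  for (code in seq_len(2^K) - 1L) {
    P <- which(bitwAnd(code, 2^(seq_len(K) - 1L)) > 0)
    if (!length(P)) next
    z <- tryCatch(qr.solve(S[, P, drop = FALSE], b), error = function(e) NULL)
    if (is.null(z) || any(z < -1e-12)) next
    a <- rep(0, K); a[P] <- pmax(z, 0)
    res <- sum((S %*% a - b)^2)
    if (res < best_res - 1e-12) { best <- a; best_res <- res }
  }
  best
}

# Hand product-limit estimator (no censoring support needed beyond risk-set
# bookkeeping); independent of survival::survfit.
km_by_hand <- function(times, events) {
  ot <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ot))
  for (i in seq_along(ot)) {
    at_risk <- sum(times >= ot[i])
    d <- sum(times == ot[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ot, surv = out)
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mw_enumerate <- function(a, b) {
  na <- length(a); n <- na + length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(na))
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, u_of)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Log-rank chi-square by direct O-E / hypergeometric-variance accumulation.
logrank_by_hand <- function(times, events, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2)
  ot <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ot) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & group == levels(group)[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == levels(group)[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# 1-D grid-search maximizer of the explicit Cox partial likelihood
# (Breslow ties) for a single binary covariate.
cox_grid_oracle <- function(times, events, x, grid = seq(-5, 5, by = 1e-4)) {
  loglik <- vapply(grid, function(b) {
    ll <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }, 0)
  grid[which.max(loglik)]
}

# Cells table builder for unit tests of the scoring layer.
make_cells <- function(n, compartment = "tumour", norm_RAD51 = 0.3,
                       saturated = FALSE) {
  data.frame(cell_id = seq_len(n), row = 0, col = 0, nucleus_area = 25L,
             compartment = rep(compartment, length.out = n),
             saturated = rep(saturated, length.out = n),
             raw_RAD51 = rep(norm_RAD51, length.out = n) * 2^12 * 0.05,
             norm_RAD51 = rep(norm_RAD51, length.out = n),
             stringsAsFactors = FALSE)
}
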