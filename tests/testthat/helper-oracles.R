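# Independent brute-force oracles. These deliberately avoid the package's
# vectorized implementations: plain loops and sum formulas only.

oracle_midpoint_velocity <- function(c7, lum, rate) {
  n <- nrow(c7)
  mid <- (c7 + lum) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- if (i == 1) mid[2, ] - mid[1, ]
         else if (i == n) mid[n, ] - mid[n - 1, ]
         else (mid[i + 1, ] - mid[i - 1, ]) / 2
    out[i] <- sqrt(sum(d^2)) * rate
  }
  out
}

oracle_time_normalize <- function(x, n_out) {
  n <- length(x)
  xi <- seq(0, 1, length.out = n)
  out <- numeric(n_out)
  for (j in seq_len(n_out)) {
    t <- (j - 1) / (n_out - 1)
    k <- max(1L, min(n - 1L, findInterval(t, xi)))
    w <- (t - xi[k]) / (xi[k + 1] - xi[k])
    out[j] <- (1 - w) * x[k] + w * x[k + 1]
  }
  out
}

oracle_segment <- function(f, thr) {
  start <- NA_integer_
  for (i in seq_along(f)) if (f[i] > thr) { start <- i; break }
  end <- 1L
  for (i in seq_along(f)) if (f[i] > f[end]) end <- i
  c(start, end)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_rmse <- function(x, y) sqrt(sum((x - y)^2) / length(x))

oracle_bland_altman <- function(m, p) {
  d <- p - m
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  c(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s)
}

# Quick stack of synthetic pairs for module tests.
make_pairs <- function(n, seed = 1, ...) {
  cfg <- sim_config(n_trials = 1, seed = seed, ...)
  with(list(), {
    set.seed(seed)
    lapply(seq_len(n), function(i) simulate_pair(cfg, sprintf("p%03d", i))$pair)
  })
}

# Monotone ramp pairs where force is proportional to velocity; used for
# learnable-identity checks.
make_ramp_pairs <- function(n, seed = 1, gain = 500) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- cumsum(runif(101, 0.2, 1)); v <- 4 * v / max(v)
    vf_pair(v, v * gain, meta = list(trial_id = sprintf("ramp%03d", i)),
            source = "gan")
  })
}
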