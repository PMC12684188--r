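# Independent oracles and small fixture builders shared across tests.

# Brute-force fixed-effect inverse-variance pooling.
brute_force_fixed <- function(yi, vi) {
  wi <- 1 / vi
  y <- sum(wi * yi) / sum(wi)
  se <- sqrt(1 / sum(wi))
  list(y = y, se = se)
}

# Closed-form DerSimonian-Laird tau2.
dl_closed_form <- function(yi, vi) {
  wi <- 1 / vi
  yw <- sum(wi * yi) / sum(wi)
  Q <- sum(wi * (yi - yw)^2)
  C <- sum(wi) - sum(wi^2) / sum(wi)
  max(0, (Q - (length(yi) - 1)) / C)
}

# Restricted log-likelihood (same definition the grid oracle maximises;
# written out independently of the package internals).
reml_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}

# Iteratively refined grid search for the REML maximiser, down to a grid
# spacing below 1e-8 on [0, hi].
grid_reml <- function(yi, vi, hi = 10) {
  lo <- 0
  repeat {
    grid <- seq(lo, hi, length.out = 1001)
    ll <- vapply(grid, reml_loglik, numeric(1), yi = yi, vi = vi)
    i <- which.max(ll)
    step <- grid[2] - grid[1]
    if (step < 1e-8) return(grid[i])
    lo <- max(0, grid[i] - 2 * step)
    hi <- grid[i] + 2 * step
  }
}

# Minimal stand-in for a reproduced pooled result, for classification and
# agreement tests that only need the summary numbers (analysis scale).
fake_result <- function(est, lo, hi, p = 0.5, measure = "MD") {
  structure(list(k = 5L, measure = measure, y_pooled = est,
                 se_pooled = (hi - lo) / (2 * qnorm(0.975)),
                 ci_low = lo, ci_high = hi, p_value = p,
                 Q = 1, df = 4L, tau2 = 0, i2 = 0, h2 = 0.25,
                 weights = rep(0.2, 5), config = meta_config("fixed"),
                 notes = character()),
            class = "meta_result")
}

# Random small meta-analytic instance for property sweeps.
random_instance <- function(k = NULL) {
  if (is.null(k)) k <- sample(2:10, 1)
  list(yi = rnorm(k, 0, 0.5), vi = runif(k, 0.01, 0.3))
}
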