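# Shared fixtures: tiny sessions, tiny configs, and a finite-difference
# gradient utility used by the gradient-check tests.

tiny_session <- function(n = 40, seed = 11, ...) {
  generate_session(synthetic_config(n_epochs = n, seed = seed, ...))
}

# Small architecture + short schedule so training-based tests stay fast.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_units = c(4, 3), code_dim = 2, epochs = 3,
         pretrain_steps = 3, batch_size = 16),
    list(...))
  do.call(dcra_config, args)
}

# Central finite difference of f at x (numeric array), elementwise.
finite_diff <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Random GRU parameter draw for oracle tests.
random_gru_params <- function(input_dim, units) {
  list(
    W_xz = matrix(stats::rnorm(input_dim * units), input_dim),
    W_xr = matrix(stats::rnorm(input_dim * units), input_dim),
    W_xg = matrix(stats::rnorm(input_dim * units), input_dim),
    W_hz = matrix(stats::rnorm(units * units), units),
    W_hr = matrix(stats::rnorm(units * units), units),
    W_hg = matrix(stats::rnorm(units * units), units),
    b_z = stats::rnorm(units),
    b_r = stats::rnorm(units),
    b_g = stats::rnorm(units)
  )
}

# Scalar-by-scalar evaluation of the GRU recurrences; the
# independent oracle for the vectorized cell.
gru_cell_oracle <- function(p, x, h_prev) {
  u <- length(p$b_z)
  z <- r <- g <- h <- numeric(u)
  for (j in seq_len(u)) {
    z[j] <- 1 / (1 + exp(-(sum(p$W_xz[, j] * x) + sum(p$W_hz[, j] * h_prev) +
                             p$b_z[j])))
    r[j] <- 1 / (1 + exp(-(sum(p$W_xr[, j] * x) + sum(p$W_hr[, j] * h_prev) +
                             p$b_r[j])))
  }
  for (j in seq_len(u)) {
    g[j] <- tanh(sum(p$W_xg[, j] * x) + sum(p$W_hg[, j] * (r * h_prev)) +
                   p$b_g[j])
    h[j] <- z[j] * h_prev[j] + (1 - z[j]) * g[j]
  }
  list(h = h, z = z, r = r, g = g)
}

# The published five-dataset rank table for the six vigilance estimators.
published_ranks <- function() vigilance_rank_table()
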