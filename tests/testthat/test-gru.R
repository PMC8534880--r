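test_that("gru_cell_step with zero parameters halves the previous state", {
  p <- random_gru_params(3, 4)
  p <- lapply(p, function(w) w * 0)
  h0 <- c(1, -2, 0.5, 4)
  res <- gru_cell_step(p, rnorm(3), h0)
  expect_equal(res$z, rep(0.5, 4))
  expect_equal(res$r, rep(0.5, 4))
  expect_equal(res$g, rep(0, 4))
  expect_equal(res$h, 0.5 * h0)
})

test_that("a saturated update gate carries the previous state through", {
  set.seed(14)
  p <- random_gru_params(3, 4)
  p$b_z <- rep(50, 4)
  h0 <- rnorm(4)
  res <- gru_cell_step(p, rnorm(3), h0)
  expect_equal(res$h, h0, tolerance = 1e-9)
})

test_that("gru_cell_step matches the scalar recurrence oracle", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_gru_params(2, 3)
    x <- rnorm(2); h0 <- rnorm(3)
    got <- gru_cell_step(p, x, h0)
    want <- gru_cell_oracle(p, x, h0)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$z, want$z, tolerance = 1e-12)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$g, want$g, tolerance = 1e-12)
  }
})

test_that("gates are bounded and h is a convex combination of h_prev and g", {
  set.seed(9)
  for (i in 1:25) {
    p <- random_gru_params(4, 3)
    h0 <- rnorm(3, sd = 2)
    res <- gru_cell_step(p, rnorm(4, sd = 2), h0)
    expect_true(all(res$z > 0 & res$z < 1))
    expect_true(all(res$r > 0 & res$r < 1))
    expect_true(all(res$g > -1 & res$g < 1))
    lo <- pmin(h0, res$g); hi <- pmax(h0, res$g)
    expect_true(all(res$h >= lo - 1e-12 & res$h <= hi + 1e-12))
  }
})

test_that("a single-layer stack equals direct iteration of the cell", {
  set.seed(4)
  layer <- gru_layer(3, 5, activation = "linear", batch_norm = FALSE)
  X <- matrix(rnorm(12), 4, 3)  # T = 4
  out <- run_stack(list(layer), X)
  h <- numeric(5)
  for (t in 1:4) h <- gru_cell_step(layer$params, X[t, ], h)$h
  expect_equal(unname(out$out[4, ]), unname(h), tolerance = 1e-12)
  expect_equal(out$final_hidden[[1]], h, tolerance = 1e-12)
})

test_that("a 2-layer stack matches a hand-unrolled loop on a T=3 input", {
  set.seed(12)
  l1 <- gru_layer(2, 3, activation = "tanh", batch_norm = FALSE)
  l2 <- gru_layer(3, 2, activation = "linear", batch_norm = FALSE)
  X <- matrix(rnorm(6), 3, 2)
  out <- run_stack(list(l1, l2), X)
  # oracle: unroll layer 1, apply activation, feed layer 2
  h1 <- numeric(3); seq1 <- matrix(0, 3, 3)
  for (t in 1:3) { h1 <- gru_cell_step(l1$params, X[t, ], h1)$h
                   seq1[t, ] <- tanh(h1) }
  h2 <- numeric(2); seq2 <- matrix(0, 3, 2)
  for (t in 1:3) { h2 <- gru_cell_step(l2$params, seq1[t, ], h2)$h
                   seq2[t, ] <- h2 }
  expect_equal(unname(out$out), unname(seq2), tolerance = 1e-12)
  expect_error(run_stack(list(l1), X[0, , drop = FALSE]), "empty")
})

test_that("stack runs are deterministic given parameters and input", {
  set.seed(3)
  stack <- list(gru_layer(3, 4, batch_norm = TRUE),
                gru_layer(4, 2, batch_norm = FALSE))
  X <- array(rnorm(2 * 5 * 3), c(2, 5, 3))
  expect_identical(run_stack(stack, X, train = FALSE)$out,
                   run_stack(stack, X, train = FALSE)$out)
})

test_that("analytic gradients of a 2-unit cell match finite differences", {
  set.seed(31)
  layer <- gru_layer(2, 2, activation = "linear", batch_norm = FALSE)
  layer$params <- random_gru_params(2, 2)
  X <- array(rnorm(1 * 3 * 2), c(1, 3, 2))
  target <- array(rnorm(6), c(1, 3, 2))
  loss_of <- function(l) {
    sum((gru_layer_forward(l, X)$out - target)^2)
  }
  fw <- gru_layer_forward(layer, X)
  bw <- gru_layer_backward(layer, fw$cache, 2 * (fw$out - target))
  for (nm in names(layer$params)) {
    num <- finite_diff(function(w) {
      l2 <- layer; l2$params[[nm]] <- w; loss_of(l2)
    }, layer$params[[nm]])
    denom <- max(max(abs(num)), 1e-6)
    expect_lt(max(abs(bw$grads[[nm]] - num)) / denom, 1e-4)
  }
})

test_that("encode/decode respect shapes and encoder/decoder separation", {
  set.seed(6)
  d <- new_dra(5, hidden_units = c(4, 3), code_dim = 2, seed = 17)
  X <- matrix(rnorm(30), 6, 5)
  code <- dra_encode(d, X)
  expect_length(code, 2)
  recon <- dra_decode(d, code, 6)
  expect_equal(dim(recon), c(6, 5))
  expect_error(dra_decode(d, code, 0), "positive")
  # code is invariant to decoder parameters
  d2 <- d
  d2$decoder[[1]]$params$W_xz <- d2$decoder[[1]]$params$W_xz + 1
  expect_identical(dra_encode(d2, X), code)
  # batch form agrees with the single-sequence form
  Xb <- array(0, c(3, 6, 5)); for (b in 1:3) Xb[b, , ] <- X
  codes <- dra_encode(d, Xb)
  expect_equal(unname(codes[2, ]), unname(code), tolerance = 1e-12)
})

test_that("layer-wise pretraining reduces each layer's reconstruction loss", {
  s <- tiny_session(n = 50, seed = 13)
  x <- dcra:::standardize_array(s$features_e,
                                dcra:::fit_standardizer(s$features_e)$center,
                                dcra:::fit_standardizer(s$features_e)$scale)
  set.seed(5)
  stack <- list(gru_layer(36, 6, batch_norm = FALSE),
                gru_layer(6, 4, batch_norm = TRUE))
  # full-batch steps: the trace is the exact training loss per step
  out <- pretrain_layers(x, stack, steps = 60, batch_size = 50, seed = 3)
  for (k in 1:2) {
    tr <- out$traces[[k]]
    expect_lt(tail(tr, 1), tr[1])
  }
  # zero steps returns the initialization unchanged
  out0 <- pretrain_layers(x, stack, steps = 0, seed = 3)
  expect_identical(out0$stack[[1]]$params, stack[[1]]$params)
  # stacking order: layer-2 input dim equals layer-1 units
  expect_equal(out$stack[[2]]$input_dim, out$stack[[1]]$units)
})

test_that("an identity-like 1-unit auto-encoder round-trips a constant", {
  # dim = units = 1 everywhere; overfit a constant sequence
  set.seed(8)
  d <- new_dra(1, hidden_units = 1, code_dim = 1, batch_norm = FALSE,
               seed = 2)
  X <- array(0.6, c(1, 5, 1))
  p <- dcra:::dra_params(d)
  opt <- dcra:::adam_init(p)
  for (i in 1:200) {
    d <- dcra:::dra_set_params(d, p)
    fw <- dcra:::dra_forward(d, X, train = FALSE)
    g <- dcra:::dra_backward(d, fw, 2 * (fw$recon - X))
    upd <- dcra:::adam_step(p, g, opt, lr = 0.05)
    p <- upd$params; opt <- upd$state
  }
  d <- dcra:::dra_set_params(d, p)
  fw <- dcra:::dra_forward(d, X, train = FALSE)
  expect_lt(max(abs(fw$recon - X)), 0.05)
})
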