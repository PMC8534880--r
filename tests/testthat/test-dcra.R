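# Joint-loss algebra and training behaviour of the coupled model. Training
# tests use a deliberately small architecture and schedule.

std_tiny <- function(n = 40, seed = 11) {
  s <- tiny_session(n = n, seed = seed)
  dcra:::standardize_session(s)
}

test_that("joint loss honours the alpha mixing identities", {
  s <- std_tiny()
  cfg <- tiny_config(seed = 5)
  model <- dcra:::new_dcra(36, 25, cfg)
  xe <- s$features_e[1:8, , , drop = FALSE]
  xo <- s$features_o[1:8, , , drop = FALSE]

  model$alpha <- 0
  l0 <- joint_loss(model, xe, xo)
  expect_equal(l0$L_total, l0$L_E + l0$L_O, tolerance = 1e-12)

  model$alpha <- 1
  l1 <- joint_loss(model, xe, xo)
  expect_equal(l1$L_total, l1$S_coupling, tolerance = 1e-12)

  model$alpha <- 0.3
  l <- joint_loss(model, xe, xo)
  expect_equal(l$L_total,
               (1 - 0.3) * (l$L_E + l$L_O) + 0.3 * l$S_coupling,
               tolerance = 1e-10)
  expect_true(all(c(l$L_E, l$L_O, l$S_coupling) >= 0))
})

test_that("an identity learned metric reproduces the Euclidean coupling", {
  s <- std_tiny()
  cfg <- tiny_config(seed = 5)
  m_eucl <- dcra:::new_dcra(36, 25, cfg)
  m_id <- dcra:::new_dcra(36, 25, cfg, metric = metric_matrix(diag(2)))
  xe <- s$features_e[1:6, , , drop = FALSE]
  xo <- s$features_o[1:6, , , drop = FALSE]
  a <- joint_loss(m_eucl, xe, xo)
  b <- joint_loss(m_id, xe, xo)
  expect_equal(a$L_total, b$L_total, tolerance = 1e-10)
  expect_equal(a$S_coupling, b$S_coupling, tolerance = 1e-10)
})

test_that("decoupled (alpha = 0) training equals independent single-modal runs", {
  s <- std_tiny(n = 36, seed = 3)
  cfg <- tiny_config(seed = 9, early_stop = FALSE, epochs = 3)
  cfg$alpha <- 0
  joint <- train_dcra(s, cfg)
  solo_e <- train_dra(s$features_e, cfg, modality = "e")
  solo_o <- train_dra(s$features_o, cfg, modality = "o")
  expect_equal(joint$trace$L_E, solo_e$trace$L_E, tolerance = 1e-8)
  expect_equal(joint$trace$L_O, solo_o$trace$L_O, tolerance = 1e-8)
  # parameters agree too, not just losses
  expect_equal(dcra:::dra_params(joint$ae_e), dcra:::dra_params(solo_e$ae_e),
               tolerance = 1e-8)
})

test_that("the logged joint-loss breakdown recombines at every step", {
  s <- std_tiny(n = 36, seed = 8)
  cfg <- tiny_config(seed = 2, alpha = 0.4, epochs = 2)
  model <- train_dcra(s, cfg)
  tr <- model$trace
  expect_gt(nrow(tr), 0)
  expect_equal(tr$L_total,
               (1 - 0.4) * (tr$L_E + tr$L_O) + 0.4 * tr$S_coupling,
               tolerance = 1e-10)
  # training reduces the joint loss relative to the first epoch
  expect_lt(tail(model$epoch_losses, 1), model$epoch_losses[1])
})

test_that("fused features concatenate the two codes", {
  s <- std_tiny()
  cfg <- tiny_config(seed = 4)
  model <- dcra:::new_dcra(36, 25, cfg)
  xe <- s$features_e[1:5, , , drop = FALSE]
  xo <- s$features_o[1:5, , , drop = FALSE]
  f <- fuse_features(model, xe, xo)
  expect_equal(dim(f), c(5, 2 * cfg$code_dim))
  expect_identical(f, fuse_features(model, xe, xo))
  expect_equal(unname(f[, 1:2]), unname(as.matrix(dra_encode(model$ae_e, xe))))
  expect_equal(unname(f[, 3:4]), unname(as.matrix(dra_encode(model$ae_o, xo))))
})

test_that("default architecture fuses to a 20-dimensional feature", {
  cfg <- dcra_config(seed = 1)
  model <- dcra:::new_dcra(36, 25, cfg)
  s <- std_tiny()
  f <- fuse_features(model, s$features_e[1:2, , , drop = FALSE],
                     s$features_o[1:2, , , drop = FALSE])
  expect_equal(ncol(f), 20)
})

test_that("the regression head solves exact affine problems", {
  s <- std_tiny()
  cfg <- tiny_config(seed = 6)
  model <- dcra:::new_dcra(36, 25, cfg)
  xe <- s$features_e; xo <- s$features_o
  f <- fuse_features(model, xe, xo)
  beta <- rnorm(ncol(f) + 1, sd = 0.05)
  y <- drop(cbind(1, f) %*% beta)
  y <- pmin(pmax(y, 0), 1)  # keep inside the clipping range
  model <- fit_head(model, xe, xo, y)
  expect_lt(rmse(y, predict_perclos(model, xe, xo)), 1e-8)

  # constant labels give a constant head
  model2 <- fit_head(model, xe, xo, rep(0.5, dim(xe)[1]))
  expect_equal(predict_perclos(model2, xe, xo), rep(0.5, dim(xe)[1]),
               tolerance = 1e-10)

  # under-determined fit falls back to ridge with a warning
  expect_warning(
    fit_head(model, xe[1:3, , , drop = FALSE], xo[1:3, , , drop = FALSE],
             c(0.1, 0.5, 0.9)),
    "ridge")
})

test_that("predictions are clipped to the unit interval", {
  s <- std_tiny()
  cfg <- tiny_config(seed = 6)
  model <- dcra:::new_dcra(36, 25, cfg)
  model$head <- list(coef = c(50, rep(1, 2 * cfg$code_dim)),
                     features = "fused")
  p <- predict_perclos(model, s$features_e, s$features_o)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("model archives round-trip to identical predictions", {
  s <- std_tiny(n = 30, seed = 12)
  cfg <- tiny_config(seed = 3, epochs = 2)
  model <- train_dcra(s, cfg)
  model <- fit_head(model, s$features_e, s$features_o, s$perclos)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  model2 <- load_model(path)
  expect_identical(predict_perclos(model, s$features_e, s$features_o),
                   predict_perclos(model2, s$features_e, s$features_o))
  unlink(path)
})

test_that("configuration validation rejects out-of-range values", {
  expect_error(dcra_config(alpha = 1.5), "\\[0, 1\\]")
  expect_error(dcra_config(alpha = -0.1), "\\[0, 1\\]")
  expect_error(dcra_config(lr = 0), "not TRUE")
  expect_error(train_dcra(std_tiny(), tiny_config(), "learned"),
               "requires a fitted metric")
  expect_error(
    train_dcra(std_tiny(), tiny_config(),
               "learned", metric = metric_matrix(diag(5))),
    "code_dim")
})

test_that("alpha_sweep returns one row per alpha including the endpoints", {
  s <- tiny_session(n = 30, seed = 14)
  cfg <- tiny_config(seed = 2, epochs = 1, pretrain_steps = 1)
  tab <- alpha_sweep(s, c(0, 1), cfg, k = 3)
  expect_equal(tab$alpha, c(0, 1))
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$rmse)))
  expect_error(alpha_sweep(s, 0.4, cfg), "at least two")
  expect_error(alpha_sweep(s, c(0, 1.2), cfg), "\\[0, 1\\]")
})
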