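# The deep coupling recurrent auto-encoder (DCRA): two single-modal deep
# recurrent auto-encoders tied at the coupling layer by the joint loss
#   L = (1 - alpha) * (L_E + L_O) + alpha * S,
# where L_E, L_O are squared-error reconstruction losses and S is the
# squared Mahalanobis distance between the two codes (identity metric for
# the Euclidean variant DCRA_E, a PGDM-learned metric for DCRA_M). Training
# follows the layer-wise-then-joint schedule: greedy pretraining of each
# encoder layer, then Adam fine-tuning of everything under the joint loss
# with the metric held fixed.

#' Training configuration for the coupled auto-encoder
#'
#' Defaults mirror the standard architecture and optimizer settings for
#' this model family: inner encoder widths 20 and 16, coupling width 10,
#' ReLU activations with a sigmoid output layer, batch normalization after
#' layers 2, 3, 5, 6, Adam with learning rate 0.001 and batch size 32, and
#' coupling weight alpha = 0.4.
#'
#' @param alpha Coupling weight in \[0, 1\]. 0 decouples the two
#'   auto-encoders entirely; 1 drops the reconstruction terms.
#' @param hidden_units Inner encoder layer widths (mirrored in the decoder).
#' @param code_dim Coupling-layer width.
#' @param batch_norm Use batch normalization (placement as above).
#' @param lr,batch_size,epochs Adam fine-tuning settings.
#' @param pretrain_steps,pretrain_lr Greedy layer-wise pretraining settings
#'   (Adam steps per encoder layer).
#' @param early_stop,early_stop_tol,early_stop_patience Stop fine-tuning
#'   when the relative epoch-loss change stays below `early_stop_tol` for
#'   `early_stop_patience` consecutive epochs.
#' @param coupling_form `"mahalanobis"` (squared metric distance between the
#'   codes, the default) or `"bilinear"` (the raw bilinear form
#'   `f_E^T M f_O`, kept for comparison; not a distance).
#' @param seed Master seed; per-modality initialization, batching and
#'   pretraining derive named sub-seeds from it.
#' @return An object of class `dcra_config`.
#' @export
dcra_config <- function(alpha = 0.4,
                        hidden_units = c(20, 16),
                        code_dim = 10,
                        batch_norm = TRUE,
                        lr = 0.001,
                        batch_size = 32,
                        epochs = 100,
                        pretrain_steps = 50,
                        pretrain_lr = 0.001,
                        early_stop = TRUE,
                        early_stop_tol = 1e-5,
                        early_stop_patience = 5,
                        coupling_form = c("mahalanobis", "bilinear"),
                        seed = 1L) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  stopifnot(lr > 0, batch_size >= 1, epochs >= 0, pretrain_steps >= 0,
            code_dim >= 1, length(hidden_units) >= 1)
  structure(list(
    alpha = alpha, hidden_units = hidden_units, code_dim = code_dim,
    batch_norm = batch_norm, lr = lr, batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    pretrain_steps = as.integer(pretrain_steps), pretrain_lr = pretrain_lr,
    early_stop = early_stop, early_stop_tol = early_stop_tol,
    early_stop_patience = as.integer(early_stop_patience),
    coupling_form = match.arg(coupling_form),
    seed = as.integer(seed)
  ), class = "dcra_config")
}

coupling_matrix <- function(model) {
  if (is.null(model$metric)) diag(model$code_dim) else model$metric$M
}

coupling_value <- function(code_e, code_o, M, form = "mahalanobis") {
  if (form == "bilinear") {
    mean(rowSums((code_e %*% M) * code_o))
  } else {
    d <- code_e - code_o
    mean(rowSums((d %*% M) * d))
  }
}

#' Joint loss of the coupled auto-encoder
#'
#' Evaluates the three components of the joint objective on a batch:
#' per-modality squared reconstruction errors `L_E`, `L_O` (summed over the
#' sequence, averaged over the batch), the coupling term `S` (squared
#' Mahalanobis distance between the two codes, averaged over the batch),
#' and the combination `L = (1 - alpha)(L_E + L_O) + alpha S`.
#'
#' @param model A `dcra` model (see [train_dcra()]).
#' @param x_e,x_o Feature arrays `B x T x dim` (or single `T x dim`
#'   matrices) for the two modalities.
#' @param train Logical; training-mode batch norm.
#' @return List with `L_total`, `L_E`, `L_O`, `S_coupling`.
#' @export
joint_loss <- function(model, x_e, x_o, train = FALSE) {
  x_e <- as_batch(x_e); x_o <- as_batch(x_o)
  fe <- dra_forward(model$ae_e, x_e, train = train)
  fo <- dra_forward(model$ae_o, x_o, train = train)
  M <- coupling_matrix(model)
  S <- coupling_value(fe$code, fo$code, M, model$coupling_form)
  a <- model$alpha
  list(L_total = (1 - a) * (fe$loss + fo$loss) + a * S,
       L_E = fe$loss, L_O = fo$loss, S_coupling = S)
}

new_dcra <- function(dim_e, dim_o, config, metric = NULL) {
  structure(list(
    ae_e = new_dra(dim_e, config$hidden_units, config$code_dim,
                   config$batch_norm, seed = derive_seed(config$seed, "init_e")),
    ae_o = new_dra(dim_o, config$hidden_units, config$code_dim,
                   config$batch_norm, seed = derive_seed(config$seed, "init_o")),
    alpha = config$alpha,
    code_dim = as.integer(config$code_dim),
    metric = metric,
    coupling_form = config$coupling_form,
    head = NULL,
    config = config
  ), class = "dcra")
}

#' @export
print.dcra <- function(x, ...) {
  cat("<dcra> dims ", x$ae_e$input_dim, "/", x$ae_o$input_dim,
      ", code ", x$code_dim, ", alpha = ", x$alpha,
      ", metric = ", if (is.null(x$metric)) "euclidean" else "learned",
      if (is.null(x$head)) ", head: none" else ", head: fitted", "\n",
      sep = "")
  invisible(x)
}

session_arrays <- function(session) {
  if (inherits(session, "vigilance_session") || is.list(session)) {
    list(e = session$features_e, o = session$features_o)
  } else stop("session must be a vigilance_session or a list with features_e/features_o")
}

# Shared fine-tuning engine. When `modalities` is c("e","o") this trains the
# coupled model; a single modality trains a stand-alone DRA with the exact
# same sub-seeds and batch stream, so an alpha = 0 coupled run reproduces
# the two independent runs step for step.
train_engine <- function(x_e, x_o, config, metric, modalities = c("e", "o")) {
  dims <- list(e = if (!is.null(x_e)) dim(x_e)[3], o = if (!is.null(x_o)) dim(x_o)[3])
  model <- new_dcra(if (is.null(dims$e)) 1L else dims$e,
                    if (is.null(dims$o)) 1L else dims$o,
                    config, metric = metric)
  xs <- list(e = x_e, o = x_o)
  n <- dim(xs[[modalities[1]]])[1]
  T_ <- dim(xs[[modalities[1]]])[2]

  # --- greedy layer-wise pretraining of each encoder stack ---
  for (m in modalities) {
    ae <- model[[paste0("ae_", m)]]
    pre <- pretrain_layers(xs[[m]], ae$encoder,
                           steps = config$pretrain_steps,
                           lr = config$pretrain_lr,
                           batch_size = config$batch_size,
                           seed = derive_seed(config$seed, paste0("pre_", m)))
    ae$encoder <- pre$stack
    model[[paste0("ae_", m)]] <- ae
    attr(model, paste0("pretrain_trace_", m)) <- pre$traces
  }

  # --- joint fine-tuning with Adam ---
  coupled <- length(modalities) == 2
  a <- if (coupled) config$alpha else 0
  M <- coupling_matrix(model)
  opts <- params <- list()
  for (m in modalities) {
    params[[m]] <- dra_params(model[[paste0("ae_", m)]])
    opts[[m]] <- adam_init(params[[m]])
  }
  set.seed(derive_seed(config$seed, "batch"))
  trace_rows <- list()
  epoch_losses <- numeric(0)
  still <- 0L
  for (epoch in seq_len(config$epochs)) {
    batches <- make_batches(n, config$batch_size)
    ep <- c(L_total = 0, L_E = 0, L_O = 0, S_coupling = 0)
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      B <- length(idx)
      fws <- list()
      losses <- list(e = 0, o = 0)
      for (m in modalities) {
        ae <- dra_set_params(model[[paste0("ae_", m)]], params[[m]])
        model[[paste0("ae_", m)]] <- ae
        fw <- dra_forward(ae, xs[[m]][idx, , , drop = FALSE], train = TRUE)
        fws[[m]] <- fw
        losses[[m]] <- fw$loss
        model[[paste0("ae_", m)]] <- dra_adopt_stats(ae, fw)
      }
      S <- if (coupled) {
        coupling_value(fws$e$code, fws$o$code, M, config$coupling_form)
      } else 0
      L_total <- (1 - a) * (losses$e + losses$o) + a * S
      if (!is.finite(L_total)) {
        stop("divergent joint loss at epoch ", epoch, "; last good loss ",
             if (length(epoch_losses)) utils::tail(epoch_losses, 1) else NA)
      }
      # gradients of the coupling term wrt each code
      dcode <- list(e = NULL, o = NULL)
      if (coupled && a > 0) {
        if (config$coupling_form == "bilinear") {
          dcode$e <- a * (fws$o$code %*% M) / B
          dcode$o <- a * (fws$e$code %*% M) / B
        } else {
          dd <- fws$e$code - fws$o$code
          common <- a * 2 * (dd %*% M) / B
          dcode$e <- common
          dcode$o <- -common
        }
      }
      for (m in modalities) {
        fw <- fws[[m]]
        dRecon <- (1 - a) * 2 * (fw$recon - xs[[m]][idx, , , drop = FALSE]) / B
        grads <- dra_backward(model[[paste0("ae_", m)]], fw, dRecon, dcode[[m]])
        upd <- adam_step(params[[m]], grads, opts[[m]], lr = config$lr)
        params[[m]] <- upd$params; opts[[m]] <- upd$state
      }
      trace_rows[[length(trace_rows) + 1]] <-
        c(epoch = epoch, batch = bi, L_total = L_total, L_E = losses$e,
          L_O = losses$o, S_coupling = S)
      ep <- ep + c(L_total, losses$e, losses$o, S) * B
    }
    ep <- ep / n
    names(ep) <- c("L_total", "L_E", "L_O", "S_coupling")
    epoch_losses <- c(epoch_losses, ep[["L_total"]])
    if (config$early_stop && epoch > 1) {
      prev <- epoch_losses[epoch - 1]
      rel <- abs(prev - ep[["L_total"]]) / max(abs(prev), 1e-12)
      still <- if (rel < config$early_stop_tol) still + 1L else 0L
      if (still >= config$early_stop_patience) break
    }
  }
  for (m in modalities) {
    model[[paste0("ae_", m)]] <-
      dra_set_params(model[[paste0("ae_", m)]], params[[m]])
  }
  model$trace <- as.data.frame(do.call(rbind, trace_rows))
  model$epoch_losses <- epoch_losses
  model
}

#' Train the coupled auto-encoder
#'
#' Runs the full training schedule on a (standardized) session: greedy
#' layer-wise pretraining of both encoder stacks, then joint Adam
#' fine-tuning under the joint loss. With `metric_mode = "learned"` a
#' previously fitted [metric_matrix()] must be supplied and is held fixed
#' throughout training; with `"euclidean"` the identity metric is used.
#'
#' @param session A `vigilance_session` (standardized; see
#'   [standardize_session()]) or list with `features_e` / `features_o`.
#' @param config A [dcra_config()].
#' @param metric_mode `"euclidean"` or `"learned"`.
#' @param metric A [metric_matrix()] (required when `metric_mode` is
#'   `"learned"`).
#' @return A `dcra` model with elements `ae_e`, `ae_o`, `alpha`, `metric`,
#'   `head` (NULL until [fit_head()]), and the fine-tuning loss `trace`.
#' @export
train_dcra <- function(session, config = dcra_config(),
                       metric_mode = c("euclidean", "learned"),
                       metric = NULL) {
  metric_mode <- match.arg(metric_mode)
  if (metric_mode == "learned") {
    if (is.null(metric)) stop("metric_mode = 'learned' requires a fitted metric")
    if (!inherits(metric, "metric_matrix")) stop("metric must be a metric_matrix")
    if (metric$d != config$code_dim) {
      stop("metric dimension ", metric$d, " != code_dim ", config$code_dim)
    }
  } else {
    metric <- NULL
  }
  xs <- session_arrays(session)
  train_engine(xs$e, xs$o, config, metric)
}

#' Train a single-modality deep recurrent auto-encoder
#'
#' Same schedule as [train_dcra()] but for one modality with no coupling
#' term; uses the identical per-modality sub-seeds and batch stream, so a
#' coupled run with `alpha = 0` reproduces this step for step.
#'
#' @param x `n x T x dim` feature array (standardized).
#' @param config A [dcra_config()] (`alpha` is ignored).
#' @param modality `"e"` or `"o"`, selecting the initialization sub-seed.
#' @return A `dcra` model whose selected auto-encoder is trained.
#' @export
train_dra <- function(x, config = dcra_config(), modality = c("e", "o")) {
  modality <- match.arg(modality)
  if (modality == "e") train_engine(x, NULL, config, NULL, "e")
  else train_engine(NULL, x, config, NULL, "o")
}

#' Fused cross-modal features
#'
#' Concatenates the two coupling-layer codes `[f_E ; f_O]` for each epoch
#' (length `2 * code_dim`).
#'
#' @param model A trained `dcra`.
#' @param x_e,x_o Feature arrays (`B x T x dim`, or single sequences).
#' @return `B x (2 code_dim)` matrix (or vector for a single epoch).
#' @export
fuse_features <- function(model, x_e, x_o) {
  if (!inherits(model, "dcra")) stop("model must be a trained dcra")
  ce <- dra_encode(model$ae_e, x_e)
  co <- dra_encode(model$ae_o, x_o)
  if (is.null(dim(ce))) c(ce, co) else cbind(ce, co)
}

fit_linear_head <- function(X, y, ridge = 1e-3) {
  X1 <- cbind(1, X)
  if (nrow(X1) < ncol(X1) || qr(X1)$rank < ncol(X1)) {
    warning("under-determined regression head; using ridge penalty ", ridge)
    pen <- diag(c(0, rep(ridge, ncol(X))))
    coef <- solve(crossprod(X1) + pen, crossprod(X1, y))
  } else {
    coef <- qr.solve(X1, y)
  }
  drop(coef)
}

#' Fit the PERCLOS regression head
#'
#' Least-squares affine map from fused features to PERCLOS, fitted on
#' training data only; falls back to a small ridge penalty when the system
#' is under-determined.
#'
#' @param model A trained `dcra`.
#' @param x_e,x_o Training feature arrays.
#' @param y Training PERCLOS labels.
#' @param features Which representation feeds the head: fused codes
#'   (default) or one modality's code alone (for single-modal baselines).
#' @return The model with `head` set.
#' @export
fit_head <- function(model, x_e, x_o, y,
                     features = c("fused", "e", "o")) {
  features <- match.arg(features)
  F_ <- switch(features,
    fused = fuse_features(model, x_e, x_o),
    e = dra_encode(model$ae_e, x_e),
    o = dra_encode(model$ae_o, x_o))
  F_ <- as.matrix(F_)
  model$head <- list(coef = fit_linear_head(F_, y), features = features)
  model
}

#' Predict PERCLOS
#'
#' Applies the fitted regression head to the model's representation of new
#' epochs; predictions are clipped to \[0, 1\].
#'
#' @param model A `dcra` with a fitted head ([fit_head()]).
#' @param x_e,x_o Feature arrays for the epochs to score.
#' @return Numeric vector of predicted PERCLOS values in \[0, 1\].
#' @export
predict_perclos <- function(model, x_e, x_o = NULL) {
  if (is.null(model$head)) stop("model has no fitted head; call fit_head()")
  F_ <- switch(model$head$features,
    fused = fuse_features(model, x_e, x_o),
    e = dra_encode(model$ae_e, x_e),
    o = dra_encode(model$ae_o, x_o))
  F_ <- if (is.null(dim(F_))) matrix(F_, 1) else as.matrix(F_)
  pred <- drop(cbind(1, F_) %*% model$head$coef)
  pmin(pmax(pred, 0), 1)
}

#' Mean cross-modal code distance
#'
#' Average Euclidean distance between the two modalities' codes over a set
#' of epochs; the quantity that the coupling term of the joint loss drives
#' down as alpha grows.
#'
#' @param model A trained `dcra`.
#' @param x_e,x_o Feature arrays.
#' @return Non-negative scalar.
#' @export
code_distance <- function(model, x_e, x_o) {
  ce <- as.matrix(dra_encode(model$ae_e, x_e))
  co <- as.matrix(dra_encode(model$ae_o, x_o))
  mean(sqrt(rowSums((ce - co)^2)))
}

#' Sweep the coupling weight alpha
#'
#' Trains one coupled model per requested alpha (shared seed and schedule)
#' and reports the cross-validated pooled RMSE of the fused PERCLOS
#' prediction for each.
#'
#' @param session A `vigilance_session` (unstandardized; folds are
#'   standardized internally).
#' @param alphas Numeric vector of coupling weights in \[0, 1\] (>= 2).
#' @param config A [dcra_config()]; its `alpha` is overridden per run.
#' @param k Number of cross-validation folds.
#' @return Data frame with one row per alpha: `alpha`, `rmse`, `pcc`.
#' @export
alpha_sweep <- function(session, alphas, config = dcra_config(), k = 5) {
  if (length(alphas) < 2) stop("need at least two alpha values")
  if (any(alphas < 0 | alphas > 1)) stop("alpha values must lie in [0, 1]")
  rows <- lapply(alphas, function(a) {
    cfg <- config; cfg$alpha <- a
    rep_ <- kfold_cv(session, cfg, k = k)
    data.frame(alpha = a, rmse = rep_$rmse, pcc = rep_$pcc)
  })
  do.call(rbind, rows)
}
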