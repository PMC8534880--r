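# Deep recurrent auto-encoder (DRA): a three-layer GRU encoder, a linear
# projection to a narrow code (the coupling width), and a mirrored
# three-layer GRU decoder that consumes the code repeated at every time
# step. Default shapes follow the standard vigilance architecture:
# dim -> dim -> 20 -> 16 -> [code 10] -> 16 -> 20 -> dim, ReLU activations
# except a Sigmoid on the output layer, batch norm after layers 2,3,5,6.

# Deterministic sub-seed derivation so each component (per-modality init,
# batching, pair sampling, ...) is independently reproducible from one seed.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Construct a deep recurrent auto-encoder
#'
#' @param input_dim Feature dimension of the modality.
#' @param hidden_units Units of the two inner encoder layers (mirrored by
#'   the decoder). Default `c(20, 16)`; the first encoder layer always has
#'   `input_dim` units.
#' @param code_dim Width of the code / coupling layer. Default 10.
#' @param batch_norm Apply batch normalization after encoder layers 2 and 3
#'   and decoder layers 1 and 2. Default TRUE.
#' @param seed Integer seed for the fan-in scaled uniform initialization.
#' @return An object of class `dra` holding the encoder stack, the linear
#'   coupling-width projection, and the decoder stack.
#' @export
new_dra <- function(input_dim, hidden_units = c(20, 16), code_dim = 10,
                    batch_norm = TRUE, seed = 1L) {
  stopifnot(input_dim >= 1, length(hidden_units) >= 1, code_dim >= 1)
  set.seed(seed)
  enc_units <- c(input_dim, hidden_units)
  enc <- list()
  in_dim <- input_dim
  for (k in seq_along(enc_units)) {
    enc[[k]] <- gru_layer(in_dim, enc_units[k], activation = "relu",
                          batch_norm = batch_norm && k > 1)
    in_dim <- enc_units[k]
  }
  proj <- list(W = init_mat(in_dim, code_dim), b = numeric(code_dim))
  dec_units <- rev(hidden_units)
  dec <- list()
  in_dim <- code_dim
  for (k in seq_along(dec_units)) {
    dec[[k]] <- gru_layer(in_dim, dec_units[k], activation = "relu",
                          batch_norm = batch_norm)
    in_dim <- dec_units[k]
  }
  dec[[length(dec) + 1]] <- gru_layer(in_dim, input_dim,
                                      activation = "sigmoid",
                                      batch_norm = FALSE)
  structure(list(
    input_dim = as.integer(input_dim),
    code_dim = as.integer(code_dim),
    encoder = enc, proj = proj, decoder = dec,
    seed = as.integer(seed)
  ), class = "dra")
}

as_batch <- function(X) {
  if (is.null(dim(X)) || length(dim(X)) == 2) {
    X <- as.matrix(X)
    array(X, dim = c(1, nrow(X), ncol(X)))
  } else X
}

#' Encode sequences to coupling-layer codes
#'
#' Runs the encoder stack over each epoch's feature sequence and maps the
#' final hidden state of the last encoder layer through the linear
#' coupling-width projection. The code depends only on encoder parameters.
#'
#' @param dra A [new_dra()] model.
#' @param X A `T x dim` matrix or `B x T x dim` array of feature sequences.
#' @param train Logical; training-mode batch norm (batch statistics).
#' @return A `B x code_dim` matrix of codes (a vector if one sequence).
#' @export
dra_encode <- function(dra, X, train = FALSE) {
  single <- length(dim(as.matrix(X))) == 2 && length(dim(X)) != 3
  Xb <- as_batch(X)
  fw <- run_stack(dra$encoder, Xb, train = train)
  hT <- fw$final_hidden[[length(dra$encoder)]]
  code <- add_bias(hT %*% dra$proj$W, dra$proj$b)
  if (single) drop(code) else code
}

#' Decode codes back to feature sequences
#'
#' Repeats each code at every time step as input to the decoder stack; the
#' final decoder layer applies its sigmoid activation to produce the
#' reconstruction.
#'
#' @param dra A [new_dra()] model.
#' @param code A code vector or `B x code_dim` matrix.
#' @param T_ Number of time steps to reconstruct (positive).
#' @param train Logical; training-mode batch norm.
#' @return A `T x dim` matrix (single code) or `B x T x dim` array.
#' @export
dra_decode <- function(dra, code, T_, train = FALSE) {
  if (T_ <= 0) stop("T_ must be positive")
  single <- is.null(dim(code))
  code <- if (single) matrix(code, 1) else as.matrix(code)
  B <- nrow(code)
  Xd <- array(0, dim = c(B, T_, ncol(code)))
  for (t in seq_len(T_)) Xd[, t, ] <- code
  fw <- run_stack(dra$decoder, Xd, train = train)
  if (single) matrix(fw$out[1, , ], T_) else fw$out
}

# Full forward pass with caches for backprop. X: [B, T, dim].
dra_forward <- function(dra, X, train = FALSE) {
  B <- dim(X)[1]; T_ <- dim(X)[2]
  enc <- run_stack(dra$encoder, X, train = train)
  hT <- enc$final_hidden[[length(dra$encoder)]]
  code <- add_bias(hT %*% dra$proj$W, dra$proj$b)
  Xd <- array(0, dim = c(B, T_, dra$code_dim))
  for (t in seq_len(T_)) Xd[, t, ] <- code
  dec <- run_stack(dra$decoder, Xd, train = train)
  recon <- dec$out
  loss <- sum((recon - X)^2) / B
  list(code = code, recon = recon, loss = loss, hT = hT,
       enc = enc, dec = dec, B = B, T_ = T_)
}

# Backward pass. dRecon: gradient wrt the reconstruction [B, T, dim];
# dCode_extra: extra gradient flowing into the code (e.g. the coupling
# term), [B, code_dim] or NULL.
dra_backward <- function(dra, fw, dRecon, dCode_extra = NULL) {
  dec_bw <- stack_backward(dra$decoder, fw$dec$caches, dRecon)
  # decoder input was the code repeated at every step: sum over time
  dcode <- colSums(aperm(dec_bw$dX, c(2, 1, 3)))
  if (fw$B == 1) dcode <- matrix(dcode, 1)
  if (!is.null(dCode_extra)) dcode <- dcode + dCode_extra
  dW <- crossprod(fw$hT, dcode)
  db <- colSums(dcode)
  dhT <- dcode %*% t(dra$proj$W)
  dOut_enc <- array(0, dim = dim(fw$enc$layer_outputs[[length(dra$encoder)]]))
  dOut_enc[, fw$T_, ] <- dhT
  enc_bw <- stack_backward(dra$encoder, fw$enc$caches, dOut_enc)
  list(enc = lapply(enc_bw$grads, identity),
       proj = list(W = dW, b = db),
       dec = lapply(dec_bw$grads, identity))
}

dra_params <- function(dra) {
  list(enc = lapply(dra$encoder, function(l) l$params),
       proj = dra$proj,
       dec = lapply(dra$decoder, function(l) l$params))
}

dra_set_params <- function(dra, p) {
  for (k in seq_along(dra$encoder)) dra$encoder[[k]]$params <- p$enc[[k]]
  dra$proj <- p$proj
  for (k in seq_along(dra$decoder)) dra$decoder[[k]]$params <- p$dec[[k]]
  dra
}

# Adopt the batch-norm running statistics recorded during a forward pass.
dra_adopt_stats <- function(dra, fw) {
  for (k in seq_along(dra$encoder)) {
    dra$encoder[[k]]$stats <- fw$enc$stack[[k]]$stats
  }
  for (k in seq_along(dra$decoder)) {
    dra$decoder[[k]]$stats <- fw$dec$stack[[k]]$stats
  }
  dra
}

# Minibatch index stream: a list of index vectors covering a shuffled 1..n.
make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

#' Greedy layer-wise pretraining of an encoder stack
#'
#' Trains each GRU layer in turn as a shallow recurrent auto-encoder: the
#' layer runs over its input sequence (the frozen activated output of the
#' previous layer) and a per-step linear readout reconstructs that input;
#' the squared reconstruction error is minimized with Adam. The readout is
#' discarded after each layer; only the GRU parameters are kept.
#'
#' @param X `n x T x dim` array of training sequences.
#' @param stack List of [gru_layer()] objects to pretrain (ordered).
#' @param steps Adam steps per layer (0 returns the initialization).
#' @param lr Learning rate (default 0.001).
#' @param batch_size Minibatch size (default 32).
#' @param seed Seed for minibatch sampling.
#' @return List with the trained `stack` and `traces`, a list of per-layer
#'   loss vectors (one value per optimization step).
#' @export
pretrain_layers <- function(X, stack, steps = 50, lr = 1e-3,
                            batch_size = 32, seed = 1L) {
  if (dim(X)[1] < 1) stop("need at least one epoch of data")
  set.seed(seed)
  n <- dim(X)[1]
  cur <- X
  traces <- vector("list", length(stack))
  for (k in seq_along(stack)) {
    layer <- stack[[k]]
    in_dim <- layer$input_dim
    readout <- list(V = init_mat(layer$units, in_dim), c = numeric(in_dim))
    params <- list(layer = layer$params, readout = readout)
    opt <- adam_init(params)
    trace <- numeric(0)
    if (steps > 0) {
      batches <- list()
      for (s in seq_len(steps)) {
        if (length(batches) == 0) batches <- make_batches(n, batch_size)
        idx <- batches[[1]]; batches <- batches[-1]
        U <- cur[idx, , , drop = FALSE]
        B <- length(idx); T_ <- dim(U)[2]
        layer$params <- params$layer
        fwd <- gru_layer_forward(layer, U, train = TRUE)
        Aflat <- matrix(fwd$out, B * T_, layer$units)
        Xhat <- add_bias(Aflat %*% params$readout$V, params$readout$c)
        Uflat <- matrix(U, B * T_, in_dim)
        loss <- sum((Xhat - Uflat)^2) / B
        if (!is.finite(loss)) {
          stop("divergent pretraining loss in layer ", k)
        }
        trace <- c(trace, loss)
        dXhat <- 2 * (Xhat - Uflat) / B
        gV <- crossprod(Aflat, dXhat)
        gc_ <- colSums(dXhat)
        dA <- array(dXhat %*% t(params$readout$V),
                    dim = c(B, T_, layer$units))
        bw <- gru_layer_backward(layer, fwd$cache, dA)
        grads <- list(layer = bw$grads, readout = list(V = gV, c = gc_))
        upd <- adam_step(params, grads, opt, lr = lr)
        params <- upd$params; opt <- upd$state
        layer$stats <- fwd$stats
      }
    }
    layer$params <- params$layer
    stack[[k]] <- layer
    traces[[k]] <- trace
    # frozen output (inference-mode batch norm) feeds the next layer
    cur <- gru_layer_forward(layer, cur, train = FALSE)$out
  }
  list(stack = stack, traces = traces)
}
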