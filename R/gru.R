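# Gated recurrent unit machinery: single cell, layers operating on batched
# sequences, batch normalization, and the analytic backward passes used by
# the trainers. The forward math follows the GRU recurrences with
# the update gate multiplying the PREVIOUS hidden state:
#   z(t) = sigmoid(x W_xz + h(t-1) W_hz + b_z)
#   r(t) = sigmoid(x W_xr + h(t-1) W_hr + b_r)
#   g(t) = tanh(x W_xg + (r(t) * h(t-1)) W_hg + b_g)
#   h(t) = z(t) * h(t-1) + (1 - z(t)) * g(t)
# (row-vector convention: weights are [input_dim x units] / [units x units]).

sigmoid <- function(x) 1 / (1 + exp(-x))

act_forward <- function(x, activation) {
  switch(activation,
    relu = pmax(x, 0),
    sigmoid = sigmoid(x),
    tanh = tanh(x),
    linear = x,
    stop("unknown activation: ", activation)
  )
}

# dX from dY given the activation OUTPUT a (sufficient for these four).
act_backward <- function(dy, a, activation) {
  switch(activation,
    relu = dy * (a > 0),
    sigmoid = dy * a * (1 - a),
    tanh = dy * (1 - a^2),
    linear = dy,
    stop("unknown activation: ", activation)
  )
}

# Fan-in scaled uniform init, the standard default for small recurrent nets.
init_mat <- function(nr, nc) {
  lim <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Construct one GRU layer
#'
#' Creates the parameter set of a single gated-recurrent-unit layer: three
#' input weight matrices, three recurrent weight matrices and three bias
#' vectors (update gate `z`, reset gate `r`, candidate state `g`), plus an
#' optional batch-normalization block applied to the hidden-state sequence
#' before the layer activation.
#'
#' @param input_dim Width of the input vectors fed to the layer.
#' @param units Number of hidden units.
#' @param activation Output activation applied to the hidden sequence
#'   (`"relu"`, `"sigmoid"`, `"tanh"` or `"linear"`). The gate
#'   nonlinearities themselves are fixed (logistic and tanh).
#' @param batch_norm Logical; normalize the hidden sequence per feature over
#'   batch and time before the activation, with learned gain/offset and
#'   running statistics for inference.
#' @return An object of class `gru_layer`.
#' @export
gru_layer <- function(input_dim, units, activation = "relu",
                      batch_norm = FALSE) {
  params <- list(
    W_xz = init_mat(input_dim, units),
    W_xr = init_mat(input_dim, units),
    W_xg = init_mat(input_dim, units),
    W_hz = init_mat(units, units),
    W_hr = init_mat(units, units),
    W_hg = init_mat(units, units),
    b_z = numeric(units),
    b_r = numeric(units),
    b_g = numeric(units)
  )
  if (batch_norm) {
    params$gamma <- rep(1, units)
    params$beta <- numeric(units)
  }
  structure(list(
    input_dim = as.integer(input_dim),
    units = as.integer(units),
    activation = activation,
    batch_norm = batch_norm,
    params = params,
    stats = if (batch_norm) {
      list(mean = numeric(units), var = rep(1, units), momentum = 0.9)
    }
  ), class = "gru_layer")
}

#' One GRU cell step
#'
#' Advances a single GRU cell by one time step, returning the new hidden
#' state and the three gate activations. The update gate `z` multiplies the
#' previous hidden state, so a saturated update gate (`z -> 1`) carries the
#' old state through unchanged.
#'
#' @param params A list (or the `params` element of a [gru_layer()]) with
#'   `W_xz, W_xr, W_xg` (`input_dim x units`), `W_hz, W_hr, W_hg`
#'   (`units x units`) and `b_z, b_r, b_g` (`units`).
#' @param x_t Input vector at time t (length `input_dim`).
#' @param h_prev Hidden state at time t-1 (length `units`).
#' @return List with `h`, `z`, `r`, `g`, each of length `units`; `z` and `r`
#'   lie in (0, 1), `g` in (-1, 1), and `h` is the elementwise convex
#'   combination `z * h_prev + (1 - z) * g`.
#' @export
gru_cell_step <- function(params, x_t, h_prev) {
  if ("params" %in% names(params)) params <- params$params
  u <- length(params$b_z)
  if (length(x_t) != nrow(params$W_xz) || length(h_prev) != u) {
    stop("dimension mismatch: x_t must have length ", nrow(params$W_xz),
         " and h_prev length ", u)
  }
  x <- matrix(x_t, 1); h <- matrix(h_prev, 1)
  z <- sigmoid(x %*% params$W_xz + h %*% params$W_hz +
                 rep(params$b_z, each = 1))
  r <- sigmoid(x %*% params$W_xr + h %*% params$W_hr +
                 rep(params$b_r, each = 1))
  g <- tanh(x %*% params$W_xg + (r * h) %*% params$W_hg +
              rep(params$b_g, each = 1))
  h_t <- z * h + (1 - z) * g
  list(h = drop(h_t), z = drop(z), r = drop(r), g = drop(g))
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Forward pass of one layer over a batched sequence.
# X: [B, T, input_dim]; returns activated output [B, T, units] plus caches.
# train = TRUE uses batch statistics for BN (and records them for backward);
# train = FALSE uses running statistics.
gru_layer_forward <- function(layer, X, train = FALSE) {
  p <- layer$params
  B <- dim(X)[1]; T_ <- dim(X)[2]; u <- layer$units
  if (dim(X)[3] != layer$input_dim) {
    stop("layer expects input dim ", layer$input_dim, ", got ", dim(X)[3])
  }
  Z <- R <- G <- H <- array(0, dim = c(B, T_, u))
  h <- matrix(0, B, u)
  for (t in seq_len(T_)) {
    x <- matrix(X[, t, ], B)
    z <- sigmoid(add_bias(x %*% p$W_xz + h %*% p$W_hz, p$b_z))
    r <- sigmoid(add_bias(x %*% p$W_xr + h %*% p$W_hr, p$b_r))
    g <- tanh(add_bias(x %*% p$W_xg + (r * h) %*% p$W_hg, p$b_g))
    h_new <- z * h + (1 - z) * g
    Z[, t, ] <- z; R[, t, ] <- r; G[, t, ] <- g; H[, t, ] <- h_new
    h <- h_new
  }
  bn_cache <- NULL
  Hn <- H
  new_stats <- layer$stats
  if (layer$batch_norm) {
    flat <- matrix(H, B * T_, u)
    eps <- 1e-5
    if (train) {
      mu <- colMeans(flat)
      cen <- sweep(flat, 2, mu, "-")
      va <- colMeans(cen^2)
      invstd <- 1 / sqrt(va + eps)
      xhat <- sweep(cen, 2, invstd, "*")
      mom <- layer$stats$momentum
      new_stats$mean <- mom * layer$stats$mean + (1 - mom) * mu
      new_stats$var <- mom * layer$stats$var + (1 - mom) * va
      bn_cache <- list(xhat = xhat, invstd = invstd)
    } else {
      invstd <- 1 / sqrt(layer$stats$var + eps)
      xhat <- sweep(sweep(flat, 2, layer$stats$mean, "-"), 2, invstd, "*")
    }
    out_flat <- add_bias(sweep(xhat, 2, p$gamma, "*"), p$beta)
    Hn <- array(out_flat, dim = c(B, T_, u))
  }
  A <- act_forward(Hn, layer$activation)
  list(out = A,
       cache = list(X = X, Z = Z, R = R, G = G, H = H, A = A,
                    bn = bn_cache, B = B, T_ = T_),
       stats = new_stats,
       final_hidden = matrix(A[, T_, ], B))
}

# Backward pass of one layer. dOut: gradient wrt the activated output
# [B, T, units]. Returns parameter gradients (same shapes/names as params)
# and dX [B, T, input_dim].
gru_layer_backward <- function(layer, cache, dOut) {
  p <- layer$params
  B <- cache$B; T_ <- cache$T_; u <- layer$units
  dA <- act_backward(dOut, cache$A, layer$activation)
  grads <- lapply(p, function(w) w * 0)
  if (layer$batch_norm) {
    flat_dy <- matrix(dA, B * T_, u)
    xhat <- cache$bn$xhat; invstd <- cache$bn$invstd
    N <- B * T_
    grads$gamma <- colSums(flat_dy * xhat)
    grads$beta <- colSums(flat_dy)
    dxhat <- sweep(flat_dy, 2, p$gamma, "*")
    sum_dxhat <- colSums(dxhat)
    sum_dxhat_xhat <- colSums(dxhat * xhat)
    dflat <- sweep(
      N * dxhat - rep(1, N) %o% sum_dxhat -
        sweep(xhat, 2, sum_dxhat_xhat, "*"),
      2, invstd / N, "*")
    dHseq <- array(dflat, dim = c(B, T_, u))
  } else {
    dHseq <- dA
  }
  dX <- array(0, dim = dim(cache$X))
  dh_next <- matrix(0, B, u)
  tW_hg <- t(p$W_hg); tW_xg <- t(p$W_xg)
  tW_hr <- t(p$W_hr); tW_xr <- t(p$W_xr)
  tW_hz <- t(p$W_hz); tW_xz <- t(p$W_xz)
  for (t in seq(T_, 1)) {
    dh <- matrix(dHseq[, t, ], B) + dh_next
    z <- matrix(cache$Z[, t, ], B)
    r <- matrix(cache$R[, t, ], B)
    g <- matrix(cache$G[, t, ], B)
    h_prev <- if (t > 1) matrix(cache$H[, t - 1, ], B) else matrix(0, B, u)
    x <- matrix(cache$X[, t, ], B)

    dz <- dh * (h_prev - g)
    dg <- dh * (1 - z)
    dh_prev <- dh * z

    da_g <- dg * (1 - g^2)
    grads$W_xg <- grads$W_xg + crossprod(x, da_g)
    grads$W_hg <- grads$W_hg + crossprod(r * h_prev, da_g)
    grads$b_g <- grads$b_g + colSums(da_g)
    drh <- da_g %*% tW_hg
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    dX[, t, ] <- dX[, t, ] + da_g %*% tW_xg

    da_r <- dr * r * (1 - r)
    grads$W_xr <- grads$W_xr + crossprod(x, da_r)
    grads$W_hr <- grads$W_hr + crossprod(h_prev, da_r)
    grads$b_r <- grads$b_r + colSums(da_r)
    dh_prev <- dh_prev + da_r %*% tW_hr
    dX[, t, ] <- dX[, t, ] + da_r %*% tW_xr

    da_z <- dz * z * (1 - z)
    grads$W_xz <- grads$W_xz + crossprod(x, da_z)
    grads$W_hz <- grads$W_hz + crossprod(h_prev, da_z)
    grads$b_z <- grads$b_z + colSums(da_z)
    dh_prev <- dh_prev + da_z %*% tW_hz
    dX[, t, ] <- dX[, t, ] + da_z %*% tW_xz

    dh_next <- dh_prev
  }
  list(grads = grads, dX = dX)
}

#' Run a stack of GRU layers over a sequence
#'
#' Feeds a sequence through stacked GRU layers: layer k consumes the full
#' activated hidden-state sequence of layer k-1. All hidden states start at
#' zero; the pass is deterministic given parameters and input.
#'
#' @param stack A list of [gru_layer()] objects (a `gru_stack`).
#' @param X Either a `T x dim` matrix (one sequence) or a `B x T x dim`
#'   array (a batch).
#' @param train Logical; use batch statistics for batch-norm layers
#'   (training mode) instead of running statistics.
#' @return A list with `out` (activated output sequence of the last layer,
#'   same leading shape as `X`), `layer_outputs` (list of per-layer output
#'   sequences), `final_hidden` (list of per-layer final activated hidden
#'   states), and internal caches.
#' @export
run_stack <- function(stack, X, train = FALSE) {
  single <- length(dim(X)) == 2 || is.null(dim(X))
  if (single) {
    X <- array(as.matrix(X), dim = c(1, nrow(as.matrix(X)), ncol(as.matrix(X))))
  }
  if (dim(X)[2] < 1) stop("empty sequence")
  caches <- list(); outs <- list(); finals <- list()
  cur <- X
  for (k in seq_along(stack)) {
    fw <- gru_layer_forward(stack[[k]], cur, train = train)
    caches[[k]] <- fw$cache
    outs[[k]] <- fw$out
    finals[[k]] <- fw$final_hidden
    stack[[k]]$stats <- fw$stats
    cur <- fw$out
  }
  if (single) {
    outs <- lapply(outs, function(a) matrix(a[1, , ], dim(a)[2]))
    finals <- lapply(finals, function(m) drop(m))
    cur <- matrix(cur[1, , ], dim(X)[2])
  }
  list(out = cur, layer_outputs = outs, final_hidden = finals,
       caches = caches, stack = stack)
}

# Backward through a whole stack given dOut for the last layer's output.
# Returns per-layer grads (list) and dX at the stack input.
stack_backward <- function(stack, caches, dOut) {
  grads <- vector("list", length(stack))
  d <- dOut
  for (k in seq(length(stack), 1)) {
    bw <- gru_layer_backward(stack[[k]], caches[[k]], d)
    grads[[k]] <- bw$grads
    d <- bw$dX
  }
  list(grads = grads, dX = d)
}

# ---- generic nested-list parameter utilities (used by Adam) ----

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_sum <- function(f, a) {
  if (is.list(a)) sum(vapply(a, function(x) tree_sum(f, x), numeric(1)))
  else f(a)
}

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

# One Adam update; returns list(params, state).
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}
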