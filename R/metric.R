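# Mahalanobis metric learning by the probabilistic global distance metric
# (PGDM) formulation: minimize the summed squared metric distance over
# same-class pairs subject to the summed metric distance over
# different-class pairs staying >= 1, with M symmetric positive
# semi-definite. The unconstrained surrogate
#   g(M) = sum_S d_M(x_i, x_j)^2 - log( sum_D d_M(x_i, x_j) )
# is minimized by projected gradient descent (gradient step, symmetrize,
# clip negative eigenvalues), then M is rescaled so the D-constraint holds.

#' Construct / validate a Mahalanobis metric matrix
#'
#' Wraps a symmetric positive semi-definite matrix `M` together with a
#' factor `P` such that `M = P P^T`, so the metric distance equals the
#' Euclidean norm of `P^T`-projected differences.
#'
#' @param M A symmetric PSD matrix.
#' @param tol Tolerance for the symmetry / eigenvalue checks.
#' @return An object of class `metric_matrix` with elements `M`, `P`, `d`.
#' @export
metric_matrix <- function(M, tol = 1e-8) {
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("M has non-finite entries")
  if (nrow(M) != ncol(M)) stop("M must be square")
  if (max(abs(M - t(M))) > 1e-10) stop("M must be symmetric")
  eg <- eigen(M, symmetric = TRUE)
  if (min(eg$values) < -tol) {
    stop("M is not positive semi-definite (min eigenvalue ",
         format(min(eg$values)), ")")
  }
  vals <- pmax(eg$values, 0)
  P <- eg$vectors %*% diag(sqrt(vals), nrow(M))
  structure(list(M = M, P = P, d = nrow(M)), class = "metric_matrix")
}

#' @export
print.metric_matrix <- function(x, ...) {
  eg <- eigen(x$M, symmetric = TRUE, only.values = TRUE)$values
  cat("<metric_matrix> d =", x$d, "; eigenvalues in [",
      format(min(eg), digits = 4), ",", format(max(eg), digits = 4), "]\n")
  invisible(x)
}

#' Project a square matrix onto the PSD cone
#'
#' Symmetrizes `(A + A^T)/2`, then clips negative eigenvalues to zero. This
#' is the projection step of the PGDM optimizer and also the way arbitrary
#' matrices are coerced into valid metrics.
#'
#' @param A A square numeric matrix.
#' @return A [metric_matrix()].
#' @export
psd_project <- function(A) {
  A <- as.matrix(A)
  if (any(!is.finite(A))) stop("A has non-finite entries")
  if (nrow(A) != ncol(A)) stop("A must be square")
  S <- (A + t(A)) / 2
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  M <- eg$vectors %*% diag(vals, nrow(S)) %*% t(eg$vectors)
  M <- (M + t(M)) / 2
  metric_matrix(M)
}

#' Mahalanobis distance under a learned metric
#'
#' `sqrt((x - y)^T M (x - y))`, clipped at zero against negative round-off.
#' With `M` the identity this is the Euclidean distance.
#'
#' @param metric A [metric_matrix()] (or a plain PSD matrix).
#' @param x,y Numeric vectors of length `d`.
#' @return A non-negative scalar.
#' @export
mahalanobis_dist <- function(metric, x, y) {
  M <- if (inherits(metric, "metric_matrix")) metric$M else
    metric_matrix(metric)$M
  if (length(x) != nrow(M) || length(y) != nrow(M)) {
    stop("x and y must have length ", nrow(M))
  }
  d <- x - y
  sqrt(max(0, drop(crossprod(d, M %*% d))))
}

#' Sample same-class and different-class index pairs
#'
#' Builds the pair constraints for PGDM: up to `max_pairs` pairs of samples
#' with equal class labels (set S) and up to `max_pairs` pairs with unequal
#' labels (set D), sampled uniformly without replacement, reproducibly.
#'
#' @param features `n x d` numeric matrix of samples.
#' @param labels Integer/factor class label per row; at least two classes.
#' @param max_pairs Maximum pairs kept in each of S and D.
#' @param seed Sampling seed.
#' @return An object of class `pair_sets`: list with `S`, `D` (2-column
#'   index matrices) and `features`.
#' @export
build_pair_sets <- function(features, labels, max_pairs = 1000, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(labels) == n, max_pairs >= 1)
  if (length(unique(labels)) < 2) {
    stop("need at least two classes (D would be empty)")
  }
  all_pairs <- t(utils::combn(n, 2))
  same <- labels[all_pairs[, 1]] == labels[all_pairs[, 2]]
  S <- all_pairs[same, , drop = FALSE]
  D <- all_pairs[!same, , drop = FALSE]
  set.seed(derive_seed(seed, "pairs"))
  if (nrow(S) > max_pairs) S <- S[sample.int(nrow(S), max_pairs), , drop = FALSE]
  if (nrow(D) > max_pairs) D <- D[sample.int(nrow(D), max_pairs), , drop = FALSE]
  structure(list(S = S, D = D, features = features),
            class = "pair_sets")
}

pair_diffs <- function(pairs, which = c("S", "D")) {
  which <- match.arg(which)
  idx <- pairs[[which]]
  pairs$features[idx[, 1], , drop = FALSE] -
    pairs$features[idx[, 2], , drop = FALSE]
}

#' PGDM objective
#'
#' `g(M) = sum_S d_M^2 - log(sum_D d_M)`: the unconstrained surrogate of the
#' metric-learning program (same-class compactness, with the log of the
#' different-class distance sum replacing the hard constraint).
#'
#' @param metric A [metric_matrix()] or PSD matrix.
#' @param pairs A [build_pair_sets()] result.
#' @return Scalar loss value.
#' @export
pgdm_loss <- function(metric, pairs) {
  M <- if (inherits(metric, "metric_matrix")) metric$M else as.matrix(metric)
  dS <- pair_diffs(pairs, "S")
  dD <- pair_diffs(pairs, "D")
  s_term <- if (nrow(dS)) sum(rowSums((dS %*% M) * dS)) else 0
  d_dists <- sqrt(pmax(0, rowSums((dD %*% M) * dD)))
  d_sum <- sum(d_dists)
  if (d_sum <= 0) stop("sum of different-class distances is zero: log undefined")
  s_term - log(d_sum)
}

# Gradient of g(M): sum_S dd^T - (1/sum_D d) * sum_D dd^T / (2 d).
pgdm_grad <- function(M, dS, dD) {
  d_ <- ncol(dS)
  gS <- crossprod(dS)                      # sum over S of dd^T
  dists <- sqrt(pmax(rowSums((dD %*% M) * dD), 1e-12))
  w <- 1 / (2 * dists * sum(dists))
  gD <- crossprod(dD * sqrt(w))            # sum w_i d_i d_i^T
  gS - gD
}

#' Fit a Mahalanobis metric by projected gradient descent (PGDM)
#'
#' Minimizes the PGDM surrogate [pgdm_loss()] over PSD matrices starting
#' from the identity: gradient step, symmetrize, eigenvalue-clip; the step
#' size is halved whenever a step would increase the loss, so the recorded
#' loss trace is non-increasing. On convergence the metric is rescaled
#' (a positive scalar, which does not change the minimizer's direction) so
#' that the different-class distance sum satisfies the `>= 1` constraint.
#'
#' @param pairs A [build_pair_sets()] result (D non-empty).
#' @param max_iter Maximum accepted iterations (0 returns the projected
#'   initialization).
#' @param step Initial gradient step size.
#' @param tol Relative loss-change convergence tolerance.
#' @return A [metric_matrix()] with attributes `trace` (loss per accepted
#'   iterate) and `final_loss`.
#' @export
pgdm_fit <- function(pairs, max_iter = 200, step = 0.1, tol = 1e-6) {
  stopifnot(inherits(pairs, "pair_sets"))
  d_ <- ncol(pairs$features)
  dS <- pair_diffs(pairs, "S")
  dD <- pair_diffs(pairs, "D")
  if (nrow(dD) == 0) stop("D is empty; cannot fit")
  M <- diag(d_)
  loss <- pgdm_loss(M, pairs)
  trace <- loss
  it <- 0
  while (it < max_iter) {
    G <- pgdm_grad(M, dS, dD)
    improved <- FALSE
    s <- step
    for (half in 1:40) {
      cand <- psd_project(M - s * G)$M
      # a step that collapses M makes the log term undefined; treat it as
      # too large and halve, like any other non-improving step
      cand_loss <- tryCatch(pgdm_loss(cand, pairs), error = function(e) Inf)
      if (is.finite(cand_loss) && cand_loss <= loss) { improved <- TRUE; break }
      s <- s / 2
    }
    if (!improved) break
    if (!is.finite(cand_loss)) stop("PGDM optimization diverged")
    rel <- abs(loss - cand_loss) / max(abs(loss), 1e-12)
    M <- cand; loss <- cand_loss; it <- it + 1
    trace <- c(trace, loss)
    if (rel < tol) break
  }
  # enforce the D-constraint sum_D d_M >= 1 by a positive rescale
  d_sum <- sum(sqrt(pmax(0, rowSums((dD %*% M) * dD))))
  if (d_sum > 0 && d_sum < 1) M <- M / d_sum^2
  out <- metric_matrix((M + t(M)) / 2)
  attr(out, "trace") <- trace
  attr(out, "final_loss") <- loss
  attr(out, "iterations") <- it
  out
}

#' Learn the coupling metric from single-modal auto-encoder codes
#'
#' Implements the preparatory metric-learning step of the coupled model:
#' both modalities are encoded with their (independently trained)
#' single-modal auto-encoders, the codes are pooled as samples in the
#' common coupling space, class labels are derived from PERCLOS via
#' [discretize_perclos()], pair constraints are sampled, and PGDM is fit.
#'
#' @param codes_e,codes_o `n x code_dim` matrices of per-epoch codes from
#'   the two modalities' encoders.
#' @param perclos_values PERCLOS label per epoch.
#' @param thresholds Class cut points passed to [discretize_perclos()].
#' @param max_pairs,max_iter,step,tol Passed to [build_pair_sets()] and
#'   [pgdm_fit()].
#' @param seed Pair-sampling seed.
#' @return A [metric_matrix()] of dimension `code_dim`.
#' @export
learn_metric <- function(codes_e, codes_o, perclos_values,
                         thresholds = c(0.35, 0.70),
                         max_pairs = 500, max_iter = 100,
                         step = 0.1, tol = 1e-6, seed = 1L) {
  codes <- rbind(as.matrix(codes_e), as.matrix(codes_o))
  labels <- rep(discretize_perclos(perclos_values, thresholds), 2)
  if (length(unique(labels)) < 2) {
    stop("PERCLOS labels fall in a single class; cannot learn a metric")
  }
  pairs <- build_pair_sets(codes, labels, max_pairs = max_pairs, seed = seed)
  pgdm_fit(pairs, max_iter = max_iter, step = step, tol = tol)
}
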