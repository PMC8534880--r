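# Evaluation: RMSE and Pearson correlation for PERCLOS regression,
# contiguous-block k-fold cross-validation, and the Friedman / Nemenyi
# machinery for comparing estimators ranked across datasets.

#' Root mean square error
#'
#' @param y,yhat Equal-length non-empty numeric vectors (true and predicted).
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    stop("y and yhat must be non-empty vectors of equal length")
  }
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation coefficient
#'
#' @param y,yhat Numeric vectors of equal length >= 2, neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
pcc <- function(y, yhat) {
  if (length(y) < 2 || length(y) != length(yhat)) {
    stop("y and yhat must have equal length >= 2")
  }
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("correlation undefined for a constant vector")
  }
  dy <- y - mean(y); dh <- yhat - mean(yhat)
  sum(dy * dh) / sqrt(sum(dy^2) * sum(dh^2))
}

# Contiguous-block fold assignment: k blocks whose sizes differ by <= 1.
contiguous_folds <- function(n, k) {
  if (k > n) stop("k must not exceed the number of epochs")
  sizes <- rep(floor(n / k), k) + c(rep(1, n %% k), rep(0, k - n %% k))
  rep(seq_len(k), times = sizes)
}

# Learn the coupling metric for a (standardized) session: train both
# single-modal auto-encoders (a decoupled alpha = 0 run), encode, and fit
# PGDM on the pooled codes with PERCLOS-derived class labels.
learn_metric_for_session <- function(xs, perclos_values, config,
                                     thresholds = c(0.35, 0.70),
                                     max_pairs = 500, max_iter = 100) {
  cfg0 <- config; cfg0$alpha <- 0
  solo <- train_engine(xs$e, xs$o, cfg0, NULL)
  learn_metric(dra_encode(solo$ae_e, xs$e), dra_encode(solo$ae_o, xs$o),
               perclos_values, thresholds = thresholds,
               max_pairs = max_pairs, max_iter = max_iter,
               seed = derive_seed(config$seed, "metric_pairs"))
}

#' k-fold cross-validated PERCLOS estimation
#'
#' Contiguous-block fold assignment (time blocks, avoiding temporal leakage
#' between neighbouring epochs), with standardization statistics, model
#' training, any metric learning, and head fitting all computed on the
#' training folds only.
#'
#' @param session A `vigilance_session` (raw; standardized per fold).
#' @param config A [dcra_config()].
#' @param k Number of folds (default 5).
#' @param metric_mode `"euclidean"` or `"learned"` (PGDM metric fitted per
#'   fold from single-modal codes).
#' @param features Representations for the regression head: `"fused"` codes
#'   and/or single modalities (`"e"`, `"o"`). Several may be requested at
#'   once; they share the fold's auto-encoder training (with coupling
#'   weight `config$alpha`) and differ only in the head. When only one
#'   single modality is requested, only that modality's auto-encoder is
#'   trained.
#' @return For a single requested representation, a list of class
#'   `eval_report`: pooled `rmse` and `pcc`, `per_fold` data frame, `folds`
#'   assignment, pooled `y` / `yhat`, and `code_distance` (mean held-out
#'   cross-modal code distance, NA when only one modality was trained).
#'   For several representations, a named list of such reports.
#' @export
kfold_cv <- function(session, config = dcra_config(), k = 5,
                     metric_mode = c("euclidean", "learned"),
                     features = "fused") {
  metric_mode <- match.arg(metric_mode)
  stopifnot(all(features %in% c("fused", "e", "o")), length(features) >= 1)
  n <- length(session$perclos)
  folds <- contiguous_folds(n, k)
  solo <- length(features) == 1 && features %in% c("e", "o")
  y_all <- numeric(n)
  yhat_all <- matrix(0, n, length(features),
                     dimnames = list(NULL, features))
  per_fold <- list()
  cdist <- numeric(k)
  for (f in seq_len(k)) {
    test <- which(folds == f); train <- which(folds != f)
    stats_e <- fit_standardizer(session$features_e[train, , , drop = FALSE])
    stats_o <- fit_standardizer(session$features_o[train, , , drop = FALSE])
    xs_tr <- list(
      e = standardize_array(session$features_e[train, , , drop = FALSE],
                            stats_e$center, stats_e$scale),
      o = standardize_array(session$features_o[train, , , drop = FALSE],
                            stats_o$center, stats_o$scale))
    xs_te <- list(
      e = standardize_array(session$features_e[test, , , drop = FALSE],
                            stats_e$center, stats_e$scale),
      o = standardize_array(session$features_o[test, , , drop = FALSE],
                            stats_o$center, stats_o$scale))
    y_tr <- session$perclos[train]
    y_te <- session$perclos[test]
    y_all[test] <- y_te

    if (solo) {
      model <- train_dra(xs_tr[[features]], config, modality = features)
      cdist[f] <- NA_real_
    } else {
      metric <- NULL
      if (metric_mode == "learned") {
        metric <- learn_metric_for_session(xs_tr, y_tr, config)
      }
      model <- train_engine(xs_tr$e, xs_tr$o, config, metric)
      cdist[f] <- code_distance(model, xs_te$e, xs_te$o)
    }
    for (feat in features) {
      m <- fit_head(model, xs_tr$e, xs_tr$o, y_tr, features = feat)
      pred <- predict_perclos(m, xs_te$e, xs_te$o)
      yhat_all[test, feat] <- pred
      per_fold[[length(per_fold) + 1]] <- data.frame(
        features = feat, fold = f, n = length(test),
        rmse = rmse(y_te, pred),
        pcc = if (stats::sd(y_te) > 0 && stats::sd(pred) > 0)
          pcc(y_te, pred) else NA_real_)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  reports <- lapply(features, function(feat) {
    structure(list(rmse = rmse(y_all, yhat_all[, feat]),
                   pcc = pcc(y_all, yhat_all[, feat]),
                   per_fold = per_fold[per_fold$features == feat, ],
                   folds = folds, y = y_all, yhat = yhat_all[, feat],
                   n = n, code_distance = mean(cdist)),
              class = "eval_report")
  })
  names(reports) <- features
  if (length(features) == 1) reports[[1]] else reports
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "; pooled RMSE =", sprintf("%.4f", x$rmse),
      ", PCC =", sprintf("%.4f", x$pcc), "\n")
  invisible(x)
}

#' Rank algorithms per dataset
#'
#' Ranks each row of a datasets-by-algorithms score matrix (1 = best, ties
#' get average ranks) and computes each algorithm's average order value
#' (AOV), its mean rank across datasets.
#'
#' @param scores Numeric matrix, rows = datasets, columns = algorithms
#'   (column names kept).
#' @param lower_is_better Logical; TRUE for error-type scores like RMSE.
#' @return An object of class `rank_table`: `scores`, `ranks`, `aov`, `k`
#'   (algorithms), `N` (datasets).
#' @export
rank_algorithms <- function(scores, lower_is_better = TRUE) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (ncol(scores) < 2) stop("need at least two algorithms")
  ranks <- t(apply(scores, 1, function(r) {
    rank(if (lower_is_better) r else -r, ties.method = "average")
  }))
  colnames(ranks) <- colnames(scores)
  structure(list(scores = scores, ranks = ranks, aov = colMeans(ranks),
                 k = ncol(scores), N = nrow(scores)),
            class = "rank_table")
}

as_rank_matrix <- function(x) {
  if (inherits(x, "rank_table")) x$ranks else as.matrix(x)
}

#' Friedman chi-square statistic
#'
#' `chi2_F = 12 / (N k (k+1)) * sum_j R_j^2 - 3 N (k+1)` with `R_j` the rank
#' sum of algorithm j over the `N` datasets and `k` algorithms.
#'
#' @param ranks A [rank_algorithms()] result or a rank matrix
#'   (datasets x algorithms).
#' @return The chi-square statistic (df = k - 1 under the null).
#' @export
friedman_statistic <- function(ranks) {
  R <- as_rank_matrix(ranks)
  k <- ncol(R); N <- nrow(R)
  if (k < 2) stop("need at least two algorithms")
  Rj <- colSums(R)
  12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
}

# Studentized-range-based critical values q_alpha for the Nemenyi test at
# alpha = 0.05, k = 2..10 (two-tailed, infinite df).
nemenyi_q05 <- c(`2` = 1.960, `3` = 2.343, `4` = 2.569, `5` = 2.728,
                 `6` = 2.850, `7` = 2.949, `8` = 3.031, `9` = 3.102,
                 `10` = 3.164)

#' Nemenyi critical difference
#'
#' `CD = q_alpha * sqrt(k (k+1) / (6 N))`: two algorithms whose average
#' order values differ by more than CD are declared significantly different.
#'
#' @param k Number of algorithms (>= 2).
#' @param N Number of datasets (>= 1).
#' @param q_alpha Critical value of the studentized range statistic; if
#'   NULL, looked up from the built-in alpha = 0.05 table (k <= 10).
#' @return The critical difference.
#' @export
nemenyi_cd <- function(k, N, q_alpha = NULL) {
  if (k < 2 || N < 1) stop("need k >= 2 and N >= 1")
  if (is.null(q_alpha)) {
    if (!as.character(k) %in% names(nemenyi_q05)) {
      stop("no built-in q_alpha for k = ", k, "; supply one")
    }
    q_alpha <- nemenyi_q05[[as.character(k)]]
  }
  if (q_alpha < 0) stop("q_alpha must be non-negative")
  q_alpha * sqrt(k * (k + 1) / (6 * N))
}

#' Critical-difference diagram and pairwise significance table
#'
#' For each algorithm, draws its average order value with a horizontal
#' segment of width CD centred on it; two algorithms whose segments do not
#' overlap (|AOV_i - AOV_j| > CD) differ significantly. Also returns the
#' full pairwise significance table.
#'
#' @param rank_table A [rank_algorithms()] result.
#' @param cd The critical difference ([nemenyi_cd()]).
#' @param file Optional path; if given, the diagram is saved there
#'   (format from the extension, via [ggplot2::ggsave()]).
#' @return List with `plot` (a ggplot) and `pairs` (data frame with
#'   `algo_i`, `algo_j`, `diff`, `significant`).
#' @export
cd_diagram <- function(rank_table, cd, file = NULL) {
  stopifnot(inherits(rank_table, "rank_table"), cd >= 0)
  aov <- rank_table$aov
  algos <- names(aov)
  if (is.null(algos)) algos <- paste0("algo", seq_along(aov))
  pr <- t(utils::combn(length(aov), 2))
  pairs <- data.frame(
    algo_i = algos[pr[, 1]], algo_j = algos[pr[, 2]],
    diff = abs(aov[pr[, 1]] - aov[pr[, 2]]),
    row.names = NULL)
  pairs$significant <- pairs$diff > cd
  df <- data.frame(algorithm = factor(algos, levels = algos[order(aov)]),
                   aov = unname(aov))
  half <- if (is.finite(cd)) cd / 2 else max(diff(range(aov)), 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = aov, y = algorithm)) +
    ggplot2::geom_segment(ggplot2::aes(x = aov - half, xend = aov + half,
                                       yend = algorithm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "average order value (mean rank)", y = NULL,
                  title = sprintf("Critical difference = %.3f", cd)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 3)
  list(plot = p, pairs = pairs)
}

#' Published benchmark ranks of six vigilance estimators
#'
#' The rank table (five evaluation datasets by six algorithms) reported in
#' the vigilance-estimation literature for the coupled recurrent
#' auto-encoder variants (Mahalanobis and Euclidean coupling), the
#' LSTM-capsule-attention model, DNNSN, LSTM, and GELM. Used to reproduce
#' the published average order values and Nemenyi comparisons.
#'
#' @return Numeric matrix of ranks, rows = datasets D1..D5.
#' @export
vigilance_rank_table <- function() {
  path <- system.file("extdata", "vigilance_rank_table.tsv", package = "dcra")
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
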