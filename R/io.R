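# Readers and writers: sessions as a directory of delimited text tables
# plus YAML metadata, run configuration files, model archives, and
# prediction tables.

flatten_features <- function(arr) {
  d <- dim(arr)
  df <- data.frame(
    epoch = rep(seq_len(d[1]), each = d[2]),
    step = rep(seq_len(d[2]), times = d[1]))
  mat <- matrix(aperm(arr, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(mat) <- paste0("f", seq_len(d[3]))
  cbind(df, as.data.frame(mat))
}

unflatten_features <- function(df, n, T_) {
  feat_cols <- grep("^f[0-9]+$", names(df), value = TRUE)
  mat <- as.matrix(df[order(df$epoch, df$step), feat_cols, drop = FALSE])
  aperm(array(mat, dim = c(T_, n, length(feat_cols))), c(2, 1, 3))
}

#' Write a session to a directory of delimited text tables
#'
#' Stores `features_e.tsv`, `features_o.tsv` (long format with `epoch` and
#' `step` columns, features as `f1..fd`), `labels.tsv` (per-epoch event
#' counts, PERCLOS and, for synthetic sessions, the latent state) and
#' `meta.yaml` (dimensions and the generating seed).
#'
#' @param session A `vigilance_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(flatten_features(session$features_e),
                     file.path(dir, "features_e.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(flatten_features(session$features_o),
                     file.path(dir, "features_o.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  labels <- data.frame(epoch = seq_along(session$perclos),
                       session$events,
                       perclos = session$perclos)
  if (!is.null(session$latent)) labels$latent <- session$latent
  utils::write.table(labels, file.path(dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(n_epochs = dim(session$features_e)[1],
               steps_per_epoch = dim(session$features_e)[2],
               dim_e = dim(session$features_e)[3],
               dim_o = dim(session$features_o)[3],
               seed = if (!is.null(session$config)) session$config$seed)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

check_features <- function(df, what) {
  feat_cols <- grep("^f[0-9]+$", names(df), value = TRUE)
  bad <- which(!is.finite(as.matrix(df[, feat_cols, drop = FALSE])),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite value in ", what, " at row ", bad[1, 1],
         ", feature column ", feat_cols[bad[1, 2]])
  }
}

#' Read a session from a directory written by [write_session()]
#'
#' Validates shapes and rejects non-finite feature values, naming the
#' offending position.
#'
#' @param dir Directory containing the session tables.
#' @return A `vigilance_session`.
#' @export
read_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  fe <- utils::read.delim(file.path(dir, "features_e.tsv"))
  fo <- utils::read.delim(file.path(dir, "features_o.tsv"))
  check_features(fe, "features_e")
  check_features(fo, "features_o")
  labels <- utils::read.delim(file.path(dir, "labels.tsv"))
  n <- meta$n_epochs; T_ <- meta$steps_per_epoch
  if (nrow(fe) != n * T_ || nrow(fo) != n * T_ || nrow(labels) != n) {
    stop("table shapes disagree with meta.yaml")
  }
  structure(list(
    features_e = unflatten_features(fe, n, T_),
    features_o = unflatten_features(fo, n, T_),
    events = labels[, c("blink", "fixation", "saccade", "clos")],
    perclos = labels$perclos,
    latent = labels$latent,
    config = NULL,
    meta = meta
  ), class = "vigilance_session")
}

#' Write predictions as a delimited table
#'
#' Columns: `epoch_id`, `true_perclos`, `predicted_perclos`.
#'
#' @param path Output file path.
#' @param ids Epoch identifiers.
#' @param y,yhat True and predicted PERCLOS.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(path, ids, y, yhat) {
  stopifnot(length(ids) == length(y), length(y) == length(yhat))
  utils::write.table(
    data.frame(epoch_id = ids, true_perclos = y, predicted_perclos = yhat),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a trained model archive
#'
#' The archive contains all named parameter arrays, batch-norm running
#' statistics, the coupling metric, the regression head and the training
#' configuration; a round trip reproduces predictions exactly.
#'
#' @param model A `dcra` model.
#' @param path Archive path (`.rds`).
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dcra")) stop("archive does not contain a dcra model")
  model
}

config_field_spec <- list(
  alpha = function(v) is.numeric(v) && v >= 0 && v <= 1,
  hidden_units = function(v) is.numeric(v) && all(v >= 1),
  code_dim = function(v) is.numeric(v) && v >= 1,
  batch_norm = function(v) is.logical(v),
  lr = function(v) is.numeric(v) && v > 0,
  batch_size = function(v) is.numeric(v) && v >= 1,
  epochs = function(v) is.numeric(v) && v >= 0,
  pretrain_steps = function(v) is.numeric(v) && v >= 0,
  pretrain_lr = function(v) is.numeric(v) && v > 0,
  early_stop = function(v) is.logical(v),
  early_stop_tol = function(v) is.numeric(v) && v > 0,
  early_stop_patience = function(v) is.numeric(v) && v >= 1,
  coupling_form = function(v) v %in% c("mahalanobis", "bilinear"),
  seed = function(v) is.numeric(v)
)

#' Load a training configuration from YAML
#'
#' Missing keys take the [dcra_config()] defaults (an empty file yields the
#' full default architecture); unknown keys and out-of-range values are
#' rejected with a descriptive error.
#'
#' @param path Path to a YAML file (may be empty).
#' @return A [dcra_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(config_field_spec))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(vals)) {
    if (!config_field_spec[[k]](vals[[k]])) {
      stop("config key '", k, "' has invalid value: ",
           paste(format(vals[[k]]), collapse = ", "))
    }
  }
  do.call(dcra_config, vals)
}

#' Save a configuration to YAML
#'
#' @param config A [dcra_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
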