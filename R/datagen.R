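#' Configuration for a synthetic multimodal vigilance session
#'
#' Describes the generative model used by [generate_session()]: a slowly
#' drifting latent vigilance state follows a stationary AR(1) process and is
#' squashed to \[0, 1\] by a logistic map; each modality observes the latent
#' state through a fixed loading vector, plus a modality-specific
#' autoregressive nuisance component at step resolution, plus white Gaussian
#' noise. Eye-event counts (blink, fixation, saccade, closure) are Poisson
#' draws whose log-rates are linear in the latent state, with closure and
#' blink rates increasing and fixation and saccade rates decreasing in
#' drowsiness, so that PERCLOS rises monotonically in expectation with the
#' latent state.
#'
#' @param n_epochs Number of labelled epochs to simulate.
#' @param steps_per_epoch Sequence length `T` of each epoch (time steps fed
#'   to the recurrent encoder). Default 8.
#' @param dim_e,dim_o Feature dimensions of the two modalities. Defaults 36
#'   and 25, the usual widths of EEG band-power and EOG feature vectors in
#'   the vigilance literature.
#' @param latent_ar_coeff AR(1) coefficient of the latent vigilance process,
#'   in (-1, 1). Default 0.95 (slow drift over epochs).
#' @param latent_innovation_sd Innovation standard deviation of the latent
#'   AR(1) process. Default 0.5, giving a stationary sd of about 1.6 and
#'   therefore good coverage of the whole \[0, 1\] PERCLOS range after the
#'   logistic squash.
#' @param shared_loading_scale Standard deviation of the per-feature loadings
#'   that couple each feature to the latent state. Default 1.
#' @param ar_coeff_within AR(1) coefficient of the modality-specific
#'   common-mode drift, applied at step resolution and continuing across
#'   epochs. Default 0.98 (drift on the same slow time scale as vigilance,
#'   the regime in which a single modality cannot distinguish drift from
#'   signal).
#' @param ar_sd_e,ar_sd_o Innovation sd of the common-mode drift of each
#'   modality (0 disables it). Defaults 0.03, i.e. a stationary drift sd of
#'   about 0.15 -- moderate modality-wide artifact drift (arousal or
#'   impedance drift in EEG, electrode drift in EOG), the contamination
#'   that motivates multimodal fusion and puts single-modality estimation
#'   in the error regime reported for this task.
#' @param noise_sd_e,noise_sd_o White observation noise sd per modality.
#'   Defaults 0.3.
#' @param nuisance_rank Number of structured background processes per
#'   modality (each an AR(1) path with its own loading direction,
#'   independent across modalities). Default 6, emulating the several
#'   artifact and background sources a physiological recording carries
#'   besides the vigilance signal.
#' @param event_rate_params Named numeric vector of log-linear Poisson rate
#'   parameters `(blink_base, blink_slope, clos_base, clos_slope, fix_base,
#'   fix_slope, sac_base, sac_slope)`; the rate of each event type within an
#'   epoch is `exp(base + slope * v)` for latent vigilance `v` in \[0, 1\].
#' @param seed Integer seed; the whole session is reproducible from it.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_session()], [perclos()]
#' @export
synthetic_config <- function(n_epochs,
                             steps_per_epoch = 8L,
                             dim_e = 36L,
                             dim_o = 25L,
                             latent_ar_coeff = 0.95,
                             latent_innovation_sd = 0.5,
                             shared_loading_scale = 1,
                             ar_coeff_within = 0.98,
                             ar_sd_e = 0.03,
                             ar_sd_o = 0.03,
                             noise_sd_e = 0.3,
                             noise_sd_o = 0.3,
                             nuisance_rank = 6L,
                             event_rate_params = c(
                               blink_base = 2.1, blink_slope = 1.5,
                               clos_base = 1.6, clos_slope = 2.5,
                               fix_base = 4.1, fix_slope = -2.0,
                               sac_base = 3.6, sac_slope = -2.0
                             ),
                             seed = 1L) {
  stopifnot(
    is.numeric(n_epochs), length(n_epochs) == 1L, n_epochs >= 1,
    is.numeric(steps_per_epoch), steps_per_epoch >= 1,
    dim_e >= 1, dim_o >= 1,
    abs(latent_ar_coeff) < 1,
    latent_innovation_sd >= 0,
    shared_loading_scale > 0,
    abs(ar_coeff_within) < 1,
    ar_sd_e >= 0, ar_sd_o >= 0,
    noise_sd_e >= 0, noise_sd_o >= 0,
    nuisance_rank >= 0,
    is.numeric(event_rate_params)
  )
  needed <- c("blink_base", "blink_slope", "clos_base", "clos_slope",
              "fix_base", "fix_slope", "sac_base", "sac_slope")
  if (!all(needed %in% names(event_rate_params))) {
    stop("event_rate_params must name: ", paste(needed, collapse = ", "))
  }
  structure(list(
    n_epochs = as.integer(n_epochs),
    steps_per_epoch = as.integer(steps_per_epoch),
    dim_e = as.integer(dim_e),
    dim_o = as.integer(dim_o),
    latent_ar_coeff = latent_ar_coeff,
    latent_innovation_sd = latent_innovation_sd,
    shared_loading_scale = shared_loading_scale,
    ar_coeff_within = ar_coeff_within,
    ar_sd_e = ar_sd_e,
    ar_sd_o = ar_sd_o,
    noise_sd_e = noise_sd_e,
    noise_sd_o = noise_sd_o,
    nuisance_rank = as.integer(nuisance_rank),
    event_rate_params = event_rate_params,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' PERCLOS from eye-event counts
#'
#' PERCLOS, the standard oculomotor index of drowsiness, is the fraction of
#' eye events that are closures or blinks:
#' `(blink + clos) / (blink + fixation + saccade + clos)`.
#'
#' @param events A list or data frame with non-negative integer components
#'   `blink`, `fixation`, `saccade` and `clos` (vectorised: each component
#'   may be a vector of per-epoch counts).
#' @return Numeric vector of PERCLOS values in \[0, 1\], one per epoch.
#'   An epoch whose four counts are all zero has no defined PERCLOS and
#'   raises an error.
#' @examples
#' perclos(list(blink = 2, fixation = 5, saccade = 0, clos = 3)) # 0.5
#' @export
perclos <- function(events) {
  needed <- c("blink", "fixation", "saccade", "clos")
  if (!all(needed %in% names(events))) {
    stop("events must have components: ", paste(needed, collapse = ", "))
  }
  b <- events$blink; f <- events$fixation; s <- events$saccade; c_ <- events$clos
  counts <- cbind(b, f, s, c_)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("event counts must be finite and non-negative")
  }
  total <- b + f + s + c_
  if (any(total == 0)) {
    stop("PERCLOS undefined: epoch(s) with zero total event count at index ",
         paste(which(total == 0), collapse = ", "))
  }
  (b + c_) / total
}

#' Discretize PERCLOS into vigilance classes
#'
#' Maps a continuous PERCLOS value to an integer class index by counting how
#' many thresholds lie strictly below it. With the default thresholds
#' (0.35, 0.70) this yields the usual awake / tired / drowsy convention
#' (classes 0, 1, 2). These class labels supply the pairwise constraints for
#' metric learning ([build_pair_sets()]).
#'
#' @param p Numeric vector of PERCLOS values in \[0, 1\].
#' @param thresholds Strictly ascending cut points inside (0, 1).
#' @return Integer vector of class indices in `0:length(thresholds)`.
#' @export
discretize_perclos <- function(p, thresholds = c(0.35, 0.70)) {
  stopifnot(is.numeric(p), is.numeric(thresholds), length(thresholds) >= 1)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]")
  }
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must be strictly ascending within (0, 1)")
  }
  vapply(p, function(pi) sum(thresholds < pi), integer(1))
}

#' Standardize feature columns using training-set statistics
#'
#' Centres and scales the columns of `apply_to` by the column means and
#' standard deviations of `train`, returning the transform parameters so the
#' identical transform can be reused on held-out folds. A zero-variance
#' training column gets scale 1 (with a warning), so constant columns map to
#' zero rather than NaN.
#'
#' @param train Numeric matrix whose columns define the location/scale.
#' @param apply_to Numeric matrix to transform (defaults to `train`).
#' @return A list with `x` (the transformed `apply_to`), `center` and
#'   `scale` (per-column statistics of `train`).
#' @export
standardize <- function(train, apply_to = train) {
  train <- as.matrix(train); apply_to <- as.matrix(apply_to)
  stopifnot(nrow(train) >= 2, ncol(train) == ncol(apply_to))
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  zero <- scale == 0 | !is.finite(scale)
  if (any(zero)) {
    warning("zero-variance column(s) ", paste(which(zero), collapse = ", "),
            ": scale replaced by 1")
    scale[zero] <- 1
  }
  x <- sweep(sweep(apply_to, 2, center, "-"), 2, scale, "/")
  list(x = x, center = center, scale = scale)
}

# Apply a previously fitted standardization to a [n, T, d] feature array.
standardize_array <- function(arr, center, scale) {
  d <- dim(arr)
  flat <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  flat <- sweep(sweep(flat, 2, center, "-"), 2, scale, "/")
  array(flat, dim = d)
}

# Fit column stats on the flattened (epochs x steps) x features view.
fit_standardizer <- function(arr) {
  d <- dim(arr)
  standardize(matrix(arr, nrow = d[1] * d[2], ncol = d[3]))[c("center", "scale")]
}

# Standardize both modalities of a session in place, optionally with
# externally supplied (training-fold) statistics.
standardize_session <- function(session, stats_e = NULL, stats_o = NULL) {
  if (is.null(stats_e)) stats_e <- fit_standardizer(session$features_e)
  if (is.null(stats_o)) stats_o <- fit_standardizer(session$features_o)
  session$features_e <- standardize_array(session$features_e,
                                          stats_e$center, stats_e$scale)
  session$features_o <- standardize_array(session$features_o,
                                          stats_o$center, stats_o$scale)
  session$standardizers <- list(e = stats_e, o = stats_o)
  session
}

# AR(1) path of length n with innovation sd sigma, started from the
# stationary distribution.
ar1_path <- function(n, phi, sigma) {
  x <- numeric(n)
  if (sigma == 0) return(x)
  x[1] <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, sigma)
    for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
  }
  x
}

#' Generate a synthetic labelled multimodal vigilance session
#'
#' Simulates the structure of a simulated-driving vigilance recording: a
#' latent drowsiness state drifting slowly over epochs, two feature streams
#' (e.g. EEG-like and EOG-like) that both load on that state, and eye-event
#' counts from which the PERCLOS label of every epoch is computed with
#' [perclos()]. The ground-truth latent state is returned so that recovery
#' can be measured; real recordings have no such column.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `vigilance_session`: a list with
#'   `features_e` (`n_epochs x T x dim_e` array), `features_o`
#'   (`n_epochs x T x dim_o`), `events` (data frame of per-epoch counts),
#'   `perclos` (numeric vector in \[0, 1\]), `latent` (numeric vector, the
#'   squashed latent state), and the generating `config`.
#' @export
generate_session <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("config must be created by synthetic_config()")
  }
  n <- config$n_epochs
  T_ <- config$steps_per_epoch
  set.seed(config$seed)

  lat_raw <- ar1_path(n, config$latent_ar_coeff, config$latent_innovation_sd)
  v <- stats::plogis(lat_raw)

  gen_modality <- function(dim_m, ar_sd, noise_sd) {
    loading <- stats::rnorm(dim_m, 0, config$shared_loading_scale)
    shared <- outer(v, loading)                     # n x dim
    # two kinds of modality-wide artifact drift, both scalar AR processes
    # independent across modalities:
    #  - confusable drift u along the SAME loading vector as the vigilance
    #    signal: the modality observes loading * (v + u), so drift and
    #    signal are indistinguishable within one modality -- this is what
    #    makes fusing the two streams informative;
    #  - a structured background subspace W (rank nuisance_rank): several
    #    independent slow processes with their own loading directions,
    #    emulating artifact / background sources unrelated to vigilance;
    #    separable in principle, but reconstruction spends code capacity on
    #    them, and because they are uncoupled across modalities the
    #    coupling loss drives the encoders to discard them
    u <- ar1_path(n * T_, config$ar_coeff_within, ar_sd)
    q <- config$nuisance_rank
    W <- vapply(seq_len(q),
                function(j) ar1_path(n * T_, config$ar_coeff_within, ar_sd),
                numeric(n * T_))
    W_loading <- matrix(stats::rnorm(dim_m * q), dim_m, q)
    noise <- matrix(stats::rnorm(n * T_ * dim_m, 0, noise_sd), n * T_, dim_m)
    arr <- array(0, dim = c(n, T_, dim_m))
    for (t in seq_len(T_)) {
      rows <- (seq_len(n) - 1L) * T_ + t
      arr[, t, ] <- shared + outer(u[rows], loading) +
        W[rows, , drop = FALSE] %*% t(W_loading) + noise[rows, , drop = FALSE]
    }
    arr
  }
  features_e <- gen_modality(config$dim_e, config$ar_sd_e, config$noise_sd_e)
  features_o <- gen_modality(config$dim_o, config$ar_sd_o, config$noise_sd_o)

  p <- config$event_rate_params
  draw_events <- function() data.frame(
    blink    = stats::rpois(n, exp(p[["blink_base"]] + p[["blink_slope"]] * v)),
    fixation = stats::rpois(n, exp(p[["fix_base"]] + p[["fix_slope"]] * v)),
    saccade  = stats::rpois(n, exp(p[["sac_base"]] + p[["sac_slope"]] * v)),
    clos     = stats::rpois(n, exp(p[["clos_base"]] + p[["clos_slope"]] * v))
  )
  events <- draw_events()
  # an epoch with no events at all has no PERCLOS; redraw such epochs
  for (i in 1:100) {
    total <- rowSums(events)
    if (all(total > 0)) break
    redraw <- draw_events()
    events[total == 0, ] <- redraw[total == 0, ]
  }
  if (any(rowSums(events) == 0)) {
    events$fixation[rowSums(events) == 0] <- 1L
  }

  structure(list(
    features_e = features_e,
    features_o = features_o,
    events = events,
    perclos = perclos(events),
    latent = v,
    config = config
  ), class = "vigilance_session")
}

#' @export
print.vigilance_session <- function(x, ...) {
  cat("<vigilance_session> ", length(x$perclos), " epochs, T = ",
      dim(x$features_e)[2], ", dims ", dim(x$features_e)[3], "/",
      dim(x$features_o)[3], "\n", sep = "")
  cat("  PERCLOS: ", sprintf("%.3f", min(x$perclos)), "-",
      sprintf("%.3f", max(x$perclos)), " (mean ",
      sprintf("%.3f", mean(x$perclos)), ")\n", sep = "")
  invisible(x)
}
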