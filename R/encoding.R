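#' Angular tuning curve of an information channel
#'
#' Each information channel is a half-wave rectified sinusoidal filter over
#' angular position, `f = |cos^alpha(0.5 * (theta - mu) * pi / 180)|`, with
#' the angular difference wrapped to (-180, 180]. `f` equals 1 at the
#' preferred angle, 0 at the opposite angle, and `0.5^alpha` at 120 degrees
#' separation.
#'
#' @param theta Stimulus angle(s) in degrees (0 = vertical up, counter-
#'   clockwise positive).
#' @param mu Preferred angle of the channel in degrees.
#' @param alpha Power exponent (positive integer; the model uses 5).
#' @return Tuning response(s) in \[0, 1\].
#' @export
#' @examples
#' tuning_curve(0, 0)          # 1
#' tuning_curve(120, 0)        # 0.5^5 = 0.03125
tuning_curve <- function(theta, mu, alpha = 5) {
  stopifnot(alpha >= 1)
  d <- wrap_angle(theta - mu)
  abs(cos(0.5 * d * pi / 180))^alpha
}

#' Tuning basis for the three angular position channels
#'
#' @param centers Preferred angles in degrees; defaults to the three stimulus
#'   positions top/left/right = 0, 120, 240.
#' @param alpha Power exponent of the tuning curves.
#' @return A list of class `tuning_basis` with `centers` and `alpha`.
#' @export
tuning_basis <- function(centers = c(0, 120, 240), alpha = 5) {
  stopifnot(length(centers) >= 2, alpha >= 1)
  structure(list(centers = centers, alpha = alpha), class = "tuning_basis")
}

#' Design matrix of predicted channel responses
#'
#' Evaluates every channel's tuning curve at the presented stimulus angles:
#' entry (k, n) is the predicted (normalized, 0-1) response of channel k to
#' observation n.
#'
#' @param angles Stimulus angle per training observation, degrees.
#' @param basis A [tuning_basis()].
#' @return Matrix `[channels x observations]` with rownames from the basis
#'   centers.
#' @export
build_design_matrix <- function(angles, basis = tuning_basis()) {
  if (length(angles) == 0L) stop("no training observations")
  C <- vapply(angles,
              function(a) tuning_curve(a, basis$centers, basis$alpha),
              numeric(length(basis$centers)))
  C <- matrix(C, nrow = length(basis$centers))
  rownames(C) <- paste0("ch", basis$centers)
  C
}

#' Per-channel weight estimation (forward model fit)
#'
#' Solves the encoding model `MEG = W C + N` on training data, by default one
#' channel at a time as the marginal least-squares estimator
#' `w_k = MEG c_k' (c_k c_k')^{-1}`, retaining the per-channel residuals
#' `eps_k = MEG - w_k c_k` for noise normalization. A joint multichannel
#' solution `W = MEG C' (C C')^{-1}` is available behind `joint = TRUE` for
#' comparison (the two agree when the design rows are orthogonal).
#'
#' @param meg Matrix `[sensors x observations]` of training data (per-trial
#'   sensor vectors averaged over the training window).
#' @param design Matrix `[channels x observations]` from
#'   [build_design_matrix()].
#' @param joint Use the joint pseudoinverse instead of the per-channel
#'   estimator.
#' @return A list with `W` `[sensors x channels]` and `residuals`, a list of
#'   per-channel residual matrices `[sensors x observations]`.
#' @export
fit_weights <- function(meg, design, joint = FALSE) {
  stopifnot(is.matrix(meg), is.matrix(design), ncol(meg) == ncol(design))
  if (ncol(meg) < nrow(design))
    stop("need at least as many training observations as channels; ",
         "provide more (or more varied) observations")
  n_ch <- nrow(design)
  if (joint) {
    gram <- design %*% t(design)
    if (rcond(gram) < 1e-12)
      stop("singular design autocovariance; provide more varied observations")
    W <- meg %*% t(design) %*% solve(gram)
  } else {
    W <- matrix(0, nrow(meg), n_ch)
    for (k in seq_len(n_ch)) {
      ck <- design[k, ]
      ss <- sum(ck^2)
      if (ss < 1e-12)
        stop("channel ", k, " has a degenerate (all-zero) tuning column; ",
             "provide more varied observations")
      W[, k] <- meg %*% ck / ss
    }
  }
  residuals <- lapply(seq_len(n_ch), function(k)
    meg - W[, k, drop = FALSE] %*% design[k, , drop = FALSE])
  rownames(W) <- rownames(meg)
  colnames(W) <- rownames(design)
  list(W = W, residuals = residuals)
}

#' Shrinkage covariance estimate
#'
#' Sample covariance shrunk toward its diagonal with the analytic optimal
#' (expected-squared-loss-minimizing) shrinkage intensity: the off-diagonal
#' entries are scaled by `1 - gamma` where
#' `gamma = sum var(s_ij) / sum s_ij^2` over `i != j`, clamped to \[0, 1\].
#'
#' @param X Matrix `[observations x variables]`.
#' @return A list with `sigma` (shrunk covariance), `gamma` (intensity) and
#'   `sample` (unshrunk sample covariance).
#' @export
shrink_covariance <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  v <- diag(S)
  if (any(v <= 0))
    stop("zero-variance variable(s): degenerate covariance")
  # var of each covariance entry: n/(n-1)^3 * sum_t (w_tij - mean_t w_ij)^2
  # with w_tij = xc_ti * xc_tj; computed via crossprod(Xc^2).
  W2 <- crossprod(Xc^2)                # sum_t w_tij^2
  Wbar <- crossprod(Xc) / n            # mean_t w_tij
  varS <- n / (n - 1)^3 * (W2 - n * Wbar^2)
  off <- upper.tri(S)
  denom <- sum(S[off]^2)
  gamma <- if (denom <= 0) 1 else min(1, max(0, sum(varS[off]) / denom))
  sigma <- (1 - gamma) * S
  diag(sigma) <- v
  list(sigma = sigma, gamma = gamma, sample = S)
}

#' Multivariate noise normalization of the channel weights
#'
#' Transforms each channel's weight vector into the pre-whitened inverse
#' `g_k = E_k^{-1} w_k (w_k' E_k^{-1} w_k)^{-1}`, where `E_k` is the channel's
#' residual noise covariance regularized by [shrink_covariance()]. By
#' construction `g_k' w_k = 1` for every channel.
#'
#' @param W Matrix `[sensors x channels]` from [fit_weights()].
#' @param residuals Per-channel residual matrices `[sensors x observations]`
#'   from [fit_weights()], or `NULL` with `noise_cov` supplied.
#' @param noise_cov Optional fixed noise covariance (e.g. `diag(n_sensors)`)
#'   used for every channel instead of the residual estimate.
#' @return A list with `G` `[sensors x channels]`, `gamma` (per-channel
#'   shrinkage intensity) and `E` (per-channel regularized covariances).
#' @export
prewhiten_weights <- function(W, residuals = NULL, noise_cov = NULL) {
  stopifnot(is.matrix(W), nrow(W) >= 2L)
  n_ch <- ncol(W)
  G <- matrix(0, nrow(W), n_ch, dimnames = dimnames(W))
  gam <- numeric(n_ch)
  Es <- vector("list", n_ch)
  for (k in seq_len(n_ch)) {
    if (is.null(noise_cov)) {
      if (is.null(residuals))
        stop("either residuals or noise_cov must be supplied")
      sh <- shrink_covariance(t(residuals[[k]]))
      Ek <- sh$sigma
      gam[k] <- sh$gamma
    } else {
      Ek <- noise_cov
      gam[k] <- NA_real_
    }
    ev <- eigen(Ek, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("regularized noise covariance of channel ", k,
           " is not positive definite")
    Ew <- solve(Ek, W[, k])
    denom <- sum(W[, k] * Ew)
    if (abs(denom) < 1e-15)
      stop("degenerate weights for channel ", k)
    G[, k] <- Ew / denom
    Es[[k]] <- Ek
  }
  list(G = G, gamma = gam, E = Es)
}

#' Train the full inverted encoding model on localizer epochs
#'
#' Averages each localizer trial's sensor data over the training window,
#' builds the design matrix from the presented angles, fits the per-channel
#' weights and pre-whitens them. Flicker trials and any trial listed in
#' `exclude_trials` (e.g. trials with (micro)saccades in the first 0.2 s, see
#' [saccade_contaminated_trials()]) are dropped before training.
#'
#' @param localizer An [epoch_set()] whose `meta` has a `position` column
#'   (and optionally `flicker`).
#' @param training_window Two seconds `(from, to)` within the epoch over
#'   which the sensor signal is averaged.
#' @param basis A [tuning_basis()].
#' @param exclude_trials Integer trial indices to drop before training.
#' @param joint Passed to [fit_weights()].
#' @return A list of class `encoding_model` with `W`, `G`, `gamma`, `basis`,
#'   `training_window` and `n_train`.
#' @export
train_encoding_model <- function(localizer, training_window = c(0.14, 0.17),
                                 basis = tuning_basis(),
                                 exclude_trials = integer(0), joint = FALSE) {
  keep <- seq_len(dim(localizer$data)[1])
  if (!is.null(localizer$meta$flicker))
    keep <- setdiff(keep, which(localizer$meta$flicker))
  keep <- setdiff(keep, exclude_trials)
  if (length(keep) < length(basis$centers))
    stop("too few usable localizer trials after exclusions")
  meg <- window_average(localizer, training_window)[, keep, drop = FALSE]
  design <- build_design_matrix(localizer$meta$position[keep], basis)
  fit <- fit_weights(meg, design, joint = joint)
  pw <- prewhiten_weights(fit$W, fit$residuals)
  structure(list(W = fit$W, G = pw$G, gamma = pw$gamma, basis = basis,
                 training_window = training_window, n_train = length(keep)),
            class = "encoding_model")
}

# Sensor vectors averaged over a time window: [sensors x trials].
window_average <- function(epochs, window) {
  tt <- epoch_times(epochs)
  idx <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  if (length(idx) == 0L) stop("training window outside the epoch")
  m <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  t(m)
}

#' Invert the encoding model on decision epochs
#'
#' Computes the estimated channel responses `C = G' MEG` at every sample, with
#' no temporal smoothing.
#'
#' @param model An `encoding_model` (or any list with `G`).
#' @param epochs An [epoch_set()] with the same sensor count and ordering as
#'   the training data.
#' @return A list of class `channel_response` with `response`
#'   `[trials x channels x time]`, `centers`, `fs`, `t0`.
#' @export
invert_model <- function(model, epochs) {
  G <- model$G
  d <- dim(epochs$data)
  if (d[2] != nrow(G)) {
    stop(sprintf("sensor mismatch: model trained on %d sensors, epochs have %d",
                 nrow(G), d[2]))
  }
  if (!is.null(rownames(G)) && !is.null(dimnames(epochs$data)[[2]]) &&
      !identical(rownames(G), dimnames(epochs$data)[[2]])) {
    bad <- which(rownames(G) != dimnames(epochs$data)[[2]])
    stop("sensor ordering mismatch at: ",
         paste(utils::head(rownames(G)[bad], 5), collapse = ", "))
  }
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])
  resp <- crossprod(G, flat)                      # channels x (trials*time)
  resp <- aperm(array(resp, c(ncol(G), d[1], d[3])), c(2, 1, 3))
  structure(list(response = resp,
                 centers = model$basis$centers %||% c(0, 120, 240),
                 fs = epochs$fs, t0 = epochs$t0),
            class = "channel_response")
}

#' Cross-validated selection of the training epoch
#'
#' For each candidate training window, trains the encoding model on all
#' blocks but one and decodes the held-out block's trials (sensor vectors
#' averaged over the same window). The decoding score of a trial is the
#' response of the true-position channel minus the mean response of the other
#' channels; the window maximizing the mean held-out score is selected, ties
#' broken toward the earlier window.
#'
#' @param localizer An [epoch_set()] whose `meta` has `position` and `block`
#'   columns.
#' @param candidate_windows List of `(from, to)` second pairs.
#' @param basis A [tuning_basis()].
#' @param exclude_trials Trials dropped before training (held-out scoring
#'   also skips them).
#' @return A list with `training_window` (the selected pair), `scores` (mean
#'   held-out score per window) and `windows`.
#' @export
select_training_epoch <- function(localizer, candidate_windows,
                                  basis = tuning_basis(),
                                  exclude_trials = integer(0)) {
  blocks <- localizer$meta$block
  if (is.null(blocks)) stop("localizer meta must contain a block column")
  ub <- unique(blocks)
  if (length(ub) < 2L) stop("cross-validation needs at least 2 blocks")
  usable <- setdiff(seq_len(dim(localizer$data)[1]), exclude_trials)
  if (!is.null(localizer$meta$flicker))
    usable <- setdiff(usable, which(localizer$meta$flicker))

  scores <- vapply(candidate_windows, function(win) {
    obs <- window_average(localizer, win)         # sensors x trials
    fold_scores <- vapply(ub, function(b) {
      train <- usable[blocks[usable] != b]
      test <- usable[blocks[usable] == b]
      if (length(test) == 0L) return(NA_real_)
      design <- build_design_matrix(localizer$meta$position[train], basis)
      fit <- fit_weights(obs[, train, drop = FALSE], design)
      pw <- prewhiten_weights(fit$W, fit$residuals)
      resp <- crossprod(pw$G, obs[, test, drop = FALSE])  # channels x tests
      true_ch <- match(localizer$meta$position[test], basis$centers)
      sc <- vapply(seq_along(test), function(i)
        resp[true_ch[i], i] - mean(resp[-true_ch[i], i]), numeric(1))
      mean(sc)
    }, numeric(1))
    mean(fold_scores, na.rm = TRUE)
  }, numeric(1))

  starts <- vapply(candidate_windows, `[`, numeric(1), 1L)
  best <- order(-scores, starts)[1L]
  list(training_window = candidate_windows[[best]],
       scores = scores, windows = candidate_windows)
}

#' Localizer trials contaminated by early (micro)saccades
#'
#' Returns the indices of trials that contain a detected saccade onset within
#' `window` (default the first 0.2 s after stimulus onset); these are excluded
#' from encoding-model training.
#'
#' @param saccades A `saccade_table` (see [detect_microsaccades()]) or any
#'   `data.frame(trial, onset)`.
#' @param window Two seconds `(from, to)` on the epoch time axis.
#' @return Sorted unique trial indices.
#' @export
saccade_contaminated_trials <- function(saccades, window = c(0, 0.2)) {
  hit <- saccades$onset >= window[1] - 1e-9 & saccades$onset <= window[2] + 1e-9
  sort(unique(saccades$trial[hit]))
}
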