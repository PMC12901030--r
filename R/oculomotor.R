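#' Detect (micro)saccades by a multiple-of-median velocity criterion
#'
#' Gaze velocity is the per-sample Euclidean norm of the first difference of
#' the (x, y) position times the sampling rate (a per-axis-maximum norm is
#' available behind `norm = "max"`), smoothed with a Gaussian kernel. A
#' saccade is recorded whenever the smoothed velocity exceeds `k` times the
#' trial's median smoothed velocity; excursions delimit candidate events, the
#' recorded onset is the first sample within the excursion whose raw velocity
#' exceeds the threshold (falling back to the smoothed-velocity peak), and
#' onsets within `refractory` seconds of the previous one are discarded. The
#' displacement of each saccade is the gaze change from 0.01 s before to
#' 0.03 s after onset; displacements under 1 degree are classed as
#' microsaccades.
#'
#' @param gaze A [gaze_record()].
#' @param kernel_sd Gaussian smoothing sd, seconds.
#' @param k Velocity threshold as a multiple of the trial median.
#' @param refractory Minimum onset spacing, seconds.
#' @param norm `"euclidean"` or `"max"` velocity norm.
#' @return A `data.frame` of class `saccade_table` with `trial`, `onset`
#'   (seconds), `displacement` (degrees) and `is_micro`.
#' @export
detect_microsaccades <- function(gaze, kernel_sd = 0.02, k = 6,
                                 refractory = 0.025,
                                 norm = c("euclidean", "max")) {
  norm <- match.arg(norm)
  fs <- gaze$fs
  if (fs < 100) stop("gaze must be sampled at 100 Hz or more")
  tt <- epoch_times(gaze)
  n_time <- ncol(gaze$x)
  out <- vector("list", nrow(gaze$x))
  for (i in seq_len(nrow(gaze$x))) {
    xi <- gaze$x[i, ]; yi <- gaze$y[i, ]
    if (all(is.na(xi)) || all(is.na(yi))) {
      warning("trial ", i, " has no usable gaze samples; skipped")
      next
    }
    dx <- diff(xi) * fs; dy <- diff(yi) * fs
    v_raw <- c(0, if (norm == "euclidean") sqrt(dx^2 + dy^2)
                  else pmax(abs(dx), abs(dy)))
    v <- smooth_gaussian(v_raw, kernel_sd * fs)
    thr <- k * stats::median(v, na.rm = TRUE)
    above <- !is.na(v) & v > thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    exc <- which(r$values)
    onsets <- integer(0)
    for (e in exc) {
      span <- starts[e]:ends[e]
      hit <- span[which(v_raw[span] > thr)]
      onsets <- c(onsets, if (length(hit)) hit[1]
                          else span[which.max(v[span])])
    }
    keep_t <- numeric(0)
    last <- -Inf
    for (o in sort(onsets)) {
      if (tt[o] - last < refractory - 1e-9) next
      keep_t <- c(keep_t, tt[o]); last <- tt[o]
    }
    if (!length(keep_t)) next
    o_idx <- round((keep_t - gaze$t0) * fs) + 1L
    pre <- pmax(1L, o_idx - round(0.01 * fs))
    post <- pmin(n_time, o_idx + round(0.03 * fs))
    disp <- sqrt((xi[post] - xi[pre])^2 + (yi[post] - yi[pre])^2)
    out[[i]] <- data.frame(trial = i, onset = keep_t, displacement = disp)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(trial = integer(0), onset = numeric(0),
                      displacement = numeric(0))
  out$is_micro <- out$displacement < 1
  rownames(out) <- NULL
  class(out) <- c("saccade_table", "data.frame")
  out
}

#' Saccade rate over trials
#'
#' The probability of a saccade onset across trials at each sample, times the
#' sampling rate (Hz).
#'
#' @param saccades A `saccade_table`.
#' @param n_trials Number of trials.
#' @param n_time Number of samples per trial.
#' @param fs Sampling rate, Hz.
#' @param t0 Epoch start, seconds.
#' @param smooth Optional boxcar width in seconds for display smoothing.
#' @return Numeric vector of rates (Hz) per sample.
#' @export
saccade_rate <- function(saccades, n_trials, n_time, fs, t0 = 0,
                         smooth = NULL) {
  idx <- round((saccades$onset - t0) * fs) + 1L
  idx <- idx[idx >= 1L & idx <= n_time]
  rate <- tabulate(idx, nbins = n_time) / n_trials * fs
  if (!is.null(smooth)) rate <- smooth_boxcar(rate, round(smooth * fs))
  rate
}

#' Coupling between attentional events and (micro)saccades
#'
#' Three linked analyses of the oculomotor-attention relationship:
#' the attentional-event-triggered saccade rate in `window` around event
#' onsets, separately per label, minus a trial-shuffle null (event trial
#' identities are reassigned per timepoint, as in [trial_shuffle_null()]);
#' the proportion of events preceded by at least one saccade in `pre_window`;
#' and, when a strength trace is supplied, the saccade-triggered attention
#' strength z-scored on the 0.4 s preceding each saccade.
#'
#' @param events A labelled [event_table()].
#' @param saccades A `saccade_table`.
#' @param n_trials,n_time,fs,t0 Geometry of the session.
#' @param window Lag window around event onsets, seconds.
#' @param pre_window Window (relative to event onset) in which a preceding
#'   saccade is counted.
#' @param trace Optional `attention_trace` for the saccade-triggered strength.
#' @param strength_window Lag window for the saccade-triggered strength.
#' @param n_shuffles Shuffles for the null rate.
#' @param labels Event labels analyzed.
#' @param seed Integer seed (fixed seed gives identical nulls).
#' @return A list with `lags`, `rate` (observed triggered rate per label),
#'   `rate_change` (observed minus null mean), `null_mean`, `preceded`
#'   (proportion per label), and optionally `strength_lags` /
#'   `strength` (z-scored saccade-triggered strength).
#' @export
event_saccade_coupling <- function(events, saccades, n_trials, n_time, fs,
                                   t0 = 0, window = c(-0.3, 0.3),
                                   pre_window = c(-0.3, 0),
                                   trace = NULL,
                                   strength_window = c(-0.4, 0.8),
                                   n_shuffles = 200,
                                   labels = c("stay", "switch"), seed = 1) {
  if (!nrow(events) || !nrow(saccades))
    stop("both event and saccade tables must be nonempty")
  set.seed(seed)
  pre <- round(-window[1] * fs); post <- round(window[2] * fs)
  lags <- seq(-pre, post) / fs
  # binary saccade trains per trial
  strain <- matrix(FALSE, n_trials, n_time)
  si <- round((saccades$onset - t0) * fs) + 1L
  ok <- si >= 1L & si <= n_time
  strain[cbind(saccades$trial[ok], si[ok])] <- TRUE

  ev <- events[events$label %in% labels, ]
  es <- round((ev$onset - t0) * fs) + 1L
  full <- es - pre >= 1L & es + post <= n_time
  ev <- ev[full, ]; es <- es[full]

  triggered <- function(trials, samples) {
    acc <- matrix(0, length(labels), length(lags),
                  dimnames = list(labels, NULL))
    n <- stats::setNames(integer(length(labels)), labels)
    for (L in labels) {
      rows <- which(ev$label == L)
      n[L] <- length(rows)
      for (r in rows)
        acc[L, ] <- acc[L, ] +
          strain[trials[r], (samples[r] - pre):(samples[r] + post)]
      if (n[L] > 0) acc[L, ] <- acc[L, ] / n[L] * fs
    }
    list(rate = acc, n = n)
  }
  obs <- triggered(ev$trial, es)

  groups <- split(seq_along(es), es)
  null_acc <- matrix(0, length(labels), length(lags),
                     dimnames = list(labels, NULL))
  for (r in seq_len(n_shuffles)) {
    new_trial <- integer(length(es))
    for (g in groups) new_trial[g] <- sample.int(n_trials, length(g))
    null_acc <- null_acc + triggered(new_trial, es)$rate
  }
  null_mean <- null_acc / n_shuffles

  pre_lo <- round(pre_window[1] * fs); pre_hi <- round(pre_window[2] * fs)
  preceded <- vapply(labels, function(L) {
    rows <- which(ev$label == L)
    if (!length(rows)) return(NA_real_)
    hit <- vapply(rows, function(r) {
      a <- max(1L, es[r] + pre_lo); b <- min(n_time, es[r] + pre_hi)
      any(strain[ev$trial[r], a:b])
    }, logical(1))
    mean(hit)
  }, numeric(1))

  out <- list(lags = lags, rate = obs$rate,
              rate_change = obs$rate - null_mean, null_mean = null_mean,
              preceded = preceded, n_events = obs$n)

  if (!is.null(trace)) {
    spre <- round(-strength_window[1] * fs)
    spost <- round(strength_window[2] * fs)
    slags <- seq(-spre, spost) / fs
    base_idx <- which(slags >= -0.4 - 1e-9 & slags < 0)
    ssam <- si[ok]
    stri <- saccades$trial[ok]
    fullS <- ssam - spre >= 1L & ssam + spost <= n_time
    accS <- numeric(length(slags)); nS <- 0L
    for (r in which(fullS)) {
      x <- trace$length[stri[r], (ssam[r] - spre):(ssam[r] + spost)]
      m <- mean(x[base_idx]); s <- stats::sd(x[base_idx])
      if (!is.finite(s) || s < 1e-15) next
      accS <- accS + (x - m) / s
      nS <- nS + 1L
    }
    out$strength_lags <- slags
    out$strength <- if (nS > 0) accS / nS else rep(NA_real_, length(slags))
    out$n_saccades <- nS
  }
  out
}

#' IEI histograms split by intervening saccades
#'
#' Recomputes the inter-event-interval histograms separately for intervals
#' that do or do not contain a (micro)saccade onset strictly between the two
#' event onsets.
#'
#' @param events A labelled [event_table()].
#' @param saccades A `saccade_table`.
#' @param fs Sampling rate, Hz.
#' @param range Displayed interval range, seconds.
#' @param which Interval class passed to the split (as in [iei_histogram()]).
#' @return A list with `with_saccade` and `without_saccade` `iei_histogram`s.
#' @export
saccade_split_iei <- function(events, saccades, fs, range = c(0.025, 0.5),
                              which = "all") {
  if (nrow(events) < 2L) stop("no within-trial intervals")
  ev <- events[order(events$trial, events$onset), ]
  s <- round(ev$onset * fs)
  same <- which(diff(ev$trial) == 0L)
  # recompute start onsets aligned with select_interval_class filtering
  starts <- data.frame(trial = ev$trial[same], s0 = s[same],
                       s1 = s[same + 1L],
                       label_prev = ev$label[same],
                       label_cur = ev$label[same + 1L])
  starts <- select_interval_class(
    data.frame(trial = starts$trial, d = starts$s1 - starts$s0,
               label_prev = starts$label_prev, label_cur = starts$label_cur,
               s0 = starts$s0, s1 = starts$s1), which)
  ss <- round(saccades$onset * fs)
  has <- vapply(seq_len(nrow(starts)), function(r) {
    any(saccades$trial == starts$trial[r] & ss > starts$s0[r] &
          ss < starts$s1[r])
  }, logical(1))
  list(with_saccade = interval_histogram(starts$d[has], fs, range),
       without_saccade = interval_histogram(starts$d[!has], fs, range))
}

#' Normalize pupil traces and compute their derivative
#'
#' Linearly maps pupil size so the 5th percentile (over all samples) becomes 0
#' and the 95th becomes 1 (values outside may exceed \[0, 1\]); the derivative
#' is the adjacent-sample difference.
#'
#' @param pupil Matrix `[trials x time]` (or vector) of pupil size.
#' @param probs Anchor percentiles.
#' @return A list with `normalized`, `derivative` (first column/element `NA`)
#'   and `anchors`.
#' @export
normalize_pupil <- function(pupil, probs = c(0.05, 0.95)) {
  p <- if (is.matrix(pupil)) pupil else matrix(pupil, nrow = 1)
  if (any(!is.finite(p))) stop("pupil samples must be finite")
  q <- stats::quantile(p, probs, names = FALSE)
  if (diff(q) < 1e-15) stop("degenerate pupil percentiles (constant trace)")
  norm <- (p - q[1]) / (q[2] - q[1])
  deriv <- cbind(NA_real_, t(apply(norm, 1, diff)))
  if (!is.matrix(pupil)) {
    norm <- drop(norm); deriv <- drop(deriv)
  }
  list(normalized = norm, derivative = deriv, anchors = q)
}
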