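#' Detect attentional events by dual thresholding
#'
#' An attentional event marks a sample at which the attention locus is
#' selective for one alternative and attention strength is high: the maximum
#' angular similarity must exceed its participant-level percentile threshold
#' (computed over all stimulus-on samples of all trials) and the vector
#' length its within-trial percentile threshold. The event onset is the first
#' sample at which both binarized series are true after at least one was
#' false (rising edge of the conjunction), or at which the nearest target
#' changes while both remain true. Onsets within `refractory` seconds of the
#' previous onset are excluded. Exact similarity ties are broken toward the
#' previously attended locus.
#'
#' @param trace An `attention_trace` from [attentional_vector()].
#' @param mas_pct Percentile (0-100) for the MAS threshold, over the entire
#'   dataset's stimulus-on samples.
#' @param len_pct Percentile (0-100) for the vector-length threshold, within
#'   each trial's stimulus-on samples.
#' @param refractory Minimum spacing between onsets, seconds.
#' @param stim_window Two seconds `(from, to)`; detection and thresholds are
#'   restricted to this interval (defaults to the whole trace).
#' @return An [event_table()] with stay/switch labels filled in.
#' @export
detect_events <- function(trace, mas_pct = 90, len_pct = 90,
                          refractory = 0.025, stim_window = NULL) {
  stopifnot(mas_pct > 0, mas_pct < 100, len_pct > 0, len_pct < 100)
  tt <- epoch_times(trace)
  if (is.null(stim_window)) stim_window <- range(tt)
  on_idx <- which(tt >= stim_window[1] - 1e-9 & tt <= stim_window[2] + 1e-9)
  if (length(on_idx) == 0L || nrow(trace$length) == 0L)
    return(event_table(integer(0), numeric(0), numeric(0)))

  mas <- trace$mas[, on_idx, drop = FALSE]
  len <- trace$length[, on_idx, drop = FALSE]
  ang <- trace$angle[, on_idx, drop = FALSE]
  t_on <- tt[on_idx]
  mas_thr <- stats::quantile(mas, mas_pct / 100, na.rm = TRUE, names = FALSE)

  out <- vector("list", nrow(len))
  for (i in seq_len(nrow(len))) {
    len_thr <- stats::quantile(len[i, ], len_pct / 100, na.rm = TRUE,
                               names = FALSE)
    conj <- !is.na(mas[i, ]) & mas[i, ] >= mas_thr & len[i, ] >= len_thr
    n <- length(conj)
    prev <- c(FALSE, conj[-n])
    rising <- conj & !prev
    loc <- nearest_target(ang[i, ], trace$centers)
    changed <- c(FALSE, !is.na(loc[-1]) & !is.na(loc[-n]) & loc[-1] != loc[-n])
    cand <- which(rising | (conj & prev & changed))
    if (!length(cand)) next
    kept_on <- numeric(0); kept_loc <- numeric(0)
    last_t <- -Inf; last_loc <- NA_real_
    sims <- vapply(trace$centers, function(mu) cos(deg2rad(ang[i, ] - mu)),
                   numeric(n))
    for (j in cand) {
      if (t_on[j] - last_t < refractory - 1e-9) next
      s <- sims[j, ]
      best <- which.max(s)
      if (!is.na(last_loc)) {
        pk <- match(last_loc, trace$centers)
        if (abs(s[pk] - s[best]) < 1e-12) best <- pk
      }
      kept_on <- c(kept_on, t_on[j])
      kept_loc <- c(kept_loc, trace$centers[best])
      last_t <- t_on[j]; last_loc <- trace$centers[best]
    }
    if (length(kept_on))
      out[[i]] <- data.frame(trial = i, onset = kept_on, locus = kept_loc)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(event_table(integer(0), numeric(0), numeric(0)))
  label_stay_switch(event_table(out$trial, out$onset, out$locus,
                                source = "detected",
                                min_spacing = refractory))
}

#' Label events as stay or switch
#'
#' The first event of each trial is labelled `"first"` (excluded from
#' stay/switch statistics); every later event is `"stay"` when its locus
#' equals the previous event's locus in the same trial, otherwise `"switch"`.
#' Cross-trial pairs are never labelled.
#'
#' @param events An [event_table()].
#' @return The table with the `label` column filled.
#' @export
label_stay_switch <- function(events) {
  if (nrow(events) == 0L) return(events)
  ord <- order(events$trial, events$onset)
  ev <- events[ord, ]
  same_trial <- c(FALSE, diff(ev$trial) == 0L)
  prev_locus <- c(NA_real_, ev$locus[-nrow(ev)])
  ev$label <- ifelse(!same_trial, "first",
                     ifelse(ev$locus == prev_locus, "stay", "switch"))
  rownames(ev) <- NULL
  ev
}

# Within-trial intervals with the labels of both flanking events.
# Returns data.frame(trial, d [samples], label_prev, label_cur).
event_intervals <- function(events, fs) {
  if (nrow(events) < 2L) return(NULL)
  ev <- events[order(events$trial, events$onset), ]
  s <- round(ev$onset * fs)
  n <- nrow(ev)
  same <- diff(ev$trial) == 0L
  if (!any(same)) return(NULL)
  i <- which(same)
  data.frame(trial = ev$trial[i], d = (s[i + 1L] - s[i]),
             label_prev = ev$label[i], label_cur = ev$label[i + 1L],
             stringsAsFactors = FALSE)
}

# Histogram of interval sample-counts over the displayed range; the
# probability denominator includes intervals outside the range.
interval_histogram <- function(d_samples, fs, range = c(0.025, 0.5)) {
  d_min <- round(range[1] * fs)
  d_max <- round(range[2] * fs)
  bins <- d_min:d_max
  counts <- tabulate(d_samples[d_samples >= d_min & d_samples <= d_max] -
                       d_min + 1L, nbins = length(bins))
  n_total <- length(d_samples)
  structure(list(bin_centers = bins / fs, counts = counts,
                 prob = if (n_total > 0) counts / n_total else counts * 0,
                 n_intervals = n_total, fs = fs, range = range),
            class = "iei_histogram")
}

#' Inter-event-interval histogram
#'
#' Times from each event onset to the next onset within the same trial, at
#' per-sample resolution over the displayed range (default 0.025-0.5 s).
#' Interval probabilities are normalized by the total interval count,
#' including intervals falling outside the displayed range; intervals
#' reaching over trials are excluded.
#'
#' @param events An [event_table()].
#' @param fs Sampling rate used to discretize intervals, Hz.
#' @param range Displayed interval range, seconds.
#' @param which Interval class: `"all"`, `"stay"` / `"switch"` (label of the
#'   interval-terminating event), or a second-order class such as
#'   `"stay_after_switch"` (current label after previous label).
#' @return An object of class `iei_histogram` with `bin_centers`, `counts`,
#'   `prob`, `n_intervals`.
#' @export
iei_histogram <- function(events, fs, range = c(0.025, 0.5), which = "all") {
  iv <- event_intervals(events, fs)
  if (is.null(iv)) stop("no within-trial intervals")
  interval_histogram(select_interval_class(iv, which)$d, fs, range)
}

select_interval_class <- function(iv, which) {
  if (which == "all") return(iv)
  if (which %in% c("stay", "switch")) return(iv[iv$label_cur == which, ])
  m <- regmatches(which, regexec("^(stay|switch)_after_(stay|switch)$", which))[[1]]
  if (length(m) != 3L) stop("unknown interval class: ", which)
  iv[iv$label_cur == m[2] & iv$label_prev == m[3], ]
}

second_order_classes <- c("stay_after_stay", "stay_after_switch",
                          "switch_after_stay", "switch_after_switch")

#' Second-order inter-event-interval histograms
#'
#' Splits intervals by the (previous label, current label) sequence type:
#' stay after stay, stay after switch, switch after stay, switch after
#' switch. If event timing passively follows a free-running oscillation,
#' repetition histograms are offset by half a cycle from alternations; if
#' each event resets the rhythm, the four histograms collapse onto the
#' first-order ones.
#'
#' @inheritParams iei_histogram
#' @return Named list of four `iei_histogram`s.
#' @export
second_order_iei <- function(events, fs, range = c(0.025, 0.5)) {
  stats::setNames(lapply(second_order_classes, function(cl)
    iei_histogram(events, fs, range, which = cl)), second_order_classes)
}

#' Trial-shuffle null distribution of IEI histograms
#'
#' Randomizes, independently at every timepoint, which trials hold the events
#' observed at that timepoint (resampling trial identities without
#' replacement), destroying within-trial temporal structure while exactly
#' preserving the per-timepoint event counts and thus the task-locked event
#' rate. After each of `n_shuffles` randomizations the events are relabelled
#' (stay/switch follow from the locus sequence in the new trial) and the IEI
#' histograms recomputed; per-bin null means and standard deviations are
#' returned for each requested interval class.
#'
#' @param events An [event_table()].
#' @param n_trials Total number of trials events can be assigned to.
#' @param fs Sampling rate, Hz.
#' @param n_shuffles Number of randomizations.
#' @param range Displayed interval range, seconds.
#' @param which Character vector of interval classes (see [iei_histogram()]).
#' @param seed Integer seed; fixed seed gives bit-identical nulls.
#' @return If one class is requested, a list with `null_mean`, `null_sd`,
#'   `bin_centers`, `n_shuffles`; otherwise a named list of such lists.
#' @export
trial_shuffle_null <- function(events, n_trials = max(events$trial),
                               fs, n_shuffles = 1000,
                               range = c(0.025, 0.5), which = "all",
                               seed = 1) {
  if (n_trials < 2L)
    stop("trial shuffling needs at least 2 trials")
  set.seed(seed)
  ev <- events[order(events$trial, events$onset), ]
  s <- round(ev$onset * fs)
  groups <- split(seq_along(s), s)
  d_min <- round(range[1] * fs); d_max <- round(range[2] * fs)
  n_bins <- d_max - d_min + 1L
  acc <- lapply(which, function(cl)
    list(sum = numeric(n_bins), sumsq = numeric(n_bins)))
  names(acc) <- which
  n_ev <- nrow(ev)
  relabel_needed <- any(which != "all")

  for (r in seq_len(n_shuffles)) {
    new_trial <- integer(n_ev)
    for (g in groups)
      new_trial[g] <- sample.int(n_trials, length(g))
    ord <- order(new_trial, s)
    tr <- new_trial[ord]; ss <- s[ord]
    same <- c(FALSE, diff(tr) == 0L)
    lab <- NULL
    if (relabel_needed) {
      loc <- ev$locus[ord]
      lab <- ifelse(!same, "first",
                    ifelse(loc == c(NA_real_, loc[-n_ev]), "stay", "switch"))
    }
    i <- which(same) - 1L
    d <- ss[i + 1L] - ss[i]
    for (cl in which) {
      dk <- if (cl == "all") {
        d
      } else if (cl %in% c("stay", "switch")) {
        d[lab[i + 1L] == cl]
      } else {
        m <- strsplit(cl, "_after_")[[1]]
        d[lab[i + 1L] == m[1] & lab[i] == m[2]]
      }
      nt <- length(dk)
      cnt <- tabulate(dk[dk >= d_min & dk <= d_max] - d_min + 1L,
                      nbins = n_bins)
      pr <- if (nt > 0) cnt / nt else cnt * 0
      acc[[cl]]$sum <- acc[[cl]]$sum + pr
      acc[[cl]]$sumsq <- acc[[cl]]$sumsq + pr^2
    }
  }
  res <- lapply(acc, function(a) {
    mu <- a$sum / n_shuffles
    v <- pmax(0, a$sumsq / n_shuffles - mu^2) * n_shuffles / (n_shuffles - 1)
    list(null_mean = mu, null_sd = sqrt(v),
         bin_centers = (d_min:d_max) / fs, n_shuffles = n_shuffles)
  })
  if (length(which) == 1L) res[[1]] else res
}

#' One trial-shuffle randomization of an event table
#'
#' Reassigns, independently at every timepoint, which trials hold the events
#' observed at that timepoint (sampling trial identities without
#' replacement). Per-timepoint event counts are preserved exactly; loci
#' travel with their events and labels are recomputed.
#'
#' @param events An [event_table()].
#' @param n_trials Total number of trials.
#' @param fs Sampling rate used to define the timepoints, Hz.
#' @param seed Optional integer seed.
#' @return A relabelled `data.frame` with the same onsets redistributed over
#'   trials (within-trial spacing below the refractory period may occur, as
#'   in the null model).
#' @export
shuffle_event_trials <- function(events, n_trials = max(events$trial), fs,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- events[order(events$trial, events$onset), ]
  s <- round(ev$onset * fs)
  for (g in split(seq_along(s), s))
    ev$trial[g] <- sample.int(n_trials, length(g))
  ev <- ev[order(ev$trial, ev$onset), ]
  rownames(ev) <- NULL
  label_stay_switch(ev)
}

#' Rhythmic modes of an IEI histogram
#'
#' Subtracts the expected (trial-shuffle null) histogram from the observed
#' one, zeroes all bins that do not significantly exceed the null (one-sided
#' z test against the shuffle distribution at `alpha`), smooths the truncated
#' difference twice with a boxcar kernel (edges padded to the first/last
#' value), and extracts its local maxima. The attention rhythm's cycle length
#' is the latency from the first to the second mode.
#'
#' @param hist An `iei_histogram`.
#' @param null A matching null from [trial_shuffle_null()].
#' @param alpha One-sided significance level for truncation.
#' @param smooth Boxcar kernel width, seconds.
#' @return A list with `modes` (`data.frame(latency, prominence)`),
#'   `cycle_length` (seconds, `NA` with fewer than two modes), the truncated
#'   smoothed `corrected` histogram, per-bin `z` and `p`, and
#'   `n_significant_bins`.
#' @export
detect_histogram_modes <- function(hist, null, alpha = 0.01, smooth = 0.01) {
  stopifnot(length(hist$prob) == length(null$null_mean))
  diff <- hist$prob - null$null_mean
  sd0 <- pmax(null$null_sd, 1e-12)
  z <- diff / sd0
  p <- stats::pnorm(z, lower.tail = FALSE)
  trunc <- diff
  trunc[!(p < alpha)] <- 0
  n_box <- max(1L, round(smooth * hist$fs))
  sm <- smooth_boxcar(smooth_boxcar(trunc, n_box), n_box)
  mx <- local_maxima(sm)
  mx <- mx[sm[mx] > 0]
  modes <- data.frame(latency = hist$bin_centers[mx], prominence = sm[mx])
  list(modes = modes,
       cycle_length = if (nrow(modes) >= 2L)
         modes$latency[2] - modes$latency[1] else NA_real_,
       corrected = sm, z = z, p = p,
       n_significant_bins = sum(p < alpha))
}

#' Threshold sweep of modulation intensity
#'
#' Re-runs event detection over a grid of MAS and vector-length percentile
#' thresholds (default 50-95 percent in 5-point steps plus 97.5 and 99: a 12 x 12
#' grid) and quantifies, per cell, the departure of the IEI histogram from an
#' exponential decay: interval probabilities are log-transformed, linearly
#' detrended, smoothed twice with a 0.025 s (10-sample at 400 Hz) boxcar, and
#' the modulation intensity is the standard deviation of the detrended values
#' between the first and second local maxima of the smoothed curve (`NA` with
#' fewer than two maxima or too few events).
#'
#' @param trace An `attention_trace`.
#' @param mas_pcts,len_pcts Percentile grids.
#' @param stim_window Passed to [detect_events()].
#' @param range IEI display range, seconds.
#' @return A list with `intensity` (matrix `[len_pcts x mas_pcts]`),
#'   `first_mode` (matrix of first-maximum latencies) and the grids.
#' @export
threshold_sweep <- function(trace,
                            mas_pcts = c(seq(50, 95, 5), 97.5, 99),
                            len_pcts = c(seq(50, 95, 5), 97.5, 99),
                            stim_window = NULL, range = c(0.025, 0.5)) {
  intensity <- matrix(NA_real_, length(len_pcts), length(mas_pcts),
                      dimnames = list(len_pcts, mas_pcts))
  first_mode <- intensity
  for (a in seq_along(len_pcts)) {
    for (b in seq_along(mas_pcts)) {
      ev <- detect_events(trace, mas_pct = mas_pcts[b], len_pct = len_pcts[a],
                          stim_window = stim_window)
      iv <- event_intervals(ev, trace$fs)
      if (is.null(iv) || nrow(iv) < 10L) next
      h <- interval_histogram(iv$d, trace$fs, range)
      lp <- log(h$prob)
      lp[!is.finite(lp)] <- NA_real_
      if (sum(is.finite(lp)) < 5L) next
      det <- detrend_linear(lp)
      filled <- fill_na_linear(det)
      n_box <- max(1L, round(0.025 * trace$fs))
      sm <- smooth_boxcar(smooth_boxcar(
        ifelse(is.finite(filled), filled, 0), n_box), n_box)
      mx <- local_maxima(sm)
      if (length(mx) >= 1L) first_mode[a, b] <- h$bin_centers[mx[1]]
      if (length(mx) >= 2L) {
        seg <- det[mx[1]:mx[2]]
        intensity[a, b] <- stats::sd(seg[is.finite(seg)])
      }
    }
  }
  list(intensity = intensity, first_mode = first_mode,
       mas_pcts = mas_pcts, len_pcts = len_pcts,
       n_cells = length(intensity))
}

#' Per-trial event counts by decision value class
#'
#' Counts stay and switch events at the high-, mid- and low-value alternative
#' of each trial (the mapping from angular position to value class comes from
#' the trial's contrast triplet and framing, stored in the session meta).
#'
#' @param events A labelled [event_table()].
#' @param meta Per-trial `data.frame` with `value_pos1..3` columns giving the
#'   value class (`"H"`, `"M"`, `"L"`) of positions 0, 120, 240 degrees.
#' @param centers Angular positions corresponding to the value columns.
#' @return A `data.frame` with one row per meta row and columns `stay_H`,
#'   `stay_M`, `stay_L`, `switch_H`, `switch_M`, `switch_L`.
#' @export
event_value_counts <- function(events, meta, centers = c(0, 120, 240)) {
  n <- nrow(meta)
  out <- matrix(0L, n, 6,
                dimnames = list(NULL, c("stay_H", "stay_M", "stay_L",
                                        "switch_H", "switch_M", "switch_L")))
  vo <- as.matrix(meta[, paste0("value_pos", 1:3)])
  ev <- events[events$label %in% c("stay", "switch"), ]
  if (nrow(ev)) {
    pos_idx <- match(ev$locus, centers)
    val <- vo[cbind(ev$trial, pos_idx)]
    col <- paste0(ev$label, "_", val)
    tab <- table(factor(ev$trial, levels = seq_len(n)),
                 factor(col, levels = colnames(out)))
    out <- out + matrix(as.integer(tab), nrow = n)
  }
  as.data.frame(out)
}

#' Logistic regression of choice on event counts
#'
#' Fits, per choice outcome (H, M, L individually), a binomial logistic
#' regression of "this alternative chosen" on the six per-trial event counts
#' (stay/switch at each value class). Constant predictors are dropped with a
#' warning; under complete separation the fit falls back to a ridge-penalized
#' logistic regression (glmnet, small lambda) and is flagged.
#'
#' @param counts `data.frame` of per-trial predictors (see
#'   [event_value_counts()]).
#' @param choice Character vector of per-trial choices (`"H"`, `"M"`, `"L"`).
#' @param outcomes Outcomes to fit.
#' @return Named list per outcome with `coef`, `se` (NA when penalized),
#'   `penalized` flag and `dropped` predictor names.
#' @export
choice_regression <- function(counts, choice, outcomes = c("H", "M", "L")) {
  stopifnot(nrow(counts) == length(choice))
  if (nrow(counts) < 30L) stop("need at least 30 trials")
  X <- as.matrix(counts)
  if (any(!is.finite(X))) stop("predictors must be finite")
  keep <- apply(X, 2, function(x) stats::sd(x) > 0)
  if (!all(keep))
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  X <- X[, keep, drop = FALSE]
  lapply(stats::setNames(outcomes, outcomes), function(o) {
    y <- as.integer(choice == o)
    fit <- NULL
    separated <- FALSE
    withCallingHandlers(
      fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                            family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!separated && fit$converged) {
      sm <- summary(stats::glm(y ~ X, family = stats::binomial()))
      co <- sm$coefficients
      cf <- co[, 1]; se <- co[, 2]
      names(cf) <- names(se) <- sub("^X", "", rownames(co))
      list(coef = cf, se = se, penalized = FALSE,
           dropped = colnames(counts)[!keep])
    } else {
      gf <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                           lambda = 0.01)
      cf <- as.numeric(stats::coef(gf))
      names(cf) <- rownames(stats::coef(gf))
      list(coef = cf, se = rep(NA_real_, length(cf)), penalized = TRUE,
           dropped = colnames(counts)[!keep])
    }
  })
}
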