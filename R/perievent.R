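#' Event-triggered average of attention strength
#'
#' Extracts the strength trace in a window around every attentional event
#' (events without a full window inside their trial are dropped), z-scores
#' each event's trace on the pooled pre- and post-event samples while
#' excluding the peri-event zone (default +/- 0.03 s, where the event itself
#' would skew the distribution), and averages per label.
#'
#' @param trace An `attention_trace`.
#' @param events A labelled [event_table()].
#' @param window Two seconds `(before, after)` around the event onset.
#' @param exclusion Half-width of the peri-event zone excluded from the
#'   normalization statistics, seconds.
#' @param labels Event labels averaged separately.
#' @return A list of class `perievent_average` with `lags` (seconds), `avg`
#'   (matrix `[labels x lags]` of mean z-scored strength), `raw` (same, not
#'   z-scored), `n_events` per label, `fs`.
#' @export
event_triggered_average <- function(trace, events, window = c(-0.2, 0.2),
                                    exclusion = 0.03,
                                    labels = c("stay", "switch")) {
  fs <- trace$fs
  tt <- epoch_times(trace)
  pre <- round(-window[1] * fs); post <- round(window[2] * fs)
  lags <- seq(-pre, post) / fs
  norm_ok <- abs(lags) > exclusion + 1e-9
  n_time <- ncol(trace$length)

  samp <- round((events$onset - trace$t0) * fs) + 1L
  full <- samp - pre >= 1L & samp + post <= n_time
  ev <- events[full, ]
  samp <- samp[full]
  if (!nrow(ev)) stop("no events with complete peri-event windows")

  avg <- matrix(NA_real_, length(labels), length(lags),
                dimnames = list(labels, NULL))
  raw <- avg
  n_events <- stats::setNames(integer(length(labels)), labels)
  for (L in labels) {
    rows <- which(ev$label == L)
    n_events[L] <- length(rows)
    if (!length(rows)) next
    acc_z <- numeric(length(lags)); acc_r <- numeric(length(lags))
    for (r in rows) {
      x <- trace$length[ev$trial[r], (samp[r] - pre):(samp[r] + post)]
      m <- mean(x[norm_ok]); s <- stats::sd(x[norm_ok])
      if (!is.finite(s) || s < 1e-15)
        stop("zero variance in the peri-event normalization samples")
      acc_z <- acc_z + (x - m) / s
      acc_r <- acc_r + x
    }
    avg[L, ] <- acc_z / length(rows)
    raw[L, ] <- acc_r / length(rows)
  }
  structure(list(lags = lags, avg = avg, raw = raw, n_events = n_events,
                 fs = fs, window = window, exclusion = exclusion),
            class = "perievent_average")
}

#' Dominant peri-event fluctuation frequency
#'
#' Linearly detrends and boxcar-smooths the event-triggered average
#' separately within the pre-event and post-event intervals, finds strict
#' local maxima, and estimates the dominant frequency as the inverse of the
#' latency between the two peaks closest to the event in each interval
#' (missing when an interval holds fewer than two peaks).
#'
#' @param pea A `perievent_average`.
#' @param pre_interval,post_interval Second pairs relative to the event.
#' @param smooth Boxcar kernel width, seconds.
#' @return A `data.frame` with one row per label and columns `f_pre`,
#'   `f_post` (Hz, `NA` when undefined).
#' @export
perievent_frequency <- function(pea, pre_interval = c(-0.2, -0.05),
                                post_interval = c(0.05, 0.2),
                                smooth = 0.025) {
  n_box <- max(1L, round(smooth * pea$fs))
  est <- function(avg_row, interval) {
    idx <- which(pea$lags >= interval[1] - 1e-9 & pea$lags <= interval[2] + 1e-9)
    if (length(idx) < 4L) return(NA_real_)
    seg <- smooth_boxcar(detrend_linear(avg_row[idx]), n_box)
    mx <- local_maxima(seg)
    if (length(mx) < 2L) return(NA_real_)
    lat <- pea$lags[idx][mx]
    # the two peaks closest to the event (lag 0)
    two <- lat[order(abs(lat))][1:2]
    1 / abs(diff(sort(two)))
  }
  out <- data.frame(label = rownames(pea$avg),
                    f_pre = NA_real_, f_post = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    out$f_pre[i] <- est(pea$avg[i, ], pre_interval)
    out$f_post[i] <- est(pea$avg[i, ], post_interval)
  }
  out
}

#' Switch/stay strength ratio before and after events
#'
#' Ratio of the mean attention strength around switch events to that around
#' stay events, computed in a pre-event (-0.15 to -0.05 s) and a post-event
#' (0.05 to 0.15 s) window of the raw event-triggered averages; the ratio
#' change is post minus pre.
#'
#' @param trace An `attention_trace`.
#' @param events A labelled [event_table()].
#' @param pre,post Second pairs relative to the event onset.
#' @return A list with `ratio_pre`, `ratio_post`, `delta`.
#' @export
pre_post_ratio <- function(trace, events, pre = c(-0.15, -0.05),
                           post = c(0.05, 0.15)) {
  labs <- c("stay", "switch")
  if (!all(labs %in% events$label))
    stop("both stay and switch events are required")
  win <- c(min(pre[1], -0.2), max(post[2], 0.2))
  pea <- event_triggered_average(trace, events, window = win, labels = labs)
  mean_in <- function(L, interval) {
    idx <- pea$lags >= interval[1] - 1e-9 & pea$lags <= interval[2] + 1e-9
    mean(pea$raw[L, idx])
  }
  rp <- mean_in("switch", pre) / mean_in("stay", pre)
  ro <- mean_in("switch", post) / mean_in("stay", post)
  list(ratio_pre = rp, ratio_post = ro, delta = ro - rp)
}
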