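#' Epoched multichannel recordings
#'
#' Container for epoched sensor data: a `trials x sensors x time` array with a
#' shared time axis and per-trial metadata, the canonical input of the
#' encoding stage.
#'
#' @param data Numeric array `[trials x sensors x time]`.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds relative to the alignment
#'   event (e.g. stimulus onset).
#' @param meta `data.frame` with one row per trial (position, contrast
#'   triplet, framing, choice, correctness, block id, ... as applicable).
#'
#' @return An object of class `epoch_set` with elements `data`, `fs`, `t0`,
#'   `meta`.
#' @export
epoch_set <- function(data, fs, t0 = 0, meta = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0)
  if (is.null(meta)) meta <- data.frame(trial = seq_len(dim(data)[1]))
  if (nrow(meta) != dim(data)[1])
    stop("meta must have one row per trial (", dim(data)[1], " trials, ",
         nrow(meta), " meta rows)")
  structure(list(data = data, fs = fs, t0 = t0, meta = meta),
            class = "epoch_set")
}

#' Time axis of an epoched container
#'
#' @param x An `epoch_set`, `attention_trace` or any list with `fs`, `t0` and
#'   a time dimension.
#' @param n_time Number of samples; taken from `x` when omitted.
#' @return Numeric vector of sample times in seconds.
#' @export
epoch_times <- function(x, n_time = NULL) {
  if (is.null(n_time)) {
    n_time <- if (inherits(x, "epoch_set")) dim(x$data)[3]
              else if (!is.null(x$length)) ncol(x$length)
              else if (!is.null(x$amp)) dim(x$amp)[3]
              else if (!is.null(x$x)) ncol(x$x)
              else stop("cannot infer the number of time samples")
  }
  x$t0 + (seq_len(n_time) - 1L) / x$fs
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d sensors x %d samples @ %g Hz (t0 = %g s)\n",
              d[1], d[2], d[3], x$fs, x$t0))
  invisible(x)
}

#' Attentional-event table
#'
#' Normalizes and validates a table of attentional events. Within each trial
#' onsets must be strictly increasing with spacing of at least the detector's
#' refractory period (0.025 s).
#'
#' @param trial Integer trial index per event.
#' @param onset Onset time in seconds (epoch time axis).
#' @param locus Attended angular position in degrees (0, 120 or 240).
#' @param label Event label: `"first"`, `"stay"` or `"switch"` (optional;
#'   filled by [label_stay_switch()]).
#' @param source `"detected"` or `"ground_truth"`.
#' @param min_spacing Minimum within-trial onset spacing in seconds.
#' @return A `data.frame` of class `event_table`, ordered by trial and onset.
#' @export
event_table <- function(trial, onset, locus,
                        label = NA_character_, source = "detected",
                        min_spacing = 0.025) {
  n <- length(trial)
  ev <- data.frame(trial = as.integer(trial), onset = as.numeric(onset),
                   locus = rep(as.numeric(locus), length.out = n),
                   label = rep(label, length.out = n),
                   source = rep(source, length.out = n),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$trial, ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) > 1L) {
    d <- diff(ev$onset)
    same <- diff(ev$trial) == 0L
    if (any(same & d < min_spacing - 1e-9))
      stop("event onsets within a trial must be spaced by at least ",
           min_spacing, " s")
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Gaze and pupil traces
#'
#' @param x,y Matrices `[trials x time]` of gaze position in degrees of
#'   visual angle.
#' @param pupil Matrix `[trials x time]` of pupil size (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @param planted Optional `data.frame(trial, onset)` of ground-truth saccade
#'   times for synthetic data.
#' @return An object of class `gaze_record`.
#' @export
gaze_record <- function(x, y, pupil = NULL, fs, t0 = 0, planted = NULL) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)), fs > 0)
  if (any(abs(x) > 5, na.rm = TRUE) || any(abs(y) > 5, na.rm = TRUE))
    warning("gaze samples beyond +/-5 degrees visual angle")
  if (!is.null(planted) && nrow(planted) > 1L) {
    sp <- unlist(tapply(planted$onset, planted$trial,
                        function(o) diff(sort(o))), use.names = FALSE)
    if (length(sp) && any(sp < 0.025 - 1e-9))
      stop("planted saccade times must be spaced by at least 0.025 s per trial")
  }
  structure(list(x = x, y = y, pupil = pupil, fs = fs, t0 = t0,
                 planted = planted),
            class = "gaze_record")
}
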