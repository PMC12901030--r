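#' Quarter-octave filterbank specification
#'
#' Center frequencies at quarter-octave steps (default 2^1.5 to 2^6.5, i.e.
#' 2.83-90.5 Hz), each with a passband of the center times 2^(+/-0.5) (half an
#' octave either side), a 4th-order Butterworth filter applied zero-phase
#' (forward-backward), and an edge trim of two cycles of the center frequency
#' per trial edge.
#'
#' @param exponents Powers of two of the center frequencies.
#' @param order Butterworth order (per direction).
#' @param trim_cycles Cycles of the center frequency trimmed per edge.
#' @return A list of class `filterbank_spec` with `centers`, `low`, `high`,
#'   `order`, `trim_cycles`.
#' @export
filterbank_spec <- function(exponents = seq(1.5, 6.5, by = 0.25),
                            order = 4, trim_cycles = 2) {
  centers <- 2^exponents
  if (is.unsorted(centers, strictly = TRUE))
    stop("center frequencies must be strictly increasing")
  structure(list(centers = centers,
                 low = centers * 2^-0.5, high = centers * 2^0.5,
                 order = order, trim_cycles = trim_cycles),
            class = "filterbank_spec")
}

#' Band-limited amplitude envelope of attention strength
#'
#' For each filterbank center: band-pass the per-trial strength series with a
#' zero-phase Butterworth filter, take the magnitude of the analytic signal
#' (Hilbert envelope), and mark two cycles of the center frequency at each
#' trial edge as missing (edge artifacts). Centers whose passband reaches the
#' Nyquist frequency are dropped with a warning.
#'
#' @param trace An `attention_trace` (its `length` matrix is analyzed) or a
#'   plain `[trials x time]` matrix with `fs`/`t0` supplied.
#' @param spec A [filterbank_spec()].
#' @param fs,t0 Sampling rate and epoch start (taken from `trace` when it is
#'   an `attention_trace`).
#' @return A list of class `amplitude_tfr` with `amp`
#'   `[trials x frequencies x time]` (non-negative, `NA` in trimmed edges),
#'   `centers`, `fs`, `t0`.
#' @export
bandlimited_amplitude <- function(trace, spec = filterbank_spec(),
                                  fs = NULL, t0 = NULL) {
  if (inherits(trace, "attention_trace")) {
    x <- trace$length; fs <- trace$fs; t0 <- trace$t0
  } else {
    x <- as.matrix(trace)
    if (is.null(fs)) stop("fs required for matrix input")
    t0 <- t0 %||% 0
  }
  nyq <- fs / 2
  ok <- spec$high < nyq
  if (!all(ok)) {
    warning(sum(!ok), " center(s) with passband at or above Nyquist dropped")
    spec$centers <- spec$centers[ok]
    spec$low <- spec$low[ok]; spec$high <- spec$high[ok]
  }
  n_time <- ncol(x)
  if (n_time < 4 * fs / min(spec$centers))
    stop("trials shorter than 4 cycles of the lowest center frequency")
  amp <- array(NA_real_, c(nrow(x), length(spec$centers), n_time))
  for (f in seq_along(spec$centers)) {
    bf <- signal::butter(spec$order, c(spec$low[f], spec$high[f]) / nyq,
                         type = "pass")
    trim <- round(spec$trim_cycles * fs / spec$centers[f])
    keep <- if (2 * trim >= n_time) integer(0)
            else (trim + 1L):(n_time - trim)
    if (!length(keep)) next
    for (i in seq_len(nrow(x))) {
      filt <- signal::filtfilt(bf, x[i, ])
      env <- Mod(analytic_signal(filt))
      amp[i, f, keep] <- env[keep]
    }
  }
  structure(list(amp = amp, centers = spec$centers, fs = fs, t0 = t0),
            class = "amplitude_tfr")
}

#' Baseline normalization of an amplitude TFR in dB
#'
#' Divides each frequency's amplitude by the trial-averaged amplitude in the
#' baseline window and converts the ratio to decibels with the amplitude
#' convention `20 * log10(ratio)`.
#'
#' @param tfr An `amplitude_tfr`.
#' @param baseline_window Two seconds `(from, to)` on the epoch time axis.
#' @param db_factor 20 for amplitude ratios (default); 10 for power.
#' @return The TFR with an added `baseline_db` array and `baseline` vector
#'   (per-frequency baseline amplitude).
#' @export
baseline_normalize_db <- function(tfr, baseline_window, db_factor = 20) {
  tt <- epoch_times(tfr, dim(tfr$amp)[3])
  idx <- which(tt >= baseline_window[1] - 1e-9 & tt <= baseline_window[2] + 1e-9)
  if (!length(idx)) stop("baseline window outside the epoch")
  base <- apply(tfr$amp[, , idx, drop = FALSE], 2, mean, na.rm = TRUE)
  if (any(!is.finite(base)))
    stop("baseline window fully trimmed at some frequencies")
  if (any(base <= 0)) stop("zero baseline amplitude")
  tfr$baseline_db <- db_factor *
    log10(sweep(tfr$amp, 2, base, "/"))
  tfr$baseline <- base
  tfr
}

#' Morlet wavelet time-frequency transform
#'
#' Convolves each trial with complex Morlet wavelets of bandwidth half an
#' octave (`f / sigma_f = 5.83`), with the kernel truncated at one temporal
#' standard deviation (`+/- sigma_t`), and returns the magnitude. Samples
#' within half a kernel of the trial edges are missing.
#'
#' @param x Matrix `[trials x time]` (one sensor or derived series) or an
#'   `attention_trace`.
#' @param centers Center frequencies, Hz (default 2 to 90.5 Hz in
#'   quarter-octave steps).
#' @param fs Sampling rate, Hz.
#' @param fwhm_ratio Frequency-to-sigma_f ratio (5.83 = half-octave bandwidth).
#' @return An `amplitude_tfr` with `amp` `[trials x frequencies x time]`.
#' @export
wavelet_tfr <- function(x, centers = 2^seq(1, 6.5, by = 0.25), fs = NULL,
                        fwhm_ratio = 5.83) {
  if (inherits(x, "attention_trace")) {
    fs <- x$fs; t0 <- x$t0; x <- x$length
  } else {
    if (is.null(fs)) stop("fs required for matrix input")
    t0 <- 0
  }
  x <- as.matrix(x)
  n_time <- ncol(x)
  sigma_f <- centers / fwhm_ratio
  sigma_t <- 1 / (2 * pi * sigma_f)
  if (n_time <= 2 * max(ceiling(sigma_t * fs)) + 1)
    stop("epochs shorter than one kernel; need more than ",
         2 * max(ceiling(sigma_t * fs)) + 1, " samples")
  amp <- array(NA_real_, c(nrow(x), length(centers), n_time))
  for (f in seq_along(centers)) {
    half <- max(1L, ceiling(sigma_t[f] * fs))
    tk <- seq(-half, half) / fs
    env <- exp(-tk^2 / (2 * sigma_t[f]^2))
    kern <- exp(2i * pi * centers[f] * tk) * env / sum(env)
    keep <- if (n_time <= 2 * half) integer(0) else (half + 1L):(n_time - half)
    for (i in seq_len(nrow(x))) {
      cv <- conv_complex(x[i, ], kern)
      amp[i, f, keep] <- Mod(cv[keep])
    }
  }
  structure(list(amp = amp, centers = centers, fs = fs, t0 = t0),
            class = "amplitude_tfr")
}

# Centered complex convolution of a real series with a complex kernel.
conv_complex <- function(x, kern) {
  half <- (length(kern) - 1L) %/% 2L
  re <- stats::filter(x, Re(kern), sides = 2)
  im <- stats::filter(x, Im(kern), sides = 2)
  complex(real = as.numeric(re), imaginary = as.numeric(im))
}

#' Condition-matched comparison of correct vs error trials
#'
#' Compares TFR amplitude between correct and error trials while matching
#' trial difficulty: within each stratum (contrast triplet x framing), correct
#' trials are randomly subsampled to the stratum's error-trial count; the
#' subsampling is repeated `n_subsamples` times and amplitudes averaged over
#' repetitions before the comparison. Strata whose error trials outnumber
#' their correct trials (or with no error trials) are dropped with a warning.
#'
#' @param tfr An `amplitude_tfr`.
#' @param meta Per-trial `data.frame` with logical `correct`, plus the
#'   stratification columns.
#' @param strata Column names defining the strata.
#' @param n_subsamples Number of random subsamples of correct trials.
#' @param seed Integer seed.
#' @return A list with `percent_change` (`(correct - error) / correct * 100`,
#'   `[frequencies x time]`), `correct_mean`, `error_mean`, `strata_counts`
#'   and `dropped_strata`.
#' @export
stratified_condition_compare <- function(tfr, meta,
                                         strata = c("triplet", "framing"),
                                         n_subsamples = 100, seed = 1) {
  stopifnot(nrow(meta) == dim(tfr$amp)[1])
  set.seed(seed)
  key <- interaction(meta[strata], drop = TRUE)
  correct <- as.logical(meta$correct)
  counts <- table(key, factor(correct, levels = c(FALSE, TRUE)))
  n_err <- counts[, 1]; n_cor <- counts[, 2]
  usable <- n_err > 0 & n_cor >= n_err
  dropped <- rownames(counts)[!usable]
  if (length(dropped))
    warning("dropping ", length(dropped),
            " stratum/strata without matchable trials")
  keep_strata <- rownames(counts)[usable]
  err_idx <- which(!correct & key %in% keep_strata)
  if (!length(err_idx)) stop("no error trials in matchable strata")

  dims <- dim(tfr$amp)[2:3]
  cor_acc <- matrix(0, dims[1], dims[2])
  for (r in seq_len(n_subsamples)) {
    pick <- unlist(lapply(keep_strata, function(st) {
      pool <- which(correct & key == st)
      pool[sample.int(length(pool), n_err[st])]
    }), use.names = FALSE)
    cor_acc <- cor_acc + apply(tfr$amp[pick, , , drop = FALSE], c(2, 3),
                               mean, na.rm = TRUE)
  }
  cor_mean <- cor_acc / n_subsamples
  err_mean <- apply(tfr$amp[err_idx, , , drop = FALSE], c(2, 3),
                    mean, na.rm = TRUE)
  list(percent_change = (cor_mean - err_mean) / cor_mean * 100,
       correct_mean = cor_mean, error_mean = err_mean,
       strata_counts = counts, dropped_strata = dropped,
       centers = tfr$centers, fs = tfr$fs, t0 = tfr$t0)
}
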