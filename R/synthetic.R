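#' Synthetic forward model from angular channels to sensors
#'
#' Generates the generative counterpart of the encoding model: a sensor gain
#' pattern per angular channel plus a sensor noise covariance. Patterns are
#' random Gaussian vectors orthonormalized across channels (full column rank
#' by construction).
#'
#' @param n_sensors Number of sensors (at least 3).
#' @param seed Integer seed; the model is reproducible given the seed.
#' @param noise_structure `"identity"` or `"random_spd"` (a random symmetric
#'   positive-definite covariance scaled to unit mean variance).
#' @param n_channels Number of angular channels.
#' @return A list of class `forward_model` with `patterns`
#'   `[sensors x channels]` and `noise_cov` `[sensors x sensors]`.
#' @export
make_forward_model <- function(n_sensors, seed = 1,
                               noise_structure = c("identity", "random_spd"),
                               n_channels = 3) {
  if (n_sensors < 3) stop("need at least 3 sensors")
  noise_structure <- match.arg(noise_structure)
  set.seed(seed)
  patterns <- qr.Q(qr(matrix(stats::rnorm(n_sensors * n_channels),
                             n_sensors, n_channels)))
  rownames(patterns) <- paste0("S", seq_len(n_sensors))
  noise_cov <- if (noise_structure == "identity") {
    diag(n_sensors)
  } else {
    A <- matrix(stats::rnorm(n_sensors * n_sensors), n_sensors)
    S <- A %*% t(A) / n_sensors + 0.1 * diag(n_sensors)
    S / mean(diag(S))
  }
  dimnames(noise_cov) <- list(rownames(patterns), rownames(patterns))
  structure(list(patterns = patterns, noise_cov = noise_cov),
            class = "forward_model")
}

# Correlated sensor noise: [n_sensors x n_samples] with covariance sd^2 * cov.
draw_noise <- function(chol_cov, n_samples, sd) {
  if (sd == 0 || !is.finite(sd)) return(matrix(0, nrow(chol_cov), n_samples))
  sd * t(chol_cov) %*% matrix(stats::rnorm(nrow(chol_cov) * n_samples),
                              nrow(chol_cov), n_samples)
}

#' Simulate retinotopic localizer epochs
#'
#' Each trial presents a single stimulus at one of the three angular
#' positions; the channel drive is the tuning-curve response to that position,
#' injected as a boxcar over `response_window` (emulating the stimulus-evoked
#' response whose decodability peaks there), so that each trial's mean sensor
#' vector over the response window equals `patterns %*% c(position)` plus
#' noise. Noise is zero-mean Gaussian with the model's covariance and
#' standard deviation `1/snr`; `snr = Inf` gives the noiseless limit.
#'
#' @param fm A [make_forward_model()].
#' @param n_blocks Number of localizer blocks.
#' @param reps Repetitions per position x orientation combination per block.
#' @param snr Signal-to-noise ratio (unit signal gain over noise sd).
#' @param fs Sampling rate, Hz.
#' @param t_range Epoch limits in seconds relative to stimulus onset.
#' @param response_window Seconds `(from, to)` of the injected response.
#' @param basis A [tuning_basis()] defining the channel drive.
#' @param seed Integer seed.
#' @return An [epoch_set()] with meta columns `position`, `orientation`,
#'   `block`, `flicker`.
#' @export
simulate_localizer <- function(fm, n_blocks = 2, reps = 10, snr = 1,
                               fs = 400, t_range = c(-0.1, 0.45),
                               response_window = c(0.14, 0.17),
                               basis = tuning_basis(), seed = 1) {
  stopifnot(snr > 0)
  set.seed(seed)
  meta <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    blk <- enumerate_localizer_block(reps = reps)
    blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
    blk$block <- b
    blk
  }))
  rownames(meta) <- NULL
  n_trials <- nrow(meta)
  tt <- seq(t_range[1], t_range[2], by = 1 / fs)
  n_time <- length(tt)
  on <- as.numeric(tt >= response_window[1] - 1e-9 &
                     tt <= response_window[2] + 1e-9)
  n_sensors <- nrow(fm$patterns)
  L <- chol(fm$noise_cov)
  sd_n <- if (is.finite(snr)) 1 / snr else 0
  data <- array(0, c(n_trials, n_sensors, n_time))
  for (i in seq_len(n_trials)) {
    drive <- tuning_curve(meta$position[i], basis$centers, basis$alpha)
    sig <- fm$patterns %*% (drive %o% on)
    data[i, , ] <- sig + draw_noise(L, n_time, sd_n)
  }
  dimnames(data) <- list(NULL, rownames(fm$patterns), NULL)
  epoch_set(data, fs = fs, t0 = t_range[1], meta = meta)
}

#' Latent attentional process parameters
#'
#' Describes the planted attentional dynamics of a simulated decision
#' session: an `osc_freq` Hz strength oscillation of depth `osc_depth`, with
#' attentional events placed either at its peaks (stay: refocusing the same
#' alternative, at integer multiples of the cycle from the previous event)
#' and troughs (switch: reorienting to a different alternative, at
#' half-integer multiples), or at uniform random phases. With
#' `reset_on_switch = TRUE` the oscillation phase restarts at its peak at
#' every event; otherwise it free-runs across the trial, so that event timing
#' depends on event history.
#'
#' @param osc_freq Oscillation frequency, Hz.
#' @param osc_depth Relative modulation depth in \[0, 1\].
#' @param p_switch Probability that an event reorients to a new alternative.
#' @param phase_policy `"stay_at_peak_switch_at_trough"` or `"uniform"`
#'   (exponential inter-event intervals, no phase preference).
#' @param reset_on_switch Reset the oscillation phase at each event.
#' @param cycle_skip Probability of skipping one further full cycle before the
#'   next event (geometric; gives the histogram its later modes).
#' @param p_gap,gap_mean_cycles With probability `p_gap` an event cluster ends
#'   and a longer, Poisson-distributed number of extra full cycles (mean
#'   `gap_mean_cycles`) passes before the next event; events thus arrive in
#'   the burst-like clusters seen empirically while every interval remains
#'   phase-locked to the oscillation.
#' @param jitter_sd Event-timing jitter sd in seconds, truncated at 3 sd so
#'   planted events stay within 10 percent of a cycle of their nominal phase.
#' @return A list of class `attention_process`.
#' @export
attention_process <- function(osc_freq = 11, osc_depth = 0.5,
                              p_switch = 0.37,
                              phase_policy = c("stay_at_peak_switch_at_trough",
                                               "uniform"),
                              reset_on_switch = TRUE,
                              cycle_skip = 0.3, p_gap = 0.35,
                              gap_mean_cycles = 4, jitter_sd = 0.0025) {
  if (osc_depth < 0 || osc_depth > 1)
    stop("osc_depth must lie in [0, 1]")
  stopifnot(osc_freq > 0, p_switch >= 0, p_switch <= 1,
            p_gap >= 0, p_gap <= 1)
  structure(list(osc_freq = osc_freq, osc_depth = osc_depth,
                 p_switch = p_switch,
                 phase_policy = match.arg(phase_policy),
                 reset_on_switch = reset_on_switch,
                 cycle_skip = cycle_skip, p_gap = p_gap,
                 gap_mean_cycles = gap_mean_cycles, jitter_sd = jitter_sd),
            class = "attention_process")
}

# One trial's planted event sequence: data.frame(onset, locus, label).
plant_events <- function(process, stim_window, centers = c(0, 120, 240)) {
  f <- process$osc_freq
  cyc <- 1 / f
  margin <- 0.05
  t_min <- stim_window[1] + margin
  t_max <- stim_window[2] - margin
  jit <- function() {
    j <- stats::rnorm(1, sd = process$jitter_sd)
    max(-3, min(3, j / max(process$jitter_sd, 1e-12))) *
      process$jitter_sd
  }
  onset <- t_min + stats::runif(1, 0, cyc)
  locus <- sample(centers, 1)
  label <- "first"
  out_on <- onset; out_loc <- locus; out_lab <- label
  # phase class of the current event: 0 = peak (stay-like), 0.5 = trough
  cls <- 0
  t_cur <- onset
  repeat {
    if (process$phase_policy == "uniform") {
      iv <- 0.025 + stats::rexp(1, rate = f)
      is_switch <- stats::runif(1) < process$p_switch
    } else {
      is_switch <- stats::runif(1) < process$p_switch
      k <- 1 + stats::rgeom(1, prob = 1 - process$cycle_skip)
      if (stats::runif(1) < process$p_gap)
        k <- k + stats::rpois(1, process$gap_mean_cycles)
      if (process$reset_on_switch) {
        # phase restarts at the peak at every event
        iv <- (k - 0.5 * is_switch) * cyc
      } else {
        # free-running phase: stays live at peaks, switches at troughs
        target <- if (is_switch) 0.5 else 0
        base <- (target - cls) %% 1
        if (base < 0.25) base <- base + 1    # enforce a minimal gap
        iv <- (base + (k - 1)) * cyc
        cls <- target
      }
    }
    t_next <- t_cur + iv + jit()
    if (t_next > t_max) break
    if (t_next - t_cur < 0.025) next
    loc_next <- if (is_switch) sample(setdiff(centers, locus), 1) else locus
    out_on <- c(out_on, t_next)
    out_loc <- c(out_loc, loc_next)
    out_lab <- c(out_lab, if (is_switch) "switch" else "stay")
    t_cur <- t_next
    locus <- loc_next
  }
  data.frame(onset = out_on, locus = out_loc, label = out_lab,
             stringsAsFactors = FALSE)
}

#' Simulate a decision session with planted attentional dynamics
#'
#' Generates epoched sensor data for the three-alternative decision task with
#' a known latent attention process. During the stimulus-on period the
#' attended channel receives a drive `locus_gain * 0.5 * (1 + osc_depth *
#' cos(phase))` oscillating at `osc_freq`, plus a brief Gaussian burst
#' (`burst_amp`, sd `burst_sd`) at every planted attentional event; all
#' channels share a constant baseline that cancels in the vector sum, and
#' every channel carries Gaussian drive noise of sd `drive_noise_sd`
#' (attentional variability intrinsic to the latent process: between events
#' the decoded locus wanders, while bursts pin it to the attended
#' alternative; without it the angular readout would saturate at high sensor
#' SNR). Sensor data are `patterns %*% drive` plus Gaussian noise of sd
#' `1/snr`. Each trial
#' is assigned a condition from the task design; the reported choice is drawn
#' with probability proportional to `exp(choice_beta * n_events)` per decision
#' value class, so that sampling an alternative more often makes it more
#' likely to be chosen.
#'
#' @param fm A [make_forward_model()].
#' @param n_trials Number of trials.
#' @param process An [attention_process()].
#' @param snr Signal-to-noise ratio (locus gain of 2 over noise sd `1/snr`).
#' @param fs Sampling rate, Hz.
#' @param t_range Epoch limits in seconds relative to stimulus onset; the
#'   spanned duration must be at least 3.8 s (the task's stimulus period).
#' @param stim_window Stimulus-on interval in seconds.
#' @param basis A [tuning_basis()].
#' @param burst_amp,burst_sd Event-burst amplitude and temporal sd (seconds).
#' @param base_drive Constant per-channel baseline drive.
#' @param locus_gain Gain of the oscillatory locus drive.
#' @param drive_noise_sd Sd of the per-channel drive noise.
#' @param choice_beta Softmax weight of event counts on choice.
#' @param seed Integer seed.
#' @return A list with `epochs` (an [epoch_set()]; meta has `framing`,
#'   contrast and value-class columns, `triplet`, `choice`, `correct`),
#'   `events` (ground-truth [event_table()]), and `process`.
#' @export
simulate_decision_session <- function(fm, n_trials,
                                      process = attention_process(),
                                      snr = 1, fs = 400,
                                      t_range = c(-1.5, 2.8),
                                      stim_window = c(0, 2.8),
                                      basis = tuning_basis(),
                                      burst_amp = 3, burst_sd = 0.005,
                                      base_drive = 1, locus_gain = 1.5,
                                      drive_noise_sd = 0.5,
                                      choice_beta = 0.5, seed = 1) {
  stopifnot(inherits(process, "attention_process"), snr > 0)
  if (diff(t_range) < 3.8 - 1e-9)
    stop("trial duration must be at least 3.8 s")
  set.seed(seed)
  centers <- basis$centers
  tt <- seq(t_range[1], t_range[2], by = 1 / fs)
  n_time <- length(tt)
  stim_on <- tt >= stim_window[1] & tt <= stim_window[2]
  n_sensors <- nrow(fm$patterns)
  L <- chol(fm$noise_cov)
  sd_n <- if (is.finite(snr)) 1 / snr else 0

  design <- enumerate_design()
  cond <- design$trial_list[sample.int(design$n_trials, n_trials,
                                       replace = n_trials > design$n_trials), ,
                            drop = FALSE]
  rownames(cond) <- NULL

  data <- array(0, c(n_trials, n_sensors, n_time))
  dimnames(data) <- list(NULL, rownames(fm$patterns), NULL)
  ev_list <- vector("list", n_trials)
  value_of <- matrix(NA_character_, n_trials, 3)  # class of each position
  choice <- character(n_trials)

  for (i in seq_len(n_trials)) {
    ev <- plant_events(process, stim_window, centers)
    ev$trial <- i
    ev_list[[i]] <- ev

    # locus path: constant between events, set by the first event before it
    locus_path <- rep(ev$locus[1], n_time)
    if (nrow(ev) > 1) {
      for (j in 2:nrow(ev))
        locus_path[tt >= ev$onset[j]] <- ev$locus[j]
    }
    # oscillation phase: zero (peak) at the most recent event
    anchor <- rep(ev$onset[1], n_time)
    for (j in seq_len(nrow(ev)))
      anchor[tt >= ev$onset[j]] <- ev$onset[j]
    if (!process$reset_on_switch) anchor <- rep(ev$onset[1], n_time)
    phase <- 2 * pi * process$osc_freq * (tt - anchor)
    osc <- locus_gain * 0.5 * (1 + process$osc_depth * cos(phase))

    drive <- matrix(base_drive, 3, n_time)
    if (drive_noise_sd > 0)
      drive <- drive + matrix(stats::rnorm(3 * n_time, sd = drive_noise_sd),
                              3, n_time)
    for (k in 1:3) {
      sel <- stim_on & locus_path == centers[k]
      drive[k, sel] <- drive[k, sel] + osc[sel]
    }
    half <- ceiling(3 * burst_sd * fs)
    for (j in seq_len(nrow(ev))) {
      k <- match(ev$locus[j], centers)
      c0 <- which.min(abs(tt - ev$onset[j]))
      idx <- max(1, c0 - half):min(n_time, c0 + half)
      drive[k, idx] <- drive[k, idx] +
        burst_amp * exp(-(tt[idx] - ev$onset[j])^2 / (2 * burst_sd^2))
    }
    data[i, , ] <- fm$patterns %*% drive + draw_noise(L, n_time, sd_n)

    # decision value class of each position given contrasts and framing
    contrasts <- as.numeric(cond[i, paste0("contrast_pos", 1:3)])
    rk <- rank(contrasts, ties.method = "first")
    value_of[i, ] <- if (cond$framing[i] == "high") {
      c("L", "M", "H")[rk]
    } else {
      c("H", "M", "L")[rk]
    }
    counts <- vapply(c("H", "M", "L"), function(v) {
      pos <- centers[value_of[i, ] == v]
      sum(ev$locus %in% pos)
    }, numeric(1))
    pr <- exp(choice_beta * counts)
    choice[i] <- sample(c("H", "M", "L"), 1, prob = pr / sum(pr))
  }

  ev_all <- do.call(rbind, ev_list)
  events <- event_table(ev_all$trial, ev_all$onset, ev_all$locus,
                        label = ev_all$label, source = "ground_truth")
  triplet <- apply(cond[, paste0("contrast_pos", 1:3)], 1L,
                   function(x) paste(sort(x), collapse = "|"))
  meta <- cbind(cond,
                data.frame(value_pos1 = value_of[, 1],
                           value_pos2 = value_of[, 2],
                           value_pos3 = value_of[, 3],
                           triplet = triplet, choice = choice,
                           correct = choice == "H",
                           stringsAsFactors = FALSE))
  list(epochs = epoch_set(data, fs = fs, t0 = t_range[1], meta = meta),
       events = events, process = process,
       stim_window = stim_window)
}

#' Simulate fixational gaze and pupil traces
#'
#' Gaze is temporally smooth fixational jitter (low-pass-filtered Gaussian
#' noise rescaled to `jitter_sd`) plus brief saccadic displacements: a
#' background train at `saccade_rate` Hz and, under
#' `coupling = "saccade_precedes_switch"`, a saccade placed `delta` seconds
#' before a fraction `p` of the planted switch events. Each saccade displaces
#' gaze by 0.3-0.8 degrees over three samples. The pupil trace is a slow
#' smooth drift.
#'
#' @param n_trials Number of trials.
#' @param fs Sampling rate, Hz.
#' @param t_range Trace limits in seconds.
#' @param events Optional ground-truth [event_table()] (needed for coupling).
#' @param coupling `"none"` or `"saccade_precedes_switch"`.
#' @param delta Saccade lead time before a switch event, seconds.
#' @param p Fraction of switch events preceded by a saccade.
#' @param jitter_sd Fixational jitter sd, degrees.
#' @param saccade_rate Background saccade rate, Hz.
#' @param amp_range Saccade amplitude range, degrees.
#' @param seed Integer seed.
#' @return A [gaze_record()] with the planted saccade table attached.
#' @export
simulate_gaze <- function(n_trials, fs = 400, t_range = c(-1.5, 2.8),
                          events = NULL,
                          coupling = c("none", "saccade_precedes_switch"),
                          delta = 0.15, p = 1, jitter_sd = 0.05,
                          saccade_rate = 1, amp_range = c(0.3, 0.8),
                          seed = 1) {
  coupling <- match.arg(coupling)
  stopifnot(delta >= 0, p >= 0, p <= 1)
  if (coupling == "saccade_precedes_switch" && is.null(events))
    stop("coupling to switch events requires the event table")
  set.seed(seed)
  tt <- seq(t_range[1], t_range[2], by = 1 / fs)
  n_time <- length(tt)
  dur <- diff(t_range)
  bf <- signal::butter(2, min(0.99, 4 / (fs / 2)), type = "low")
  smooth_noise <- function(sd_target) {
    z <- signal::filtfilt(bf, stats::rnorm(n_time))
    s <- stats::sd(z)
    if (s < 1e-12 || sd_target == 0) return(rep(0, n_time))
    z / s * sd_target
  }
  x <- matrix(0, n_trials, n_time)
  y <- matrix(0, n_trials, n_time)
  pupil <- matrix(0, n_trials, n_time)
  planted <- vector("list", n_trials)
  bp <- signal::butter(2, min(0.99, 0.5 / (fs / 2)), type = "low")

  for (i in seq_len(n_trials)) {
    xi <- if (jitter_sd > 0) smooth_noise(jitter_sd) else rep(0, n_time)
    yi <- if (jitter_sd > 0) smooth_noise(jitter_sd) else rep(0, n_time)
    sacc <- numeric(0)
    if (coupling == "saccade_precedes_switch") {
      sw <- events$onset[events$trial == i & events$label == "switch"]
      sw <- sw[stats::runif(length(sw)) < p]
      cand <- sort(sw - delta)
      cand <- cand[cand > t_range[1] + 0.01 & cand < t_range[2] - 0.02]
      for (s in cand)
        if (!length(sacc) || min(abs(sacc - s)) >= 0.025) sacc <- c(sacc, s)
    }
    if (saccade_rate > 0) {
      # background train thinned to a 0.15 s floor (serial-saccade delay;
      # empirical inter-saccade intervals peak around 0.25 s)
      n_bg <- stats::rpois(1, saccade_rate * dur)
      bg <- sort(stats::runif(n_bg, t_range[1] + 0.01, t_range[2] - 0.02))
      for (s in bg)
        if (!length(sacc) || min(abs(sacc - s)) >= 0.15) sacc <- c(sacc, s)
    }
    sacc <- sort(sacc)
    for (s in sacc) {
      amp <- stats::runif(1, amp_range[1], amp_range[2])
      i0 <- which.min(abs(tt - s))
      pos <- c(xi[i0], yi[i0])
      dir <- if (sqrt(sum(pos^2)) > 2) {
        atan2(-pos[2], -pos[1]) + stats::rnorm(1, sd = 0.5)
      } else {
        stats::runif(1, 0, 2 * pi)
      }
      step <- amp * c(cos(dir), sin(dir))
      frac <- c(0.25, 0.75, 1)                 # ramp over 3 samples
      for (q in seq_along(frac)) {
        j <- i0 + q - 1L
        if (j <= n_time) {
          xi[j:n_time] <- xi[j:n_time] +
            step[1] * (frac[q] - if (q == 1) 0 else frac[q - 1])
          yi[j:n_time] <- yi[j:n_time] +
            step[2] * (frac[q] - if (q == 1) 0 else frac[q - 1])
        }
      }
    }
    x[i, ] <- xi
    y[i, ] <- yi
    pupil[i, ] <- 0.5 + {
      z <- signal::filtfilt(bp, stats::rnorm(n_time))
      s <- stats::sd(z)
      if (s > 1e-12) 0.1 * z / s else rep(0, n_time)
    }
    planted[[i]] <- if (length(sacc))
      data.frame(trial = i, onset = sacc) else NULL
  }
  planted <- do.call(rbind, planted)
  gaze_record(x, y, pupil = pupil, fs = fs, t0 = t_range[1],
              planted = planted)
}
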