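# Shared fixtures: a small forward model, a localizer-trained encoding model
# and one decision session with planted 11 Hz dynamics. Built once when the
# helpers are sourced; individual tests derive what they need.

fx <- local({
  fm <- make_forward_model(16, seed = 2)
  localizer <- simulate_localizer(fm, n_blocks = 4, snr = 1, seed = 3)
  model <- train_encoding_model(localizer)
  session <- simulate_decision_session(fm, n_trials = 80, snr = 1, seed = 7)
  trace <- attentional_vector(invert_model(model, session$epochs))
  events <- detect_events(trace, stim_window = session$stim_window)
  list(fm = fm, localizer = localizer, model = model, session = session,
       trace = trace, events = events)
})

# Hand-built attention trace: one or more trials assembled from explicit
# length / angle series (mas derived), at fs Hz starting at t0.
make_trace <- function(length_mat, angle_mat, fs = 400, t0 = 0) {
  length_mat <- rbind(length_mat)
  angle_mat <- rbind(angle_mat)
  structure(list(length = length_mat, angle = angle_mat,
                 mas = max_angular_similarity(angle_mat),
                 fs = fs, t0 = t0, centers = c(0, 120, 240)),
            class = "attention_trace")
}

# Event table on an exact oscillatory grid: per trial, events at
# start + cumsum(k_i - 0.5 * switch_i) cycles; used to test the IEI
# machinery independently of the decoding pipeline.
grid_events <- function(n_trials, f = 11, t_max = 2.75, p_switch = 0.37,
                        seed = 1) {
  set.seed(seed)
  cyc <- 1 / f
  rows <- lapply(seq_len(n_trials), function(i) {
    t <- runif(1, 0.05, 0.05 + cyc)
    locus <- sample(c(0, 120, 240), 1)
    on <- t; loc <- locus
    repeat {
      sw <- runif(1) < p_switch
      k <- 1 + rgeom(1, 0.7) + if (runif(1) < 0.3) rpois(1, 4) else 0
      t <- t + (k - 0.5 * sw) * cyc
      if (t > t_max) break
      locus <- if (sw) sample(setdiff(c(0, 120, 240), locus), 1) else locus
      on <- c(on, t); loc <- c(loc, locus)
    }
    data.frame(trial = i, onset = round(on * 400) / 400, locus = loc)
  })
  df <- do.call(rbind, rows)
  label_stay_switch(event_table(df$trial, df$onset, df$locus))
}

# Homogeneous Bernoulli ("Poisson at sample resolution") event trains;
# thin = TRUE applies the detector's 0.025 s refractory rule, thin = FALSE
# keeps the train exactly memoryless.
poisson_events <- function(n_trials, n_time = 1100, p = 0.02, fs = 400,
                           thin = FALSE, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_trials), function(i) {
    s <- which(runif(n_time) < p)
    if (thin && length(s) > 1) {
      keep <- s[1]
      for (v in s[-1]) if (v - keep[length(keep)] >= 0.025 * fs)
        keep <- c(keep, v)
      s <- keep
    }
    if (!length(s)) return(NULL)
    data.frame(trial = i, onset = s / fs,
               locus = sample(c(0, 120, 240), length(s), replace = TRUE))
  })
  df <- do.call(rbind, rows)
  label_stay_switch(event_table(df$trial, df$onset, df$locus,
                                min_spacing = if (thin) 0.025 else 0))
}

# Smooth fixational drift (random walk rescaled to the target position sd)
# for hand-built gaze traces.
smooth_jitter <- function(n, sd_target, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- cumsum(rnorm(n))
  z <- z - mean(z)
  if (sd_target == 0) rep(0, n) else z / stats::sd(z) * sd_target
}
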