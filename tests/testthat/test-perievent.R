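# Constructions: traces with known peri-event structure, small additive
# noise so the z-scoring variance is defined.

osc_trace_with_events <- function(n_trials, f = 10, fs = 400, t_max = 3,
                                  noise = 0.02, seed = 1) {
  set.seed(seed)
  tt <- seq(0, t_max, by = 1 / fs)
  len <- matrix(0, n_trials, length(tt))
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    phase <- runif(1, 0, 1 / f)
    len[i, ] <- cos(2 * pi * f * (tt - phase)) +
      rnorm(length(tt), sd = noise)
    peaks <- seq(phase, t_max, by = 1 / f)
    peaks <- round(peaks * fs) / fs
    peaks <- peaks[peaks > 0.3 & peaks < t_max - 0.3]
    keep <- sort(sample(seq_along(peaks), max(2, length(peaks) %/% 2)))
    rows[[i]] <- data.frame(trial = i, onset = peaks[keep], locus = 0)
  }
  df <- do.call(rbind, rows)
  list(trace = make_trace(len, matrix(0, n_trials, ncol(len)), fs = fs),
       events = label_stay_switch(event_table(df$trial, df$onset, df$locus)))
}

test_that("events planted at oscillation peaks give a phase-locked average", {
  cx <- osc_trace_with_events(40, f = 10, seed = 3)
  pea <- event_triggered_average(cx$trace, cx$events,
                                 labels = c("first", "stay"))
  avg <- pea$avg["stay", ]
  expect_equal(pea$lags[which.max(avg)], 0)
  # oscillation visible at +/- one cycle
  cyc <- which.min(abs(pea$lags - 0.1))
  expect_gt(avg[cyc], 0.5 * max(avg))
  trough <- which.min(abs(pea$lags - 0.05))
  expect_lt(avg[trough], 0)
})

test_that("shuffled event times give a flat average", {
  cx <- osc_trace_with_events(40, f = 10, seed = 4)
  ev <- cx$events
  set.seed(5)
  ev$onset <- round(runif(nrow(ev), 0.3, 2.7) * 400) / 400
  ev <- label_stay_switch(event_table(ev$trial, ev$onset, ev$locus,
                                      min_spacing = 0))
  pea <- event_triggered_average(cx$trace, ev, labels = c("first", "stay"))
  expect_lt(max(abs(pea$avg["stay", ])), 0.35)
})

test_that("degenerate peri-event inputs raise errors", {
  flat <- make_trace(matrix(1, 2, 1200), matrix(0, 2, 1200))
  ev <- label_stay_switch(event_table(1:2, c(1, 1.5), 0))
  expect_error(event_triggered_average(flat, ev, labels = "first"),
               "zero variance")
  edge <- label_stay_switch(event_table(1, 0.01, 0))
  tr <- make_trace(matrix(rnorm(1200), 2), matrix(0, 2, 600))
  expect_error(event_triggered_average(tr, edge, labels = "first"),
               "complete")
})

test_that("the dominant-frequency estimator inverts peak spacing exactly", {
  # 12 Hz: two peaks fall strictly inside each estimation interval
  cx <- osc_trace_with_events(60, f = 12, seed = 6)
  pea <- event_triggered_average(cx$trace, cx$events,
                                 labels = c("first", "stay"))
  fr <- perievent_frequency(pea)
  f_post <- fr$f_post[fr$label == "stay"]
  # 12 Hz up to one-sample quantization of the peak latencies
  expect_equal(f_post, 12, tolerance = 0.05)
  f_pre <- fr$f_pre[fr$label == "stay"]
  expect_equal(f_pre, 12, tolerance = 0.05)
})

test_that("frequencies are missing with fewer than two peaks", {
  fs <- 400
  lags <- seq(-80, 80) / fs
  avg <- matrix(sin(2 * pi * 3 * lags), 1,
                dimnames = list("stay", NULL))   # < 2 peaks per interval
  pea <- structure(list(lags = lags, avg = avg, raw = avg,
                        n_events = c(stay = 10L), fs = fs),
                   class = "perievent_average")
  fr <- perievent_frequency(pea)
  expect_true(is.na(fr$f_pre) && is.na(fr$f_post))
})

test_that("pre-switch acceleration doubles the pre-event frequency", {
  # trace built so switch events see 20 Hz before and 10 Hz after onset
  fs <- 400
  tt <- seq(0, 2, by = 1 / fs)
  set.seed(7)
  n <- 50
  len <- matrix(rnorm(n * length(tt), sd = 0.02), n)
  onsets <- round(runif(n, 0.5, 1.5) * fs) / fs
  for (i in seq_len(n)) {
    rel <- tt - onsets[i]
    len[i, ] <- len[i, ] +
      ifelse(rel < 0, cos(2 * pi * 24 * rel), cos(2 * pi * 12 * rel))
  }
  ev <- label_stay_switch(event_table(rep(seq_len(n), each = 2),
                                      as.vector(rbind(onsets - 0.45, onsets)),
                                      as.vector(rbind(0, 120))))
  tr <- make_trace(len, matrix(0, n, length(tt)), fs = fs)
  pea <- event_triggered_average(tr, ev, labels = "switch")
  fr <- perievent_frequency(pea)
  expect_equal(fr$f_pre / fr$f_post, 2, tolerance = 0.25)
})

test_that("switch/stay strength ratios track planted deficits", {
  fs <- 400
  tt <- seq(0, 2, by = 1 / fs)
  set.seed(8)
  build <- function(pre_level, post_level) {
    n <- 60
    len <- matrix(1 + rnorm(n * length(tt), sd = 0.02), n)
    onsets <- round(runif(n, 0.5, 1.5) * fs) / fs
    lab_locus <- ifelse(seq_len(n) %% 2 == 0, 120, 0)
    for (i in seq_len(n)) {
      if (lab_locus[i] == 120) {      # switch trials carry the deficit
        rel <- tt - onsets[i]
        len[i, rel < -0.02] <- len[i, rel < -0.02] * pre_level
        len[i, rel > 0.02] <- len[i, rel > 0.02] * post_level
      }
    }
    ev <- label_stay_switch(event_table(rep(seq_len(n), each = 2),
                                        as.vector(rbind(onsets - 0.3,
                                                        onsets)),
                                        as.vector(rbind(0, lab_locus))))
    list(trace = make_trace(len, matrix(0, n, length(tt)), fs = fs),
         events = ev)
  }
  same <- build(1, 1)
  r0 <- pre_post_ratio(same$trace, same$events)
  expect_equal(r0$ratio_pre, 1, tolerance = 0.02)
  expect_equal(r0$ratio_post, 1, tolerance = 0.02)
  deficit <- build(0.9, 0.9)
  r1 <- pre_post_ratio(deficit$trace, deficit$events)
  expect_equal(r1$ratio_pre, 0.9, tolerance = 0.03)
  expect_equal(r1$ratio_post, 0.9, tolerance = 0.03)
  pre_only <- build(0.9, 1)
  r2 <- pre_post_ratio(pre_only$trace, pre_only$events)
  expect_gt(r2$delta, 0.05)
  stays <- same$events[same$events$label != "switch", ]
  expect_error(pre_post_ratio(same$trace, stays), "stay and switch")
})

test_that("event-triggered averages are invariant to event order", {
  cx <- osc_trace_with_events(20, seed = 9)
  ev <- cx$events
  pea1 <- event_triggered_average(cx$trace, ev, labels = c("stay"))
  ev2 <- ev[rev(seq_len(nrow(ev))), ]
  pea2 <- event_triggered_average(cx$trace, ev2, labels = c("stay"))
  expect_equal(pea1$avg, pea2$avg)
})
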