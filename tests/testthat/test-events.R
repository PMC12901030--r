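toy_trace <- function(blocks, n_time = 200, fs = 400) {
  # blocks: list of c(start_sample, len, angle); the floor has an undefined
  # locus (zero-length vector), so only block samples can pass the MAS gate
  len <- rep(0.1, n_time) + seq_len(n_time) * 1e-6
  ang <- rep(NA_real_, n_time)
  for (b in blocks) {
    idx <- b[1]:(b[1] + b[2] - 1L)
    len[idx] <- 10
    ang[idx] <- b[3]
  }
  make_trace(len, ang, fs = fs)
}

test_that("dual thresholding records rising-edge onsets with loci", {
  tr <- toy_trace(list(c(21, 10, 0), c(61, 10, 120)))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$locus, c(0, 120))
  expect_equal(ev$onset, c(20, 60) / 400)
  expect_equal(ev$label, c("first", "switch"))
  # undefined angles everywhere: no sample passes the MAS gate
  none <- detect_events(make_trace(rep(1, 100) + 1:100 * 1e-6,
                                   rep(NA_real_, 100)))
  expect_equal(nrow(none), 0)
})

test_that("the refractory rule suppresses close re-crossings", {
  # two crossings 8 samples (0.02 s) apart at the same locus -> one event
  tr <- toy_trace(list(c(21, 4, 0), c(29, 4, 0)))
  expect_equal(nrow(detect_events(tr)), 1)
  # 12 samples (0.03 s) apart -> two events
  tr2 <- toy_trace(list(c(21, 4, 0), c(33, 4, 0)))
  expect_equal(nrow(detect_events(tr2)), 2)
})

test_that("a locus change during a sustained conjunction re-arms detection", {
  len <- rep(0.1, 200) + seq_len(200) * 1e-6
  ang <- rep(60, 200)
  len[21:52] <- 10
  ang[21:36] <- 0; ang[37:52] <- 120   # change 16 samples (0.04 s) in
  ev <- detect_events(make_trace(len, ang))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$locus, c(0, 120))
  expect_equal(ev$onset[2] - ev$onset[1], 16 / 400)
})

test_that("stay/switch labelling follows the locus sequence", {
  ev <- event_table(rep(1, 5), seq(0.1, 0.5, by = 0.1),
                    c(0, 0, 120, 120, 240))
  lab <- label_stay_switch(ev)
  expect_equal(lab$label, c("first", "stay", "switch", "stay", "switch"))
  single <- label_stay_switch(event_table(1:3, rep(0.1, 3), c(0, 120, 240)))
  expect_true(all(single$label == "first"))
})

test_that("IEI histograms are normalized over all intervals", {
  start <- round(runif(50, 0.1, 0.4) * 400) / 400
  ev <- label_stay_switch(event_table(rep(1:50, each = 2),
                                      as.vector(rbind(start, start + 0.1)),
                                      0))
  h <- iei_histogram(ev, fs = 400)
  expect_equal(sum(h$prob), 1)
  expect_equal(h$bin_centers[which(h$prob > 0)], 0.1)
  # alternating 0.09 / 0.18 spacings split 50/50
  on <- cumsum(rep(c(0.09, 0.18), 10))
  ev2 <- label_stay_switch(event_table(rep(1:4, each = 20),
                                       rep(on, 4), 0))
  h2 <- iei_histogram(ev2, fs = 400)
  nz <- which(h2$prob > 0)
  expect_equal(h2$bin_centers[nz], c(0.09, 0.18))
  # 19 intervals per trial alternating from 0.18: ten long, nine short
  expect_equal(unname(h2$prob[nz]), c(9, 10) / 19)
  # intervals beyond the display range stay in the denominator
  ev3 <- label_stay_switch(event_table(1, c(0.1, 0.2, 1.2), 0))
  h3 <- iei_histogram(ev3, fs = 400)
  expect_equal(h3$n_intervals, 2)
  expect_equal(sum(h3$prob), 0.5)
})

test_that("Poisson event trains give a discretized exponential IEI decay", {
  p <- 0.03
  ev <- poisson_events(400, p = p, seed = 5)
  h <- iei_histogram(ev, fs = 400)
  d <- round(h$bin_centers * 400)
  oracle <- (1 - p)^(d - 1) * p          # geometric interval pmf
  expect_lt(max(abs(h$prob - oracle)), 0.006)
  expect_gt(cor(h$prob, oracle), 0.97)
})

test_that("histograms are invariant to trial order permutation", {
  ev <- grid_events(60, seed = 2)
  perm <- sample(60)
  ev2 <- ev
  ev2$trial <- perm[ev2$trial]
  ev2 <- label_stay_switch(event_table(ev2$trial, ev2$onset, ev2$locus))
  for (w in c("all", "stay", "switch"))
    expect_equal(iei_histogram(ev2, 400, which = w)$prob,
                 iei_histogram(ev, 400, which = w)$prob)
})

test_that("trial shuffling preserves per-timepoint counts exactly", {
  ev <- grid_events(40, seed = 3)
  sh <- shuffle_event_trials(ev, n_trials = 40, fs = 400, seed = 9)
  expect_equal(table(round(sh$onset * 400)), table(round(ev$onset * 400)))
  expect_true(all(sh$trial %in% 1:40))
  expect_false(identical(sh$trial, ev$trial))
})

test_that("shuffle nulls are seed-reproducible and calibrated", {
  ev <- poisson_events(150, p = 0.025, seed = 6)   # memoryless train
  n1 <- trial_shuffle_null(ev, n_trials = 150, fs = 400, n_shuffles = 50,
                           seed = 4)
  n2 <- trial_shuffle_null(ev, n_trials = 150, fs = 400, n_shuffles = 50,
                           seed = 4)
  expect_identical(n1, n2)
  # independent events: observed probabilities sit inside the null band
  h <- iei_histogram(ev, fs = 400)
  z <- (h$prob - n1$null_mean) / pmax(n1$null_sd, 1e-12)
  expect_lt(mean(abs(z) > 2), 0.12)
  expect_error(trial_shuffle_null(ev[ev$trial == 1, ], n_trials = 1,
                                  fs = 400), "2 trials")
})

test_that("concentrating all events in one trial is destroyed by shuffling", {
  on <- seq(0.05, 2.5, by = 0.0909)
  ev <- label_stay_switch(event_table(rep(1, length(on)), on, 0))
  nul <- trial_shuffle_null(ev, n_trials = 50, fs = 400, n_shuffles = 200,
                            seed = 2)
  h <- iei_histogram(ev, fs = 400)
  # observed mass concentrates at ~0.0909 s; the null spreads it out
  expect_gt(max(h$prob - nul$null_mean), 0.5)
})

test_that("mode detection recovers a planted 11 Hz cycle length", {
  ev <- grid_events(250, f = 11, seed = 8)
  nul <- trial_shuffle_null(ev, n_trials = 250, fs = 400, n_shuffles = 400,
                            which = c("stay", "switch"), seed = 5)
  ms <- detect_histogram_modes(iei_histogram(ev, 400, which = "stay"),
                               nul$stay)
  expect_lte(abs(ms$modes$latency[1] - 1 / 11), 2 / 400 + 1e-9)
  expect_lte(abs(ms$cycle_length - 1 / 11), 1 / 400 + 1e-9)
  msw <- detect_histogram_modes(iei_histogram(ev, 400, which = "switch"),
                                nul$switch)
  expect_lte(abs(msw$modes$latency[1] - 0.5 / 11), 2 / 400 + 1e-9)
  # stay-at-peak / switch-at-trough: first switch mode at half the stay mode
  expect_equal(msw$modes$latency[1] / ms$modes$latency[1], 0.5,
               tolerance = 0.12)
})

test_that("Poisson event trains produce no spurious rhythmic modes", {
  ev <- poisson_events(200, p = 0.025, seed = 9)
  nul <- trial_shuffle_null(ev, n_trials = 200, fs = 400, n_shuffles = 400,
                            seed = 6)
  md <- detect_histogram_modes(iei_histogram(ev, 400), nul, alpha = 0.01)
  expect_lte(md$n_significant_bins, ceiling(0.05 * length(nul$null_mean)))
  expect_lte(nrow(md$modes), 8)
})

test_that("second-order histograms separate reset and free-running regimes", {
  # reset regime: intervals independent of history by construction
  ev <- grid_events(250, seed = 10)
  h <- second_order_iei(ev, fs = 400)
  expect_named(h, c("stay_after_stay", "stay_after_switch",
                    "switch_after_stay", "switch_after_switch"))
  nul <- trial_shuffle_null(ev, n_trials = 250, fs = 400, n_shuffles = 300,
                            which = names(h), seed = 7)
  lat <- vapply(names(h), function(cl)
    detect_histogram_modes(h[[cl]], nul[[cl]])$modes$latency[1], numeric(1))
  expect_lte(abs(lat["stay_after_stay"] - lat["stay_after_switch"]),
             2 / 400 + 1e-9)
  # no switches at all: switch-conditioned histograms are empty
  ev0 <- grid_events(30, p_switch = 0, seed = 11)
  h0 <- second_order_iei(ev0, fs = 400)
  expect_equal(h0$switch_after_stay$n_intervals, 0)
  expect_equal(sum(h0$stay_after_switch$prob), 0)
})

test_that("the threshold sweep covers the stated 12 x 12 grid", {
  sw <- threshold_sweep(fx$trace, stim_window = fx$session$stim_window)
  expect_equal(sw$n_cells, 144)
  expect_equal(dim(sw$intensity), c(12, 12))
  expect_equal(sw$mas_pcts, c(seq(50, 95, 5), 97.5, 99))
  # the planted rhythm yields measurable modulation intensity in the
  # recommended threshold band, and every first-mode latency there lands on
  # a rhythm-consistent lag (half or one full cycle of the 11 Hz rhythm)
  band <- sw$intensity[c("80", "85", "90"), c("80", "85", "90")]
  expect_true(all(is.finite(band)))
  expect_true(all(band > 0))
  fl <- sw$first_mode[c("80", "85", "90"), c("80", "85", "90")]
  # the double 10-sample boxcar on the log histogram can displace the peak
  # of the merged hump by a few samples; 5 samples is still well under half
  # the half-cycle separation of the two rhythm lags
  dev <- pmin(abs(fl - 0.5 / 11), abs(fl - 1 / 11))
  expect_lte(max(dev), 5 / 400 + 1e-9)
})

test_that("Poisson events give near-zero modulation intensity", {
  set.seed(15)
  # a trace whose suprathreshold crossings are temporally unstructured
  len <- matrix(rexp(500 * 1100), 500)
  ang <- matrix(runif(500 * 1100, 0, 360), 500)
  tr <- make_trace(len, ang)
  sw <- threshold_sweep(tr, mas_pcts = c(70, 80), len_pcts = c(70, 80))
  rhythmic <- threshold_sweep(fx$trace, mas_pcts = c(80, 85, 90),
                              len_pcts = c(80, 85, 90),
                              stim_window = fx$session$stim_window)
  # typical null modulation is small and well below the strongest planted
  # modulation in the recommended band
  expect_lt(median(sw$intensity, na.rm = TRUE), 0.15)
  expect_gt(max(rhythmic$intensity, na.rm = TRUE),
            2 * median(sw$intensity, na.rm = TRUE))
})

test_that("choice regression recovers planted sampling-to-choice coupling", {
  set.seed(16)
  n <- 400
  counts <- as.data.frame(matrix(rpois(n * 6, 3), n,
    dimnames = list(NULL, c("stay_H", "stay_M", "stay_L",
                            "switch_H", "switch_M", "switch_L"))))
  # null: choice independent of counts
  fit0 <- choice_regression(counts, sample(c("H", "M", "L"), n, TRUE))
  expect_lt(max(abs(fit0$H$coef[-1])), 0.35)
  expect_false(fit0$H$penalized)
  # planted: sampling H drives choosing H
  pr <- exp(0.8 * counts$stay_H + 0.8 * counts$switch_H)
  choice <- ifelse(runif(n) < pr / (pr + 20), "H",
                   sample(c("M", "L"), n, TRUE))
  fit <- choice_regression(counts, choice)
  expect_gt(unname(fit$H$coef["stay_H"]), 0.2)
  expect_gt(unname(fit$H$coef["switch_H"]), 0.2)
  # constant predictors are dropped with a warning
  counts$stay_L <- 2L
  expect_warning(choice_regression(counts, choice), "constant predictor")
  expect_error(choice_regression(counts[1:10, ], choice[1:10]), "30 trials")
})

test_that("per-trial value-class event counts match direct tallies", {
  ses <- fx$session
  cnt <- event_value_counts(ses$events, ses$epochs$meta)
  expect_equal(nrow(cnt), nrow(ses$epochs$meta))
  ev1 <- ses$events[ses$events$trial == 1 &
                      ses$events$label %in% c("stay", "switch"), ]
  vo <- unlist(ses$epochs$meta[1, paste0("value_pos", 1:3)])
  manual <- table(factor(paste0(ev1$label, "_",
                                vo[match(ev1$locus, c(0, 120, 240))]),
                         levels = colnames(cnt)))
  expect_equal(unlist(cnt[1, ]), c(unclass(manual)), ignore_attr = TRUE)
})
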