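test_that("tuning curve matches its closed form and wraps angles", {
  expect_equal(tuning_curve(0, 0), 1)
  expect_equal(tuning_curve(180, 0), 0, tolerance = 1e-12)
  expect_equal(tuning_curve(120, 0, alpha = 5), 0.5^5)   # cos(60 deg)^5
  expect_equal(tuning_curve(240, 0), tuning_curve(120, 0))
  expect_equal(tuning_curve(350, 0), tuning_curve(10, 0))
  th <- seq(0, 359, by = 7)
  expect_true(all(tuning_curve(th, 120) >= 0 & tuning_curve(th, 120) <= 1))
})

test_that("design matrix evaluates every channel at every observation", {
  C <- build_design_matrix(c(0, 120, 240))
  expect_equal(dim(C), c(3, 3))
  expect_equal(diag(C), rep(1, 3))
  expect_equal(C[upper.tri(C)], rep(0.03125, 3))
  single <- build_design_matrix(0)
  expect_equal(unname(single[, 1]), c(1, 0.03125, 0.03125))
  # permuting centers permutes rows identically
  Cp <- build_design_matrix(c(0, 120, 240), tuning_basis(c(240, 0, 120)))
  expect_equal(unname(Cp), unname(C[c(3, 1, 2), ]))
  expect_error(build_design_matrix(numeric(0)), "observations")
})

test_that("weight fit solves the per-channel least squares exactly", {
  set.seed(4)
  C <- build_design_matrix(rep(c(0, 120, 240), 8))
  P <- matrix(rnorm(10 * 3), 10, 3)
  meg <- P %*% C
  joint <- fit_weights(meg, C, joint = TRUE)
  # consistent noiseless system: the joint fit reproduces the data exactly
  expect_equal(joint$W %*% C, meg, tolerance = 1e-10)
  # the printed per-channel (marginal) estimator tolerates the slight
  # non-orthogonality of the tuning columns (off-diagonal 0.03125)
  fit <- fit_weights(meg, C)
  expect_gt(cor(as.vector(fit$W %*% C), as.vector(meg)), 0.995)
  expect_lt(max(abs(fit$W %*% C - meg)) / max(abs(meg)), 0.15)
  # one-hot (orthogonal) design: per-channel and joint estimators agree
  Ci <- diag(3)[, rep(1:3, 5)]
  megi <- P %*% Ci
  expect_equal(fit_weights(megi, Ci)$W, fit_weights(megi, Ci, joint = TRUE)$W)
  expect_equal(fit_weights(megi * 0, Ci)$W, matrix(0, 10, 3),
               ignore_attr = TRUE)
  expect_error(fit_weights(meg[, 1:2], C[, 1:2]), "observations")
})

test_that("weights recover the forward patterns from noisy localizers", {
  fit <- fx$model
  cors <- diag(cor(fit$W, fx$fm$patterns))
  expect_true(all(cors > 0.9))
})

test_that("prewhitening keeps the g'w identity and regularizes", {
  m <- fx$model
  expect_equal(diag(crossprod(m$G, m$W)), rep(1, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # identity noise: g reduces to w / (w'w)
  W <- matrix(rnorm(12), 4, 3)
  pw <- prewhiten_weights(W, noise_cov = diag(4))
  expect_equal(pw$G, sweep(W, 2, colSums(W^2), "/"), ignore_attr = TRUE)
  # shrinkage lowers the condition number of a rank-deficient-ish estimate
  set.seed(8)
  X <- matrix(rnorm(50 * 100), 50, 100)
  sh <- shrink_covariance(X)
  kappa_raw <- kappa(sh$sample, exact = TRUE)
  kappa_shr <- kappa(sh$sigma, exact = TRUE)
  expect_true(sh$gamma > 0 && sh$gamma <= 1)
  expect_lt(kappa_shr, kappa_raw)
  expect_error(shrink_covariance(cbind(rnorm(20), rep(1, 20))),
               "zero-variance")
})

test_that("model inversion is the stated matrix product with guards", {
  m <- fx$model
  # one channel's weight pattern as data decodes to exactly 1 on that channel
  for (k in 1:3) {
    ep <- epoch_set(array(m$W[, k], c(1, nrow(m$W), 1)), fs = 400)
    expect_equal(invert_model(m, ep)$response[1, k, 1], 1, tolerance = 1e-8)
  }
  bad <- epoch_set(array(0, c(1, 5, 2)), fs = 400)
  expect_error(invert_model(m, bad), "sensor mismatch")
})

test_that("sensor permutation leaves decoded responses unchanged", {
  m <- fx$model
  ep <- fx$session$epochs
  perm <- sample(dim(ep$data)[2])
  m2 <- m
  m2$W <- m$W[perm, ]; m2$G <- m$G[perm, ]
  ep2 <- ep
  ep2$data <- ep$data[, perm, , drop = FALSE]
  r1 <- invert_model(m, ep)$response[1:3, , 1:50]
  r2 <- invert_model(m2, ep2)$response[1:3, , 1:50]
  expect_equal(r1, r2)
})

test_that("noiseless single-stimulus epochs decode perfectly", {
  quiet <- simulate_localizer(fx$fm, n_blocks = 1, snr = Inf, seed = 5)
  resp <- invert_model(fx$model, quiet)$response
  tt <- epoch_times(quiet)
  win <- tt >= 0.14 & tt <= 0.17
  av <- apply(resp[, , win, drop = FALSE], c(1, 2), mean)
  pred <- c(0, 120, 240)[max.col(av)]
  expect_equal(mean(pred == quiet$meta$position), 1)
})

test_that("held-out decoding beats chance on noisy localizers", {
  held <- simulate_localizer(fx$fm, n_blocks = 1, snr = 1, seed = 19)
  resp <- invert_model(fx$model, held)$response
  tt <- epoch_times(held)
  av <- apply(resp[, , tt >= 0.14 & tt <= 0.17, drop = FALSE], c(1, 2), mean)
  pred <- c(0, 120, 240)[max.col(av)]
  expect_gt(mean(pred == held$meta$position), 0.5)  # chance = 1/3
})

test_that("training-epoch selection finds the planted latency", {
  wins <- lapply(seq(0.00, 0.30, by = 0.03), function(s) c(s, s + 0.03))
  sel <- select_training_epoch(fx$localizer, wins)
  # response is injected at 0.14-0.17 s
  expect_true(sel$training_window[2] > 0.14 && sel$training_window[1] < 0.17)
  # uniform held-out scores tie-break toward the earliest window
  sel2 <- sel
  sel2$scores[] <- 1
  starts <- vapply(wins, `[`, numeric(1), 1)
  best <- order(-sel2$scores, starts)[1]
  expect_equal(wins[[best]], wins[[1]])
  one_block <- simulate_localizer(fx$fm, n_blocks = 1, seed = 1)
  expect_error(select_training_epoch(one_block, wins), "2 blocks")
})

test_that("pure-noise localizers produce near-zero held-out scores", {
  # per-trial held-out decoding scores on a signal-free localizer are
  # statistically indistinguishable from zero
  noise <- simulate_localizer(fx$fm, n_blocks = 3, snr = 0.0001, seed = 21)
  train <- which(noise$meta$block != 3 & !noise$meta$flicker)
  test <- which(noise$meta$block == 3 & !noise$meta$flicker)
  obs <- t(apply(noise$data[, , epoch_times(noise) >= 0.14 &
                              epoch_times(noise) <= 0.17, drop = FALSE],
                 c(1, 2), mean))
  design <- build_design_matrix(noise$meta$position[train])
  fit <- fit_weights(obs[, train], design)
  G <- prewhiten_weights(fit$W, fit$residuals)$G
  resp <- crossprod(G, obs[, test])
  true_ch <- match(noise$meta$position[test], c(0, 120, 240))
  sc <- vapply(seq_along(test), function(i)
    resp[true_ch[i], i] - mean(resp[-true_ch[i], i]), numeric(1))
  expect_gt(t.test(sc)$p.value, 0.01)
})

test_that("saccade-contaminated trials are identified for exclusion", {
  sac <- data.frame(trial = c(3, 3, 7, 9), onset = c(0.05, 0.30, 0.19, 0.21))
  expect_equal(saccade_contaminated_trials(sac), c(3, 7))
  m <- train_encoding_model(fx$localizer, exclude_trials = c(3, 7))
  expect_equal(m$n_train, fx$model$n_train - 2)
})
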