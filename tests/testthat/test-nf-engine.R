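test_that("streamed coefficients equal a full batch refit at every volume", {
  set.seed(1)
  n_vol <- 40; n_vox <- 5
  X <- cbind(intercept = 1, trend = seq(0, 1, length.out = n_vol),
             meditation = rbinom(n_vol, 1, 0.4))
  Y <- matrix(rnorm(n_vol * n_vox, 1000, 5), n_vol, n_vox)
  st <- incremental_glm_init(n_vox, colnames(X))
  for (t in seq_len(n_vol)) {
    st <- update_incremental_glm(st, Y[t, ], X[t, ])
    if (t >= ncol(X) + 1 && qr(X[1:t, ])$rank == ncol(X)) {
      inc <- incremental_glm_coef(st)$beta
      batch <- qr.coef(qr(X[1:t, , drop = FALSE]),
                       Y[1:t, , drop = FALSE])
      expect_equal(unname(inc), unname(batch), tolerance = 1e-8)
    }
  }
  # and the slice-based constructor gives the identical state
  st2 <- glm_state_from_data(Y, X)
  expect_equal(incremental_glm_coef(st2)$beta,
               incremental_glm_coef(st)$beta, tolerance = 1e-12)
})

test_that("noiseless identifiable systems are recovered exactly and
           intercept-only designs give the running mean", {
  set.seed(2)
  X <- cbind(intercept = 1, trend = seq(0, 1, length.out = 20),
             meditation = rep(c(0, 1), 10))
  beta <- c(500, 30, -4)
  Y <- matrix(X %*% beta, ncol = 1)
  st <- glm_state_from_data(Y, X)
  expect_equal(unname(incremental_glm_coef(st)$beta[, 1]), beta)

  y <- rnorm(15, 10)
  st0 <- incremental_glm_init(1, "intercept")
  for (t in 1:15) {
    st0 <- update_incremental_glm(st0, y[t], 1)
    if (t >= 2) {
      expect_equal(unname(incremental_glm_coef(st0)$beta[1, 1]),
                   mean(y[1:t]))
    }
  }
})

test_that("non-finite volumes are rejected with a warning, leaving the
           state unchanged", {
  st <- incremental_glm_init(2, c("intercept", "meditation"))
  st <- update_incremental_glm(st, c(1, 2), c(1, 0))
  expect_warning(st2 <- update_incremental_glm(st, c(NA, 2), c(1, 1)),
                 "non-finite")
  expect_identical(st2$volumes_seen, st$volumes_seen)
  expect_identical(st2$XtX, st$XtX)
  expect_error(incremental_glm_coef(st), "underdetermined")
})

test_that("voxel selection takes max(1, floor(fraction * V)) most negative
           t, ties by id", {
  set.seed(3)
  n_vol <- 60
  X <- cbind(intercept = 1, trend = seq(0, 1, length.out = n_vol),
             meditation = rep(c(0, 1), n_vol / 2))
  mk_state <- function(n_vox) {
    Y <- matrix(rnorm(n_vol * n_vox, 100, 1), n_vol, n_vox)
    glm_state_from_data(Y, X)
  }
  expect_length(select_responsive_voxels(mk_state(300), nf_config()), 99)
  expect_length(select_responsive_voxels(mk_state(3), nf_config()), 1)
  expect_error(select_responsive_voxels(
    incremental_glm_init(3, colnames(X)), nf_config()), "underdetermined")
})

test_that("selection homes in on signal-carrying voxels at low noise", {
  overlaps <- vapply(seq_len(100), function(s) {
    truth <- quiet_truth(amp = -0.5, thermal = 0.05, seed = s)
    run <- simulate_roi_run(default_design, default_acq, truth,
                            n_target_voxels = 20)
    X <- build_design_matrix(run$design, default_acq$n_volumes,
                             default_acq$tr_seconds)
    st <- glm_state_from_data(t(run$target), X)
    sel <- select_responsive_voxels(st, nf_config())
    mean(sel %in% run$signal_voxels)
  }, numeric(1))
  expect_gte(mean(overlaps), 0.9)
})

test_that("block PSC is zero for flat data and exact for constant offsets", {
  n_vol <- default_acq$n_volumes
  X <- cbind(intercept = 1, trend = seq(0, 1, length.out = n_vol),
             meditation = condition_boxcar(default_design$events,
                                           "meditation", n_vol,
                                           default_acq$tr_seconds))
  B <- 1000
  blk <- default_design$events[default_design$events$trial_type ==
                                 "meditation", ][1, ]
  flat <- glm_state_from_data(matrix(B, n_vol, 3), X)
  expect_equal(compute_block_psc(flat, 1:3, blk, 0,
                                 default_acq$tr_seconds), 0)
  # uniformly 1% below baseline during the (unconvolved) meditation blocks
  y <- B * (1 - 0.01 * X[, "meditation"])
  st <- glm_state_from_data(matrix(y, ncol = 1), X)
  expect_equal(compute_block_psc(st, 1, blk, 0, default_acq$tr_seconds),
               -1.0, tolerance = 1e-10)
})

test_that("block PSC of an HRF-convolved deactivation matches the
           brute-force convolution oracle", {
  amp <- -0.5
  fx <- make_noiseless_state(amp, n_voxels = 1)
  box <- condition_boxcar(default_design$events, "meditation",
                          default_acq$n_volumes, default_acq$tr_seconds)
  conv_oracle <- brute_convolve(box, canonical_hrf(default_acq$tr_seconds))
  shift <- 4
  med <- default_design$events[default_design$events$trial_type ==
                                 "meditation", ]
  for (k in c(1, 4, 6)) {
    t0 <- (seq_len(default_acq$n_volumes) - 1) * default_acq$tr_seconds
    win <- which(t0 >= med$onset[k] + shift &
                   t0 < med$onset[k] + med$duration[k] + shift)
    expect_equal(compute_block_psc(fx$state, 1, med[k, ], shift,
                                   default_acq$tr_seconds),
                 amp * mean(conv_oracle[win]), tolerance = 1e-8)
  }
})

test_that("scores are intermittent: not computable before the shifted
           block window has elapsed", {
  fx <- make_noiseless_state(-0.5, n_voxels = 3)
  med <- default_design$events[default_design$events$trial_type ==
                                 "meditation", ]
  blk <- med[2, ]
  early <- glm_state_from_data(fx$Y, fx$X,
                               upto = floor(blk$onset /
                                              default_acq$tr_seconds))
  expect_error(compute_block_psc(early, 1, blk, 4,
                                 default_acq$tr_seconds), "intermittent")
})

test_that("a non-positive cumulative baseline raises a scoring error", {
  n_vol <- 30
  X <- cbind(intercept = 1, trend = seq(0, 1, length.out = n_vol),
             meditation = rep(c(0, 1), n_vol / 2))
  st <- glm_state_from_data(matrix(rnorm(n_vol, 0, 1), ncol = 1), X)
  expect_error(psc_series(st, 1), "degenerate")
})

test_that("confound residualization matches closed-form regression and is
           orthogonal to the confound", {
  set.seed(4)
  conf <- rnorm(200)
  target <- 0.7 * conf + rnorm(200, sd = 0.3)
  res <- residualize_against_confound(target, conf)
  expect_lt(abs(stats::cor(res, conf)), 1e-10)
  b <- stats::cov(target, conf) / stats::var(conf)
  a <- mean(target) - b * mean(conf)
  expect_equal(res, target - a - b * conf, tolerance = 1e-10)

  # perfect fit and orthogonal-covariate limits
  expect_equal(residualize_against_confound(2 * conf, conf),
               rep(0, 200), tolerance = 1e-10)
  x <- c(1, -1, 1, -1); z <- c(1, 1, -1, -1)     # exactly orthogonal
  expect_equal(residualize_against_confound(x + 5, z), x,
               tolerance = 1e-12)
  expect_warning(r0 <- residualize_against_confound(x, rep(1, 4)),
                 "constant confound")
  expect_equal(r0, x - mean(x))
})

test_that("slope recovery: fitted confound slope is unbiased across seeds", {
  slopes <- vapply(seq_len(100), function(s) {
    set.seed(s)
    conf <- rnorm(300)
    target <- 0.7 * conf + rnorm(300)
    stats::cov(target, conf) / stats::var(conf)
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.7), 0.02)
})

test_that("thermometer mapping is correct at the anchors and monotone", {
  cfg <- nf_config()
  expect_equal(map_to_thermometer(0, cfg), 1L)
  expect_equal(map_to_thermometer(0.4, cfg), 1L)
  expect_equal(map_to_thermometer(-1, cfg), 20L)
  expect_equal(map_to_thermometer(-3, cfg), 20L)
  expect_equal(map_to_thermometer(-0.5, cfg), 11L)
  grid <- seq(0.5, -1.5, by = -0.01)
  lv <- vapply(grid, map_to_thermometer, integer(1), config = cfg)
  expect_true(all(diff(lv) >= 0))   # more negative PSC, never lower level
  expect_true(all(lv >= 1 & lv <= 20))
})

test_that("a veridical session emits exactly 6 scores per run, 18 per
           session, in block order", {
  runs <- lapply(1:3, function(r)
    simulate_roi_run(default_design, default_acq, quiet_truth(seed = r)))
  log <- run_nf_session(runs, nf_config())
  expect_equal(nrow(log), 18)
  expect_equal(log$run, rep(1:3, each = 6))
  expect_equal(log$block, rep(1:6, 3))
  expect_equal(log$displayed_psc, log$residual_psc)
  expect_true(all(log$n_selected == floor(0.33 * 50)))
})

test_that("every score and level is invariant to rescaling all raw
           intensities", {
  run <- simulate_roi_run(default_design, default_acq, quiet_truth(seed = 6))
  scaled <- run
  scaled$target <- run$target * 3.7
  scaled$confound <- run$confound * 3.7
  a <- run_nf_session(list(run), nf_config())
  b <- run_nf_session(list(scaled), nf_config())
  expect_equal(a$raw_psc, b$raw_psc, tolerance = 1e-10)
  expect_equal(a$residual_psc, b$residual_psc, tolerance = 1e-10)
  expect_identical(a$level, b$level)
})

test_that("sham replay displays the donor's scores verbatim and checks the
           count", {
  donor_runs <- lapply(1:3, function(r)
    simulate_roi_run(default_design, default_acq, quiet_truth(seed = 10 + r)))
  donor_log <- run_nf_session(donor_runs, nf_config())
  recip_runs <- lapply(1:3, function(r)
    simulate_roi_run(default_design, default_acq, quiet_truth(seed = 20 + r)))
  sham <- sham_schedule("sub-exp001", donor_log, matching_key = 120)
  log <- run_nf_session(recip_runs, nf_config(mode = "sham"), sham)
  expect_identical(log$displayed_psc, donor_log$residual_psc)
  expect_identical(log$displayed_level, donor_log$level)
  # recipient's own scores still computed and differ from the display
  expect_false(isTRUE(all.equal(log$residual_psc, log$displayed_psc)))
  expect_error(run_nf_session(recip_runs[1:2], nf_config(mode = "sham"),
                              sham), "replay error")
  expect_error(run_nf_session(recip_runs, nf_config(mode = "sham")),
               "needs a sham_schedule")
})

test_that("sham donors are matched by nearest experience hours with id
           tie-break", {
  hours <- c(`sub-exp002` = 50, `sub-exp001` = 100, `sub-exp003` = 200)
  expect_equal(match_sham_donor(hours, 60), "sub-exp002")
  expect_equal(match_sham_donor(hours, 150), "sub-exp001")
  expect_equal(match_sham_donor(c(a = 10, b = 10), 10), "a")
})

test_that("session-mean NF scores track offline activation betas at high
           SNR", {
  stats <- t(vapply(seq_len(30), function(s) {
    amp <- stats::runif(1, -0.8, -0.1)
    truth <- nf_ground_truth(target_deactivation_pct = amp,
                             thermal_sd = 0.2, physio_sd = 0.1,
                             drift_amplitude = 0.1, seed = 100 + s)
    run <- simulate_roi_run(default_design, default_acq, truth,
                            n_target_voxels = 20)
    log <- run_nf_session(list(run), nf_config())
    fit <- fit_block_glm(run)
    c(online = mean(log$raw_psc),
      offline = mean(fit$contrast[run$signal_voxels]))
  }, numeric(2)))
  expect_gt(stats::cor(stats[, "online"], stats[, "offline"]), 0.5)
})
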