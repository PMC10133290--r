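calibration_night <- function() {
  get_fixture("calibration_night", function() {
    po <- tibble::tibble(label = "non-scratch movement",
                         start_s = seq(300, 4500, by = 420),
                         end_s = seq(305, 4505, by = 420),
                         hand = "left", freq_hz = NA_real_, amp_g = NA_real_,
                         kind = "posture")
    simulate_night(night_scenario(duration_h = 1.3, events = po, seed = 9))
  })
}

test_that("autocalibration undoes an injected gain/offset distortion", {
  rec <- calibration_night()$left
  g_inj <- c(1.05, 1, 1); o_inj <- c(0, 0.02, 0)
  pert <- rec
  pert$ax <- rec$ax * g_inj[1] + o_inj[1]
  pert$ay <- rec$ay * g_inj[2] + o_inj[2]
  pert$az <- rec$az * g_inj[3] + o_inj[3]
  cal <- autocalibrate(pert)
  expect_true(cal$params$converged)
  # the recovered parameters composed with the injection are the identity
  expect_lt(max(abs(cal$params$gain * g_inj - 1)), 0.01)
  expect_lt(max(abs(cal$params$gain * o_inj + cal$params$offset)), 0.01)
  vm <- sqrt(cal$recording$ax^2 + cal$recording$ay^2 + cal$recording$az^2)
  expect_lt(abs(mean(vm) - 1), 0.002)
})

test_that("already-calibrated input yields identity parameters", {
  cal <- autocalibrate(calibration_night()$left)
  expect_lt(max(abs(cal$params$gain - 1)), 0.005)
  expect_lt(max(abs(cal$params$offset)), 0.005)
})

test_that("single-orientation stationary data gives identity with a warning", {
  nt <- simulate_night(night_scenario(duration_h = 0.35, seed = 12))
  expect_warning(cal <- autocalibrate(nt$left), "orientation")
  expect_identical(cal$params$gain, c(1, 1, 1))
  expect_false(cal$params$converged)
})

test_that("resampling produces floor(duration * rate) samples by interpolation", {
  n <- 50 * 60
  rec <- as_recording(tibble::tibble(time_s = (seq_len(n) - 1) / 50,
                                     ax = sin((seq_len(n)) / 40), ay = 0.25,
                                     az = 1), 50, "left")
  out <- resample_recording(rec, 20)
  expect_equal(nrow(out), 1200)
  expect_equal(rec_rate(out), 20)
  expect_true(all(abs(out$ay - 0.25) < 1e-12))      # constant stays constant
  # identity when already uniform at the target rate
  rec20 <- as_recording(tibble::tibble(time_s = (0:1199) / 20, ax = 1, ay = 0,
                                       az = 0), 20, "left")
  out2 <- resample_recording(rec20, 20)
  expect_equal(nrow(out2), 1200)
  expect_equal(out2$ax, rec20$ax)
  expect_error(resample_recording(out, 50), class = "ns_error_rate")
})

test_that("accel-only gravity removal rejects DC and preserves the motion band", {
  n <- 20 * 120
  rec <- make_rec20(cbind(rep(0.3, n), rep(-0.4, n), rep(0.87, n)))
  lin <- remove_gravity_accel(rec)
  core <- 200:(n - 200)
  expect_lt(max(abs(as.matrix(lin[core, c("X", "Y", "Z")]))), 1e-6)
  # a 3 Hz unit tone passes with amplitude preserved within 2%
  tone <- sin(2 * pi * 3 * (seq_len(n) - 1) / 20)
  rec2 <- make_rec20(cbind(tone, rep(0, n), rep(1, n)))
  lin2 <- remove_gravity_accel(rec2)
  amp <- max(abs(lin2$X[core]))
  expect_lt(abs(amp - 1), 0.02)
  # too-short input is refused
  expect_error(remove_gravity_accel(make_rec20(matrix(1, 30, 3))),
               class = "ns_error_short")
})

test_that("the single-pass high-pass response at the cutoff is -3 dB", {
  bf <- signal::butter(1, 0.25 / 10, type = "high")
  w <- 2 * pi * 0.25 / 20
  H <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
    sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
  gain_db <- 20 * log10(Mod(H))
  expect_lt(abs(gain_db - (-3.0103)), 0.1)
})

test_that("fused gravity removal cancels gravity at any fixed orientation", {
  set.seed(31)
  g0 <- c(0.3, -0.5, 0.81); g0 <- g0 / sqrt(sum(g0^2))
  n <- 20 * 60
  noise <- 0.005
  rec <- make_rec20(cbind(g0[1] + rnorm(n, 0, noise),
                          g0[2] + rnorm(n, 0, noise),
                          g0[3] + rnorm(n, 0, noise)),
                    gyro = matrix(rnorm(3 * n, 0, 0.2), ncol = 3))
  fz <- remove_gravity_fused(rec)
  rms <- sqrt(mean(as.matrix(fz$linear[, c("X", "Y", "Z")])^2))
  expect_lt(rms, 2 * noise)
  expect_true(all(abs(sqrt(rowSums(fz$orientation^2)) - 1) < 1e-6))
})

test_that("constant-rate rotation integrates to the closed-form orientation", {
  n <- 20 * 60
  w_dps <- 30
  rec <- make_rec20(cbind(rep(0, n), rep(0, n), rep(1, n)),
                    gyro = cbind(rep(0, n), rep(0, n), rep(w_dps, n)))
  fz <- remove_gravity_fused(rec, stationary = rep(FALSE, n), alpha = 0)
  th_true <- (w_dps * pi / 180) * (n - 1) / 20
  q_true <- c(cos(th_true / 2), 0, 0, sin(th_true / 2))
  ang_err <- 2 * acos(pmin(1, abs(sum(fz$orientation[n, ] * q_true))))
  expect_lt(ang_err * 180 / pi, 0.5)
})

test_that("stationary fusion mitigates gyro bias drift", {
  set.seed(33)
  n <- 20 * 60
  acc <- cbind(rnorm(n, 0, 0.003), rnorm(n, 0, 0.003), 1 + rnorm(n, 0, 0.003))
  gyro <- cbind(rep(0.5, n), rep(0, n), rep(0, n))   # 0.5 deg/s bias
  rec <- make_rec20(acc, gyro = gyro)
  e_on <- sqrt(mean(tail(as.matrix(
    remove_gravity_fused(rec, stationary = rep(TRUE, n))$linear[, 2:4]), 20)^2))
  e_off <- sqrt(mean(tail(as.matrix(
    remove_gravity_fused(rec, stationary = rep(TRUE, n),
                         alpha = 0)$linear[, 2:4]), 20)^2))
  expect_lt(e_on, e_off)
  expect_lt(e_on, 0.05)
})

test_that("fused and accel-only agree on motion at or above 1 Hz", {
  n <- 20 * 120
  tone <- 0.4 * sin(2 * pi * 3 * (seq_len(n) - 1) / 20)
  rec <- make_rec20(cbind(tone, rep(0, n), rep(1, n)),
                    gyro = matrix(0, n, 3))
  la <- remove_gravity_accel(rec)
  lf <- remove_gravity_fused(rec, stationary = rep(FALSE, n), alpha = 0)$linear
  core <- 400:(n - 400)
  d <- as.matrix(la[core, 2:4]) - as.matrix(lf[core, 2:4])
  rel <- sqrt(mean(d^2)) / sqrt(mean(as.matrix(lf[core, 2:4])^2))
  expect_lt(rel, 0.05)
})

test_that("missing gyro routes callers to the accel-only path", {
  rec <- make_rec20(matrix(rep(c(0, 0, 1), each = 100), ncol = 3))
  expect_error(remove_gravity_fused(rec), class = "ns_error_schema")
})

test_that("channel derivation: norms, rotation invariance, derivatives, ordering", {
  m345 <- matrix(rep(c(3, 4, 0), each = 80), ncol = 3)
  ch <- derive_channels(m345, 20)
  expect_true(all(ch$VM == 5))
  expect_true(all(abs(ch$dX) < 1e-12))
  set.seed(41)
  m <- matrix(rnorm(180), 60, 3)
  ch0 <- derive_channels(m, 20)
  for (i in 1:5) {
    R <- random_rotation()
    chr <- derive_channels(m %*% t(R), 20)
    expect_equal(chr$VM, ch0$VM, tolerance = 1e-12)
    expect_lt(max(abs(abs(chr$PC1) - abs(ch0$PC1))), 1e-8)
  }
  # energy ordering in every tile of a long random series
  set.seed(42)
  big <- derive_channels(matrix(rnorm(3 * 600), ncol = 3), 20)
  for (s in seq(1, 600, by = 60)) {
    idx <- s:(s + 59)
    expect_gte(stats::var(big$PC1[idx]) + 1e-12, stats::var(big$PC2[idx]))
  }
  # zero-variance window projects to zero
  chz <- derive_channels(matrix(1, 60, 3), 20)
  expect_true(all(chz$PC1 == 0) && all(chz$PC2 == 0))
})
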