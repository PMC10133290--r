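test_that("a stationary night contains no movement seconds", {
  nt <- quiet_night()
  mv <- detect_movement(resample_recording(nt$left, 20))
  expect_equal(attr(mv, "fraction_movement"), 0)
})

test_that("a planted 3 Hz, 0.5 g bout is flagged within one second", {
  nt <- bout_night()
  mv <- detect_movement(resample_recording(nt$left, 20))
  flagged <- mv$second[mv$movement]
  expect_true(all(100:109 %in% flagged))        # the bout itself
  expect_true(all(flagged >= 99 & flagged <= 110))  # +/- 1 s boundary only
})

test_that("raising either threshold never enlarges the movement set", {
  nt <- bout_night()
  rec20 <- resample_recording(nt$left, 20)
  base <- detect_movement(rec20, 0.41, 0.013)
  for (th in list(c(0.8, 0.013), c(0.41, 0.03), c(2, 0.05))) {
    m <- detect_movement(rec20, th[1], th[2])
    expect_true(all(which(m$movement) %in% which(base$movement)))
  }
  expect_error(detect_movement(rec20, -1, 0.013),
               class = "ns_error_threshold")
})

test_that("threshold fitting returns pooled quantiles with sane edges", {
  nt <- bout_night()
  rec20 <- resample_recording(nt$left, 20)
  fit <- fit_movement_thresholds(rec20, 0.08)
  expect_true(fit$theta_cov > 0 && fit$theta_sd > 0)
  st <- nightscratch:::movement_statistics(rec20)
  lo <- fit_movement_thresholds(rec20, quantile = 1e-9)
  expect_equal(lo$theta_sd, min(st$max_sd), tolerance = 1e-6)
  # quantile 1 -> thresholds at the maxima -> downstream all-non-movement
  hi <- fit_movement_thresholds(rec20, 0.999999)
  m <- detect_movement(rec20, hi$theta_cov + 1e-9, hi$theta_sd + 1e-9)
  expect_equal(sum(m$movement), 0)
  expect_error(fit_movement_thresholds(rec20, 1.5),
               class = "ns_error_threshold")
})

test_that("the non-wear rule needs cold and still for more than 10 minutes", {
  mk_mask <- function(mov) {
    structure(tibble::tibble(second = seq_along(mov) - 1L, movement = mov),
              rate_hz = 20)
  }
  still <- mk_mask(rep(FALSE, 1200))
  nw <- detect_nonwear(still, rep(24, 1200))      # 20 min at 24 C
  expect_equal(nrow(nw), 1)
  expect_gt(nw$end_s - nw$start_s, 600)
  nw9 <- detect_nonwear(mk_mask(rep(FALSE, 540)), rep(24, 540))  # 9 min
  expect_equal(nrow(nw9), 0)
  warm <- detect_nonwear(still, rep(32, 1200))    # worn all night
  expect_equal(nrow(warm), 0)
  # exactly 15 min at 24 C inside a warm night
  temp <- c(rep(32, 200), rep(24, 900), rep(32, 100))
  nw15 <- detect_nonwear(mk_mask(rep(FALSE, 1200)), temp)
  expect_equal(nrow(nw15), 1)
  expect_equal(nw15$start_s, 200)
  expect_equal(nw15$end_s, 1100)
})

test_that("simulated non-wear is detected from stillness plus temperature", {
  nw_true <- tibble::tibble(start_s = 200, end_s = 1500, hand = "left")
  nt <- simulate_night(night_scenario(duration_h = 0.5, nonwear = nw_true,
                                      seed = 14))
  rec20 <- resample_recording(nt$left, 20)
  nw <- detect_nonwear(detect_movement(rec20), rec20)
  expect_equal(nrow(nw), 1)
  # detected interval sits inside the planted one (temperature needs a few
  # minutes to cross the threshold after removal)
  expect_gte(nw$start_s, 200)
  expect_lte(nw$start_s, 200 + 360)
  expect_gte(nw$end_s, 1400)
})

test_that("the movement-filter report computes loss and prevalence by count", {
  # 10-s toy: 8 s annotated scratch, mask covers 8 s but misses 2 scratch s
  mask <- tibble::tibble(second = 0:9,
                         movement = c(FALSE, FALSE, rep(TRUE, 8)))
  ann <- as_annotations(tibble::tibble(start_s = 0, end_s = 8,
                                       label = "scratch", hand = "left"))
  rep <- movement_filter_report(mask, ann, "left")
  expect_equal(rep$pct_scratch_lost, 25)          # 2 of 8 s outside the mask
  expect_equal(rep$scratch_prevalence_pct, 100 * 6 / 8)
  # perfect mask -> zero loss; all-false mask -> total loss
  all_mov <- tibble::tibble(second = 0:9, movement = rep(TRUE, 10))
  expect_equal(movement_filter_report(all_mov, ann, "left")$pct_scratch_lost, 0)
  none <- tibble::tibble(second = 0:9, movement = rep(FALSE, 10))
  expect_equal(movement_filter_report(none, ann, "left")$pct_scratch_lost, 100)
  # no scratch annotated -> undefined
  quiet <- as_annotations(tibble::tibble(start_s = 0, end_s = 10,
                                         label = "in-bed still",
                                         hand = "left"))
  expect_true(is.na(movement_filter_report(all_mov, quiet,
                                           "left")$pct_scratch_lost))
})

test_that("finger-scratch-heavy nights lose more scratch than hand-scratch nights", {
  mk <- function(amp_lo, amp_hi, seed) {
    ev <- tibble::tibble(label = "scratch",
                         start_s = c(60, 180, 300), end_s = c(80, 200, 320),
                         hand = "left", freq_hz = 3.5,
                         amp_g = stats::runif(3, amp_lo, amp_hi),
                         kind = NA_character_)
    simulate_night(night_scenario(duration_h = 0.12, events = ev, seed = seed))
  }
  set.seed(77)
  hand <- mk(0.3, 1.0, 15)
  fing <- mk(0.015, 0.03, 16)
  lost <- function(nt) {
    rec20 <- resample_recording(nt$left, 20)
    movement_filter_report(detect_movement(rec20), nt$annotations,
                           "left")$pct_scratch_lost
  }
  expect_lt(lost(hand), lost(fing))
})
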