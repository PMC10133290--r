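fake_pred <- function(n_pos, n_neg, tso_h = 8, domfreq = 3) {
  n <- n_pos + n_neg
  structure(list(
    pooled = tibble::tibble(start_s = 3 * (seq_len(n) - 1),
                            prob = c(rep(0.9, n_pos), rep(0.1, n_neg)),
                            call = c(rep(TRUE, n_pos), rep(FALSE, n_neg)),
                            domfreq_hz = domfreq),
    per_hand = list(), tso = tso_from_reference(c(0, tso_h * 3600)),
    nonwear = list()), class = "ns_night_pred")
}

test_that("endpoints follow the 3-s tiling arithmetic", {
  # 96 scratch seconds in an 8-h TSO -> 12 s/h
  ep <- compute_endpoints(fake_pred(32, 10))
  expect_equal(ep$total_scratch_s, 96)
  expect_equal(ep$hourly_scratch_s_per_h, 12)
  expect_equal(ep$intensity_hz, 3)
  none <- compute_endpoints(fake_pred(0, 10))
  expect_equal(none$total_scratch_s, 0)
  expect_true(is.na(none$intensity_hz))
})

test_that("a quiet night deploys to zero scratch windows", {
  mdl <- mini_model()
  pr <- predict_night(mdl, quiet_night())
  expect_equal(sum(pr$pooled$call), 0)
  ep <- compute_endpoints(pr)
  expect_equal(ep$total_scratch_s, 0)
  expect_true(is.na(ep$intensity_hz))
})

test_that("deployment recovers planted hand scratches per night", {
  coh <- mini_cohort()
  mdl <- mini_model()
  derived <- vapply(seq_len(nrow(coh)), function(i) {
    compute_endpoints(predict_night(mdl, coh$night_data[[i]]))$total_scratch_s
  }, numeric(1))
  planted <- coh$planted_scratch_s
  # pooled across the small cohort the tiling recovers >= 90% of scratch time
  expect_gt(sum(pmin(derived, planted)) / sum(planted), 0.9)
  expect_lt(abs(sum(derived) - sum(planted)) / sum(planted), 0.2)
})

test_that("single-hand nights produce endpoints from that hand alone", {
  coh <- mini_cohort()
  mdl <- mini_model()
  nd <- coh$night_data[[1]]
  both <- predict_night(mdl, nd)
  left_only <- predict_night(mdl, list(left = nd$left,
                                       true_tso = nd$true_tso))
  expect_equal(names(left_only$per_hand), "left")
  expect_equal(sum(left_only$pooled$call), sum(both$per_hand$left$call))
})

test_that("pooling conserves seconds across hours", {
  pr <- fake_pred(40, 60)
  ep <- compute_endpoints(pr)
  pos <- pr$pooled[pr$pooled$call, ]
  hours <- floor(pos$start_s / 3600)
  expect_equal(sum(3 * table(hours)), ep$total_scratch_s)
  expect_true(all(diff(pr$pooled$start_s) >= 3))   # non-overlapping tiles
})

test_that("Bland-Altman matches its closed forms", {
  x <- c(2, 4, 6, 9)
  expect_equal(unlist(bland_altman(x, x)[, c("mean_diff", "lower", "upper")],
                      use.names = FALSE), c(0, 0, 0))
  k <- 3.5
  ba <- bland_altman(x + k, x)
  expect_equal(c(ba$mean_diff, ba$lower, ba$upper), c(k, k, k))
  ba2 <- bland_altman(c(1, -1), c(0, 0))
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$upper, 1.96 * sqrt(2))
  expect_equal(ba2$lower, -1.96 * sqrt(2))
  expect_error(bland_altman(1:3, 1:4), class = "ns_error_schema")
})

test_that("one-way ICC matches an ANOVA oracle and behaves at the extremes", {
  # 3 subjects x 2 nights, hand-checkable
  v <- c(10, 12, 20, 22, 30, 31)
  s <- rep(c("a", "b", "c"), each = 2)
  got <- icc_oneway(v, s)
  aov_fit <- stats::aov(v ~ factor(s))
  ms <- summary(aov_fit)[[1]]$`Mean Sq`
  k <- 2
  expect_equal(got$msb, ms[1])
  expect_equal(got$msw, ms[2])
  expect_equal(got$icc, (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2]))
  # within-subject constant, between-subject varying -> 1
  expect_equal(icc_oneway(rep(c(1, 5, 9), each = 3),
                          rep(c("a", "b", "c"), each = 3))$icc, 1)
  # i.i.d. noise, 50 subjects x 5 nights -> near zero on average
  set.seed(71)
  null_icc <- replicate(30, icc_oneway(rnorm(250), rep(1:50, each = 5))$icc)
  expect_lt(abs(mean(null_icc)), 0.05)
  expect_lt(stats::quantile(abs(null_icc), 0.9), 0.12)
  # shift invariance
  expect_equal(icc_oneway(v + 100, s)$icc, got$icc)
  # singleton subjects are excluded with a warning
  expect_warning(icc_oneway(c(v, 50), c(s, "d")), "excluded")
})

test_that("PRO correlations behave on exact, null and planted relations", {
  set.seed(72)
  ep <- tibble::tibble(subject = rep(sprintf("S%02d", 1:12), each = 8),
                       night = rep(1:8, 12),
                       hourly_scratch_s_per_h = rlnorm(96, 2, 0.6))
  # endpoint proportional to the PRO -> r = 1
  pro_exact <- tibble::tibble(subject = ep$subject, night = ep$night,
                              ADSS2 = ep$hourly_scratch_s_per_h * 0.3,
                              SCORAD = NA_real_)
  pro_exact$SCORAD <- stats::ave(ep$hourly_scratch_s_per_h, ep$subject) * 2
  r <- correlate_with_pro(ep, pro_exact)
  expect_equal(r$r[r$pro == "ADSS2" & r$method == "pearson"], 1)
  expect_equal(r$r[r$pro == "SCORAD" & r$method == "pearson"], 1,
               tolerance = 1e-12)
  # independent PRO -> small correlation at n = 96
  pro_null <- tibble::tibble(subject = ep$subject, night = ep$night,
                             ADSS2 = sample(0:15, 96, replace = TRUE))
  rn <- correlate_with_pro(ep, pro_null)
  expect_lt(abs(rn$r[rn$pro == "ADSS2" & rn$method == "pearson"]), 0.35)
  # severity driving both the endpoint and the PRO -> clear correlation
  sev <- rep(rlnorm(12, 1, 0.7), each = 8)
  ep2 <- ep
  ep2$hourly_scratch_s_per_h <- sev * 10 + rlnorm(96, 0, 0.4)
  pro2 <- tibble::tibble(subject = ep$subject, night = ep$night,
                         ADSS2 = sev + rnorm(96, 0, 0.5))
  r2 <- correlate_with_pro(ep2, pro2)
  expect_gt(r2$r[r2$pro == "ADSS2" & r2$method == "spearman"], 0.5)
  # too few pairs -> NA
  tiny <- correlate_with_pro(ep[1:2, ], pro_exact[1:2, ])
  expect_true(all(is.na(tiny$r[tiny$pro == "ADSS2"])))
})
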