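test_that("a 60-s movement run yields 39 half-overlapping training windows", {
  n <- 20 * 60
  mask <- structure(tibble::tibble(second = 0:59, movement = rep(TRUE, 60)),
                    rate_hz = 20)
  lin <- tibble::tibble(time_s = (seq_len(n) - 1) / 20,
                        X = rnorm(n, 0, 0.1), Y = rnorm(n, 0, 0.1),
                        Z = rnorm(n, 0, 0.1))
  w <- segment_windows(mask, lin, hand = "left", mode = "train")
  expect_equal(nrow(w), 39)                       # floor((60 - 3) / 1.5) + 1
  expect_equal(diff(w$start_s)[1], 1.5)
  expect_true(all(vapply(w$accel, nrow, 1L) == 60))
  # deployment tiles the same run without overlap
  d <- segment_windows(mask, lin, hand = "left", mode = "deploy",
                       tso = tso_from_reference(c(0, 60)))
  expect_equal(nrow(d), 20)
  expect_equal(unique(diff(d$start_s)), 3)
})

test_that("window labels follow the strict more-than-1-s scratch rule", {
  n <- 20 * 30
  mask <- structure(tibble::tibble(second = 0:29, movement = rep(TRUE, 30)),
                    rate_hz = 20)
  lin <- tibble::tibble(time_s = (seq_len(n) - 1) / 20, X = 0, Y = 0, Z = 0)
  ann <- as_annotations(tibble::tibble(
    label = "scratch", hand = "left",
    start_s = c(0, 10.5), end_s = c(1.6, 11.5)))   # 1.6 s and exactly 1.0 s
  w <- segment_windows(mask, lin, annotations = ann, hand = "left")
  w0 <- w[w$start_s == 0, ]
  expect_equal(w0$label, "scratch")               # 1.6 s > 1 s
  w1 <- w[w$start_s == 9, ]
  expect_equal(w1$scratch_s, 1.0, tolerance = 1e-9)
  expect_equal(w1$label, "non-scratch")           # exactly 1.0 s is not enough
  # round trip: windows fully inside a scratch event are labeled scratch
  ann2 <- as_annotations(tibble::tibble(label = "scratch", hand = "left",
                                        start_s = 18, end_s = 27))
  w2 <- segment_windows(mask, lin, annotations = ann2, hand = "left")
  inside <- w2$start_s >= 18 & w2$start_s + 3 <= 27
  expect_true(all(w2$label[inside] == "scratch"))
  outside <- w2$start_s + 3 <= 17 | w2$start_s >= 28
  expect_true(all(w2$label[outside] == "non-scratch"))
})

test_that("windows with under one second of movement are dropped", {
  mask <- structure(tibble::tibble(second = 0:29,
                                   movement = c(rep(FALSE, 10), rep(TRUE, 2),
                                                rep(FALSE, 18))),
                    rate_hz = 20)
  n <- 20 * 30
  lin <- tibble::tibble(time_s = (seq_len(n) - 1) / 20, X = 0, Y = 0, Z = 0)
  w <- segment_windows(mask, lin, hand = "left")
  expect_true(all(w$movement_s >= 1))
  expect_true(all(w$start_s >= 7.5 & w$start_s <= 12))
  expect_true(all(w$edge))
})

test_that("the persistence diagram matches the examples and conventions", {
  pd <- persistence_diagram(c(0, 2, 1, 3))
  expect_equal(sorted_pairs(as.data.frame(pd)),
               data.frame(birth = c(0, 1), death = c(3, 2),
                          essential = c(TRUE, FALSE)))
  mono <- persistence_diagram(c(1, 2, 3, 7))
  expect_equal(nrow(mono), 1)
  expect_equal(c(mono$birth, mono$death), c(1, 7))
  const <- persistence_diagram(rep(4.2, 10))
  expect_equal(c(const$birth, const$death), c(4.2, 4.2))
  single <- persistence_diagram(3)
  expect_true(single$essential)
  expect_error(persistence_diagram(c(1, NA)), class = "ns_error_pd")
})

test_that("the sweep agrees with the level-set oracle, ties included", {
  set.seed(60)
  for (i in 1:60) {
    x <- rnorm(60)
    expect_equal(sorted_pairs(as.data.frame(persistence_diagram(x))),
                 sorted_pairs(oracle_pd(x)))
  }
  # plateaus and ties
  for (i in 1:40) {
    x <- sample(0:4, 30, replace = TRUE)
    expect_equal(sorted_pairs(as.data.frame(persistence_diagram(x))),
                 sorted_pairs(oracle_pd(x)))
  }
})

test_that("finite lifespans sum to half the total variation for closed series", {
  set.seed(61)
  for (i in 1:8) {
    x <- c(0, abs(cumsum(rnorm(40))) + 0.1, 0)
    pd <- persistence_diagram(x)
    fin <- pd[!pd$essential, ]
    expect_equal(sum(fin$death - fin$birth), sum(abs(diff(x))) / 2,
                 tolerance = 1e-12)
  }
})

test_that("persistence statistics follow the declared guards", {
  one <- tibble::tibble(birth = 0, death = 2)
  ps <- persistence_statistics(one)
  expect_equal(unname(ps[c("life_mean", "life_sd", "life_skew", "life_kurt",
                           "life_entropy")]), c(2, 0, 0, 0, 0))
  expect_equal(unname(ps[c("mid_mean", "mid_sd", "mid_skew", "mid_kurt",
                           "mid_entropy")]), c(1, 0, 0, 0, 0))
  empty <- tibble::tibble(birth = numeric(), death = numeric())
  expect_equal(unname(persistence_statistics(empty)), rep(0, 10))
  dup <- tibble::tibble(birth = c(0, 0), death = c(2, 2))
  pd2 <- persistence_statistics(dup)
  expect_equal(pd2[["life_mean"]], ps[["life_mean"]])
  expect_equal(pd2[["life_sd"]], 0)
})

test_that("the Gaussian persistence curve norm matches its closed form", {
  expect_equal(gaussian_persistence_curve_norm(
    tibble::tibble(birth = numeric(), death = numeric())), 0)
  one <- tibble::tibble(birth = 0, death = 2)
  # single kernel: ||l * N(m, s)||_2 = l / sqrt(2 s sqrt(pi)), l = 2, s = 1
  expect_equal(gaussian_persistence_curve_norm(one), sqrt(2 / sqrt(pi)),
               tolerance = 1e-3)
  # doubling lifespans strictly increases the norm
  set.seed(62)
  pd <- persistence_diagram(rnorm(60))
  doubled <- tibble::tibble(birth = pd$birth - (pd$death - pd$birth) / 2,
                            death = pd$death + (pd$death - pd$birth) / 2)
  expect_gt(gaussian_persistence_curve_norm(doubled),
            gaussian_persistence_curve_norm(pd))
  # zero-lifespan-only diagrams give zero
  flat <- tibble::tibble(birth = c(1, 2), death = c(1, 2))
  expect_equal(gaussian_persistence_curve_norm(flat), 0)
})

test_that("per-channel features behave on tones, constants and noise", {
  tone <- sin(2 * pi * 3 * (0:59) / 20)
  f <- channel_features(tone, 20)
  expect_lt(abs(f[["domfreq"]] - 3), 20 / 60)     # FFT bin width
  expect_gt(f[["dompower"]], 0)
  const <- channel_features(rep(2.5, 60), 20)
  expect_equal(const[["mean"]], 2.5)
  expect_equal(unname(const[c("sd", "zcr", "domfreq", "spec_entropy")]),
               c(0, 0, 0, 0))
  # white noise: periodogram bins are ~ iid Exponential, so the expected
  # spectral entropy is log(n_bins) - (1 - gamma), just under the flat cap
  set.seed(63)
  ent <- replicate(40, channel_features(rnorm(60), 20)[["spec_entropy"]])
  expect_equal(mean(ent), log(30) - (1 - 0.5772157), tolerance = 0.03)
  expect_gt(mean(ent), 0.85 * log(30))
  expect_equal(length(channel_features(tone, 20)), 27)
  expect_equal(length(tda_features(tone)), 11)
})

test_that("the assembled matrix has the frozen catalog widths", {
  w <- mini_windows()[1:12, ]
  attr(w, "rate_hz") <- 20
  class(w) <- class(mini_windows())
  f <- assemble_features(w, "accel")
  expect_equal(length(attr(f, "feature_cols")), 338)
  expect_equal(length(feature_catalog("accel")), 338)
  expect_equal(length(feature_catalog("both")), 676)
  expect_false(anyNA(as.matrix(f[, attr(f, "feature_cols")])))
  expect_false(any(duplicated(feature_catalog("both"))))
  wb <- mini_windows_both()[1:8, ]
  attr(wb, "rate_hz") <- 20
  class(wb) <- class(mini_windows_both())
  fb <- assemble_features(wb, "both")
  expect_equal(length(attr(fb, "feature_cols")), 676)
})

test_that("feature extraction is deterministic", {
  sl <- sample_window()
  expect_identical(window_features(sl, rate_hz = 20),
                   window_features(sl, rate_hz = 20))
})
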