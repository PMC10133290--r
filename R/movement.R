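#' Per-sample and per-second movement statistics
#'
#' Implements the pre-classifier movement filter's two statistics on a 20 Hz
#' calibrated recording: the vector magnitude is low-passed (6th-order
#' Butterworth, 3 Hz) to remove noise and high-passed (1st-order, 0.25 Hz) to
#' remove the gravity constant; the rolling coefficient of variation over a
#' sliding 1-s window is `rolling SD / max(|rolling mean|, eps)` of the
#' band-passed VM (one value per sample), and the second statistic is the
#' maximum per-axis SD of the band-passed axes within each non-overlapping
#' 1-s block. Computing the CoV on the band-passed series makes it a
#' scale-free burst detector (huge during oscillatory motion because the
#' rolling mean of a mean-free series is near zero) while the per-axis SD
#' criterion rejects quiet noise.
#'
#' @param recording A 20 Hz calibrated `ns_recording` (gravity retained).
#' @return List: `cov` (per sample), `max_sd` (per second), `n_sec`, `rate`.
#' @keywords internal
movement_statistics <- function(recording) {
  rate <- rec_rate(recording)
  acc <- as.matrix(recording[, c("ax", "ay", "az")])
  vm <- vm3(acc)
  lp <- signal::butter(6, 3 / (rate / 2), type = "low")
  hp <- butter_hp(0.25, rate)
  pad <- round(30 * rate)
  vm_lp <- zp_filter(lp, vm, pad)
  vm_bp <- zp_filter(hp, vm_lp, pad)
  ax_bp <- sapply(1:3, function(j) {
    zp_filter(hp, zp_filter(lp, acc[, j], pad), pad)
  })
  w <- round(rate)
  cov <- roll_sd(vm_bp, w) / pmax(abs(roll_mean(vm_bp, w)), 1e-12)
  n_sec <- floor(nrow(acc) / rate)
  sec <- rep(seq_len(n_sec), each = rate)
  idx <- seq_along(sec)
  sds <- sapply(1:3, function(j) tapply(ax_bp[idx, j], sec, stats::sd))
  max_sd <- apply(matrix(sds, ncol = 3), 1, max)
  list(cov = cov, max_sd = max_sd, n_sec = n_sec, rate = rate)
}

#' Detect hand movement from a 20 Hz recording
#'
#' A second (non-overlapping `[k, k+1)` tiling) is flagged as movement iff
#' strictly more than half of its per-sample CoV values exceed `theta_cov`
#' and its maximum per-axis band-passed SD exceeds `theta_sd`. The default
#' thresholds are the deployed values (chosen as 8% quantiles over a full
#' study dataset); [fit_movement_thresholds()] refits them on new data.
#'
#' @param recording A 20 Hz calibrated `ns_recording`.
#' @param theta_cov CoV threshold (> 0), default 0.41.
#' @param theta_sd Max-axis-SD threshold in g (> 0), default 0.013.
#' @return A `ns_movement` tibble: `second` (0-based start), `movement`,
#'   `cov_exceed_n`, `max_sd`; attributes `theta_cov`, `theta_sd`,
#'   `fraction_movement`, `rate_hz`.
#' @export
detect_movement <- function(recording, theta_cov = 0.41, theta_sd = 0.013) {
  if (theta_cov <= 0 || theta_sd <= 0) {
    ns_abort("movement thresholds must be positive", "ns_error_threshold")
  }
  st <- movement_statistics(recording)
  rate <- st$rate
  sec <- rep(seq_len(st$n_sec), each = rate)
  idx <- seq_along(sec)
  exceed <- tapply(!is.na(st$cov[idx]) & st$cov[idx] > theta_cov, sec, sum)
  mov <- as.numeric(exceed) > rate / 2 & st$max_sd > theta_sd
  out <- tibble::tibble(second = seq_len(st$n_sec) - 1L,
                        movement = as.logical(mov),
                        cov_exceed_n = as.integer(exceed),
                        max_sd = as.numeric(st$max_sd))
  structure(out, class = c("ns_movement", class(tibble::tibble())),
            theta_cov = theta_cov, theta_sd = theta_sd,
            fraction_movement = mean(mov), rate_hz = rate)
}

#' Fit movement thresholds as dataset quantiles
#'
#' Returns the stated quantile of the pooled per-sample CoV distribution and
#' of the pooled per-second max-axis-SD distribution over one or more nights.
#'
#' @param recordings A `ns_recording` or list of them (20 Hz, calibrated).
#' @param quantile Quantile in (0, 1); default 0.08.
#' @return Named list `theta_cov`, `theta_sd`.
#' @export
fit_movement_thresholds <- function(recordings, quantile = 0.08) {
  if (quantile <= 0 || quantile >= 1) {
    ns_abort("quantile must be inside (0, 1)", "ns_error_threshold")
  }
  if (inherits(recordings, "ns_recording")) recordings <- list(recordings)
  st <- lapply(recordings, movement_statistics)
  covs <- unlist(lapply(st, function(s) s$cov))
  sds <- unlist(lapply(st, function(s) s$max_sd))
  list(theta_cov = as.numeric(stats::quantile(covs, quantile, na.rm = TRUE)),
       theta_sd = as.numeric(stats::quantile(sds, quantile, na.rm = TRUE)))
}

#' Detect non-wear periods from stillness plus temperature
#'
#' Within maximal non-movement runs, contiguous stretches whose device
#' temperature stays below `temp_threshold_c` for more than `min_duration_min`
#' minutes are flagged as non-wear.
#'
#' @param movement A `ns_movement` mask.
#' @param recording The matching recording (for `temp_c`), or a numeric
#'   per-second temperature vector.
#' @param temp_threshold_c Threshold, default 25 C.
#' @param min_duration_min Minimum duration, default 10 min (strictly more).
#' @return A `ns_nonwear` tibble of half-open intervals `start_s`, `end_s`.
#' @export
detect_nonwear <- function(movement, recording, temp_threshold_c = 25,
                           min_duration_min = 10) {
  n_sec <- nrow(movement)
  if (is.numeric(recording)) {
    temp <- recording
  } else if ("temp_c" %in% names(recording)) {
    rate <- rec_rate(recording)
    sec <- rep(seq_len(n_sec), each = rate)
    idx <- seq_along(sec)
    temp <- as.numeric(tapply(recording$temp_c[idx], sec, mean))
  } else {
    warning("no temperature channel: returning empty non-wear mask", call. = FALSE)
    return(structure(tibble::tibble(start_s = numeric(), end_s = numeric()),
                     class = c("ns_nonwear", class(tibble::tibble()))))
  }
  temp <- rep_len(temp, n_sec)
  cold_still <- !movement$movement & temp < temp_threshold_c
  iv <- runs_from_flags(cold_still)
  iv <- iv[iv$end_s - iv$start_s > min_duration_min * 60, , drop = FALSE]
  structure(iv, class = c("ns_nonwear", class(tibble::tibble())),
            temp_threshold_c = temp_threshold_c,
            min_duration_min = min_duration_min)
}

#' Report what the movement filter does to annotated scratch
#'
#' Computes the percentage of annotated scratch seconds that fall in
#' non-movement (scratch wrongly excluded before classification) and the
#' prevalence of scratch among movement seconds.
#'
#' @param movement A `ns_movement` mask.
#' @param annotations A `ns_annotations` track (times relative to the same
#'   recording start).
#' @param hand Which hand's annotations to evaluate against.
#' @return Tibble: `pct_scratch_lost`, `scratch_prevalence_pct`,
#'   `scratch_s_total`, `movement_s`. Percentages are `NA` when undefined
#'   (no scratch annotated / no movement).
#' @export
movement_filter_report <- function(movement, annotations, hand = "left") {
  ann <- dplyr::filter(tibble::as_tibble(annotations),
                       .data$hand == !!hand, .data$label == "scratch")
  secs <- movement$second
  scr <- vapply(secs, function(k) overlap_s(k, k + 1, ann$start_s, ann$end_s),
                numeric(1))
  total <- sum(scr)
  lost <- if (total <= 0) NA_real_ else 100 * sum(scr[!movement$movement]) / total
  mov_s <- sum(movement$movement)
  prev <- if (mov_s == 0) NA_real_ else 100 * sum(scr[movement$movement]) / mov_s
  tibble::tibble(pct_scratch_lost = lost, scratch_prevalence_pct = prev,
                 scratch_s_total = total, movement_s = mov_s)
}
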