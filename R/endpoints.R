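# Dominant frequency of a window's vector magnitude. Computed on the
# gravity-retained signal: with gravity present the oscillation enters the
# norm linearly (VM ~ 1 + a_parallel sin), whereas the norm of gravity-free
# linear acceleration rectifies the oscillation and doubles its frequency.
window_domfreq <- function(slice, rate) {
  x <- vm3(as.matrix(slice))
  x <- x - mean(x)
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  sp <- abs(stats::fft(x * w))^2
  nb <- floor(n / 2)
  freqs <- seq_len(nb) * rate / n
  p <- sp[1 + seq_len(nb)]
  band <- freqs > 0 & freqs <= 10
  if (sum(p[band]) < 1e-24) return(0)
  freqs[band][which.max(p[band])]
}

#' Deploy the classifier on one night
#'
#' The deployment flow: resample each worn hand to 20 Hz, detect movement,
#' detect non-wear from stillness plus temperature, take the TSO window
#' (supplied, or the night's reference window, or the per-hand heuristic
#' combined across hands), excise non-wear, tile non-overlapping 3-s windows,
#' keep those with at least 1 s of movement, classify them, and pool both
#' hands onto a common tiling (a tile is scratch when either hand calls it).
#'
#' @param model A trained `ns_model`.
#' @param night A `ns_night`, or a list with `ns_recording` elements `left`
#'   and/or `right`.
#' @param tso Optional `ns_tso` row; default uses the night's `true_tso` when
#'   present, otherwise the heuristic per hand combined.
#' @param theta_cov,theta_sd Movement thresholds.
#' @param threshold Probability call threshold (default from the model).
#' @return A `ns_night_pred` list: `pooled` (tile-level tibble with `start_s`,
#'   `prob`, `call`, `domfreq_hz`), `per_hand`, `tso`, `nonwear`.
#' @export
predict_night <- function(model, night, tso = NULL, theta_cov = 0.41,
                          theta_sd = 0.013, threshold = NULL) {
  threshold <- threshold %||% model$threshold
  hands <- intersect(c("left", "right"), names(night))
  hands <- hands[vapply(hands, function(h) inherits(night[[h]], "ns_recording"),
                        logical(1))]
  if (length(hands) == 0L) ns_abort("no recordings in night", "ns_error_schema")
  prep <- list()
  for (h in hands) {
    rec20 <- resample_recording(night[[h]], 20)
    mov <- detect_movement(rec20, theta_cov, theta_sd)
    nw <- detect_nonwear(mov, rec20)
    lin <- remove_gravity_accel(rec20)
    gyr <- if (model$sensors == "both") {
      as.matrix(rec20[, c("gx", "gy", "gz")]) * pi / 180
    } else NULL
    prep[[h]] <- list(rec20 = rec20, movement = mov, nonwear = nw,
                      linear = lin, gyro = gyr)
  }
  if (is.null(tso)) {
    tso <- if (!is.null(night$true_tso)) {
      tso_from_reference(night$true_tso)
    } else {
      per <- lapply(hands, function(h)
        tso_heuristic(prep[[h]]$rec20, prep[[h]]$nonwear))
      if (length(per) == 2L) combine_hands(per[[1]], per[[2]]) else per[[1]]
    }
  }
  if (!isTRUE(tso$valid[1])) {
    warning("empty TSO: no prediction", call. = FALSE)
    return(structure(list(pooled = tibble::tibble(start_s = numeric(),
                                                  prob = numeric(),
                                                  call = logical(),
                                                  domfreq_hz = numeric()),
                          per_hand = list(), tso = tso,
                          nonwear = list()),
                     class = "ns_night_pred"))
  }
  per_hand <- list()
  for (h in hands) {
    p <- prep[[h]]
    wins <- segment_windows(p$movement, p$linear, gyro = p$gyro, hand = h,
                            mode = "deploy", tso = tso, nonwear = p$nonwear)
    if (nrow(wins) == 0L) {
      per_hand[[h]] <- tibble::tibble(hand = character(), start_s = numeric(),
                                      prob = numeric(), call = logical(),
                                      domfreq_hz = numeric())
      next
    }
    pr <- predict(model, wins)
    pr$call <- pr$prob >= threshold
    # intensity from the calibrated (gravity-retained) signal
    acc_raw <- as.matrix(p$rec20[, c("ax", "ay", "az")])
    pr$domfreq_hz <- vapply(wins$start_s, function(a) {
      i0 <- round(a * 20) + 1L
      window_domfreq(acc_raw[i0:(i0 + 59L), , drop = FALSE], 20)
    }, numeric(1))
    per_hand[[h]] <- pr
  }
  tiles <- dplyr::bind_rows(per_hand)
  pooled <- if (nrow(tiles) == 0L) {
    tibble::tibble(start_s = numeric(), prob = numeric(), call = logical(),
                   domfreq_hz = numeric())
  } else {
    tiles |>
      dplyr::group_by(.data$start_s) |>
      dplyr::summarise(prob = max(.data$prob), call = any(.data$call),
                       domfreq_hz = .data$domfreq_hz[which.max(.data$prob)],
                       .groups = "drop") |>
      dplyr::arrange(.data$start_s)
  }
  structure(list(pooled = pooled, per_hand = per_hand, tso = tso,
                 nonwear = lapply(prep, function(p) p$nonwear)),
            class = "ns_night_pred")
}

#' Per-night digital endpoints from window calls
#'
#' Total scratch duration is 3 s per positive non-overlapping window (pooled
#' across hands); hourly scratch duration is the total divided by the TSO
#' worn hours; mean scratch intensity is the mean vector-magnitude dominant
#' frequency (Hz) over positive windows, `NA` when there are none.
#'
#' @param pred A `ns_night_pred` from [predict_night()].
#' @param subject,night Optional identifiers carried into the result.
#' @return One-row tibble: `total_scratch_s`, `hourly_scratch_s_per_h`,
#'   `intensity_hz`, `tso_h`, `n_windows`.
#' @export
compute_endpoints <- function(pred, subject = NA_character_, night = NA_integer_) {
  tso <- pred$tso
  tso_h <- if (!isTRUE(tso$valid[1])) NA_real_ else {
    wh <- tso$worn_h[1]
    if (is.na(wh)) (tso$end_s[1] - tso$start_s[1]) / 3600 else wh
  }
  pos <- pred$pooled[pred$pooled$call, , drop = FALSE]
  total <- 3 * nrow(pos)
  if (!is.na(tso_h)) total <- min(total, tso_h * 3600)
  tibble::tibble(
    subject = subject, night = night,
    total_scratch_s = total,
    hourly_scratch_s_per_h = if (is.na(tso_h) || tso_h <= 0) NA_real_ else
      total / tso_h,
    intensity_hz = if (nrow(pos) == 0L) NA_real_ else mean(pos$domfreq_hz),
    tso_h = tso_h, n_windows = nrow(pred$pooled))
}

#' Bland-Altman agreement between two paired measures
#'
#' Mean difference (derived minus reference) and 95% limits of agreement
#' `mean(d) +/- 1.96 sd(d)`.
#'
#' @param derived,reference Paired numeric vectors, equal length >= 2.
#' @return One-row tibble: `mean_diff`, `lower`, `upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(derived, reference) {
  if (length(derived) != length(reference)) {
    ns_abort("paired vectors must have equal length", "ns_error_schema")
  }
  if (length(derived) < 2L) ns_abort("need at least 2 pairs", "ns_error_schema")
  d <- derived - reference
  m <- mean(d); s <- stats::sd(d)
  tibble::tibble(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
                 sd_diff = s, n = length(d))
}

#' One-way random-effects intraclass correlation, single measure
#'
#' ICC(1,1) for repeated per-night measures nested in subjects:
#' `(MSB - MSW) / (MSB + (k - 1) MSW)` with `k` the mean group size for
#' unbalanced designs (`k = (N - sum(n_i^2)/N) / (g - 1)`). Subjects with a
#' single night are excluded with a warning.
#'
#' @param values Numeric measurements.
#' @param subject Grouping vector, same length.
#' @return One-row tibble: `icc`, `msb`, `msw`, `k`, `n_subjects`, `n`.
#' @export
icc_oneway <- function(values, subject) {
  ok <- is.finite(values)
  values <- values[ok]; subject <- as.character(subject)[ok]
  cnt <- table(subject)
  if (any(cnt < 2L)) {
    warning("subject(s) with a single measurement excluded from ICC",
            call. = FALSE)
    keep <- subject %in% names(cnt)[cnt >= 2L]
    values <- values[keep]; subject <- subject[keep]
  }
  g <- length(unique(subject))
  if (g < 2L) ns_abort("ICC needs >= 2 subjects with repeats", "ns_error_degenerate")
  N <- length(values)
  gm <- mean(values)
  mts <- tapply(values, subject, mean)
  ns <- tapply(values, subject, length)
  msb <- sum(ns * (mts - gm)^2) / (g - 1)
  msw <- sum((values - mts[subject])^2) / (N - g)
  k <- (N - sum(ns^2) / N) / (g - 1)
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  tibble::tibble(icc = icc, msb = msb, msw = msw, k = k,
                 n_subjects = g, n = N)
}

#' Correlate digital endpoints with patient-reported outcomes
#'
#' Severity scores reported once per subject (SCORAD) are correlated against
#' subject-level mean endpoints; nightly sleep-scale items (ADSS) are
#' correlated at the night level. Pearson and Spearman coefficients are both
#' reported; pairs with fewer than 3 observations give `NA`.
#'
#' @param endpoints Tibble with `subject`, `night` and an endpoint column.
#' @param pro Tibble with `subject`, `night`, ADSS item columns and `SCORAD`.
#' @param endpoint_col Endpoint column name, default
#'   `"hourly_scratch_s_per_h"`.
#' @return Tidy tibble: `pro`, `level`, `method`, `r`, `n`.
#' @export
correlate_with_pro <- function(endpoints, pro,
                               endpoint_col = "hourly_scratch_s_per_h") {
  res <- list()
  corr_pair <- function(x, y, label, level) {
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    for (m in c("pearson", "spearman")) {
      r <- if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        NA_real_ else stats::cor(x[ok], y[ok], method = m)
      res[[length(res) + 1L]] <<- tibble::tibble(
        pro = label, level = level, method = m, r = r, n = n)
    }
  }
  if ("SCORAD" %in% names(pro)) {
    subj_end <- endpoints |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(v = mean(.data[[endpoint_col]], na.rm = TRUE),
                       .groups = "drop")
    subj_pro <- pro |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(SCORAD = .data$SCORAD[1], .groups = "drop")
    j <- dplyr::inner_join(subj_end, subj_pro, by = "subject")
    corr_pair(j$v, j$SCORAD, "SCORAD", "subject")
  }
  adss_cols <- grep("^ADSS", names(pro), value = TRUE)
  if (length(adss_cols) > 0L) {
    j <- dplyr::inner_join(endpoints, pro, by = c("subject", "night"))
    for (cl in adss_cols) {
      corr_pair(j[[endpoint_col]], j[[cl]], cl, "night")
    }
  }
  dplyr::bind_rows(res)
}
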