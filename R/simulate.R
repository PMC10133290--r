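#' Describe a synthetic hand-night
#'
#' A scenario fixes everything the simulator needs to generate one night of
#' two-wrist 6-axis actigraphy with millisecond-resolution ground-truth
#' annotations: the event schedule (scratch bouts, other in-bed movements,
#' posture changes, out-of-bed periods), the sleep-opportunity window, the
#' sensor noise floor, and the device temperature model. The same seed always
#' yields byte-identical output.
#'
#' Scratch bouts are amplitude-modulated sinusoids with +/-10% slowly-wandering
#' frequency, mixed onto one or two sensor axes with a guaranteed component
#' along gravity; hand scratches default to 0.3-1.0 g peak amplitude, finger
#' scratches to 0.02-0.08 g. The scratch band defaults to 2-5 Hz (a modeling
#' choice; the band is exposed here rather than hard-coded downstream).
#'
#' @param duration_h Night length in hours (> 0).
#' @param sample_rate_hz Native sampling rate, default 50 Hz.
#' @param events Tibble with `label` (annotation vocabulary), `start_s`,
#'   `end_s`, `hand`, and optional `freq_hz`, `amp_g`, `kind`
#'   (`"move"`/`"posture"` refinement for non-scratch movement). `NULL` means
#'   a quiet night.
#' @param tso `c(start_s, end_s)` sleep-opportunity window; default the whole
#'   night.
#' @param nonwear Tibble `(start_s, end_s, hand)` of planted non-wear periods.
#' @param noise_sd_g Accelerometer noise SD in g (default 0.005).
#' @param gyro_noise_sd_dps Gyroscope noise SD in deg/s.
#' @param temp_worn_c Worn skin-contact temperature baseline (deg C).
#' @param temp_ambient_c Ambient temperature the device decays toward when off
#'   wrist (deg C); decay time constant 3 min.
#' @param scratch_freq_range_hz Band scratch frequencies are drawn from when an
#'   event does not fix its own `freq_hz`.
#' @param gravity_orientation Optional unit 3-vector: sensor-frame gravity
#'   direction at lights-out (per-hand random if `NULL`).
#' @param start_epoch_s Epoch seconds of the first sample (defaults to a fixed
#'   22:00 UTC so clock-gated stages behave reproducibly).
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A `night_scenario` list.
#' @export
night_scenario <- function(duration_h = 8,
                           sample_rate_hz = 50,
                           events = NULL,
                           tso = NULL,
                           nonwear = NULL,
                           noise_sd_g = 0.005,
                           gyro_noise_sd_dps = 0.2,
                           temp_worn_c = 32,
                           temp_ambient_c = 22,
                           scratch_freq_range_hz = c(2, 5),
                           gravity_orientation = NULL,
                           start_epoch_s = as.numeric(as.POSIXct(
                             "2026-01-01 22:00:00", tz = "UTC")),
                           seed = 1L) {
  if (!is.numeric(duration_h) || duration_h <= 0) {
    ns_abort("duration_h must be > 0", "ns_error_scenario")
  }
  if (sample_rate_hz <= 0) ns_abort("sample_rate_hz must be > 0", "ns_error_scenario")
  dur_s <- duration_h * 3600
  if (is.null(tso)) tso <- c(0, dur_s)
  if (tso[1] < 0 || tso[2] > dur_s + 1e-9 || tso[1] >= tso[2]) {
    ns_abort("tso must lie within the night and satisfy start < end", "ns_error_scenario")
  }
  events <- if (is.null(events)) empty_schedule() else tibble::as_tibble(events)
  if (!"freq_hz" %in% names(events)) events$freq_hz <- NA_real_
  if (!"amp_g" %in% names(events)) events$amp_g <- NA_real_
  if (!"kind" %in% names(events)) events$kind <- NA_character_
  if (nrow(events) > 0L) {
    if (any(events$start_s < 0 | events$end_s > dur_s + 1e-9)) {
      ns_abort("events must lie within [0, duration]", "ns_error_scenario")
    }
    if (any(events$start_s >= events$end_s)) {
      ns_abort("events must satisfy start < end", "ns_error_scenario")
    }
    bad <- setdiff(unique(events$label), annotation_labels())
    if (length(bad) > 0L) {
      ns_abort(paste0("unknown event label(s): ", paste(bad, collapse = ", ")),
               "ns_error_label")
    }
    for (h in unique(events$hand)) {
      ev <- events[events$hand == h, , drop = FALSE]
      ev <- ev[order(ev$start_s), , drop = FALSE]
      if (nrow(ev) > 1L && any(ev$start_s[-1] < ev$end_s[-nrow(ev)] - 1e-9)) {
        ns_abort(sprintf("overlapping events on hand '%s'", h), "ns_error_overlap")
      }
    }
    sc <- events[events$label == "scratch", , drop = FALSE]
    if (nrow(sc) > 0L && any(sc$start_s < tso[1] - 1e-9 | sc$end_s > tso[2] + 1e-9)) {
      ns_abort("scratch events must lie inside the TSO window", "ns_error_scenario")
    }
  }
  nonwear <- if (is.null(nonwear)) {
    tibble::tibble(start_s = numeric(), end_s = numeric(), hand = character())
  } else tibble::as_tibble(nonwear)
  structure(list(
    duration_h = duration_h, sample_rate_hz = sample_rate_hz,
    events = events, tso = tso, nonwear = nonwear,
    noise_sd_g = noise_sd_g, gyro_noise_sd_dps = gyro_noise_sd_dps,
    temp_worn_c = temp_worn_c, temp_ambient_c = temp_ambient_c,
    scratch_freq_range_hz = scratch_freq_range_hz,
    gravity_orientation = gravity_orientation,
    start_epoch_s = start_epoch_s, seed = as.integer(seed)),
    class = "night_scenario")
}

empty_schedule <- function() {
  tibble::tibble(label = character(), start_s = numeric(), end_s = numeric(),
                 hand = character(), freq_hz = numeric(), amp_g = numeric(),
                 kind = character())
}

#' Draw a random in-bed event schedule
#'
#' Places non-overlapping scratch bouts, other in-bed movements and posture
#' changes on one hand at given hourly rates. Bout lengths are uniform within
#' the stated ranges; a fraction of scratch bouts are low-amplitude finger
#' scratches.
#'
#' @param duration_h Night length (hours).
#' @param hand Which wrist the events are placed on.
#' @param scratch_rate_per_h,movement_rate_per_h,posture_rate_per_h Expected
#'   event counts per hour (Poisson).
#' @param scratch_len_s,movement_len_s Length ranges (seconds).
#' @param hand_amp_g,finger_amp_g Peak-amplitude ranges for hand and finger
#'   scratches.
#' @param finger_frac Fraction of scratch bouts that are finger scratches.
#' @param freq_hz Optional fixed scratch frequency (otherwise drawn downstream
#'   from the scenario band).
#' @param tso TSO window the scratch bouts must stay inside.
#' @return An event tibble usable as `night_scenario(events = ...)`.
#' @export
random_schedule <- function(duration_h, hand = "left",
                            scratch_rate_per_h = 2,
                            movement_rate_per_h = 3,
                            posture_rate_per_h = 1.5,
                            scratch_len_s = c(15, 35),
                            movement_len_s = c(8, 20),
                            hand_amp_g = c(0.3, 1.0),
                            finger_amp_g = c(0.02, 0.08),
                            finger_frac = 0,
                            freq_hz = NA_real_,
                            tso = NULL) {
  dur_s <- duration_h * 3600
  if (is.null(tso)) tso <- c(0, dur_s)
  n_sc <- stats::rpois(1, scratch_rate_per_h * duration_h)
  n_mv <- stats::rpois(1, movement_rate_per_h * duration_h)
  n_po <- stats::rpois(1, posture_rate_per_h * duration_h)
  lens <- c(stats::runif(n_sc, scratch_len_s[1], scratch_len_s[2]),
            stats::runif(n_mv, movement_len_s[1], movement_len_s[2]),
            stats::runif(n_po, 3, 8))
  labs <- c(rep("scratch", n_sc), rep("non-scratch movement", n_mv + n_po))
  kinds <- c(rep("scratch", n_sc), rep("move", n_mv), rep("posture", n_po))
  n_ev <- length(lens)
  if (n_ev == 0L) return(empty_schedule())
  # place events without overlap by jittering around a uniform grid
  ord <- sample.int(n_ev)
  lens <- lens[ord]; labs <- labs[ord]; kinds <- kinds[ord]
  gap <- dur_s / n_ev
  starts <- (seq_len(n_ev) - 1) * gap +
    stats::runif(n_ev, 0.05 * gap, pmax(0.05 * gap, gap - lens - 0.05 * gap))
  ends <- pmin(starts + lens, dur_s)
  keep <- ends - starts >= 2
  starts <- starts[keep]; ends <- ends[keep]; labs <- labs[keep]; kinds <- kinds[keep]
  is_fing <- kinds == "scratch" & stats::runif(length(kinds)) < finger_frac
  amp <- ifelse(kinds == "scratch",
                ifelse(is_fing,
                       stats::runif(length(kinds), finger_amp_g[1], finger_amp_g[2]),
                       stats::runif(length(kinds), hand_amp_g[1], hand_amp_g[2])),
                stats::runif(length(kinds), 0.2, 0.45))
  ev <- tibble::tibble(label = labs, start_s = starts, end_s = ends, hand = hand,
                       freq_hz = ifelse(labs == "scratch", freq_hz, NA_real_),
                       amp_g = amp,
                       kind = ifelse(kinds == "scratch", NA_character_, kinds))
  # clamp scratch bouts into the TSO window; drop those that cannot fit
  sc <- ev$label == "scratch"
  ev$start_s[sc] <- pmax(ev$start_s[sc], tso[1])
  ev$end_s[sc] <- pmin(ev$end_s[sc], tso[2])
  ev <- ev[ev$end_s - ev$start_s >= 2, , drop = FALSE]
  ev <- dplyr::arrange(ev, .data$start_s)
  # drop any event that would overlap its predecessor (long bout spilling over)
  if (nrow(ev) > 1L) {
    keep <- rep(TRUE, nrow(ev))
    last_end <- ev$end_s[1]
    for (i in seq_len(nrow(ev))[-1]) {
      if (ev$start_s[i] < last_end) keep[i] <- FALSE else last_end <- ev$end_s[i]
    }
    ev <- ev[keep, , drop = FALSE]
  }
  ev
}

# quaternion helpers (w, x, y, z); rotate world vector into sensor frame
quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_norm <- function(q) q / sqrt(sum(q^2))

quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# rotation matrix of unit quaternion (maps body/sensor coords to world coords)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# quaternion rotating world z onto sensor-frame gravity direction g (unit)
quat_align_z <- function(g) {
  e3 <- c(0, 0, 1)
  v <- c(e3[2] * g[3] - e3[3] * g[2],
         e3[3] * g[1] - e3[1] * g[3],
         e3[1] * g[2] - e3[2] * g[1])
  d <- sum(e3 * g)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) return(c(0, 1, 0, 0))
  quat_norm(c(1 + d, v))
}

random_unit_vec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# band-limited smooth noise, unit SD
smooth_noise <- function(n, rate, low, high) {
  if (n < 24L) return(rep(0, n))
  bf <- signal::butter(2, c(low, high) / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  s <- stats::sd(x)
  if (s < 1e-12) rep(0, n) else x / s
}

simulate_hand <- function(scn, hand) {
  rate <- scn$sample_rate_hz
  n <- floor(scn$duration_h * 3600 * rate)
  t <- (seq_len(n) - 1) / rate
  g0 <- scn$gravity_orientation %||% random_unit_vec()
  g0 <- g0 / sqrt(sum(g0^2))

  ev <- scn$events[scn$events$hand == hand, , drop = FALSE]
  ev <- ev[order(ev$start_s), , drop = FALSE]

  # --- orientation path: piecewise constant, rotating during posture events
  grav <- matrix(rep(g0, each = n), ncol = 3)
  omega_body <- matrix(0, n, 3)        # rad/s, sensor frame
  q <- quat_conj(quat_align_z(g0))     # body -> world: R(q)^T e3 = g0
  po <- ev[!is.na(ev$kind) & ev$kind == "posture", , drop = FALSE]
  if (nrow(po) > 0L) {
    for (i in seq_len(nrow(po))) {
      i0 <- max(1L, floor(po$start_s[i] * rate) + 1L)
      i1 <- min(n, ceiling(po$end_s[i] * rate))
      if (i1 <= i0) next
      axis <- random_unit_vec()
      angle <- stats::runif(1, pi / 6, pi / 2) * sample(c(-1, 1), 1)
      dur <- (i1 - i0) / rate
      w <- angle / dur                 # constant body rate about `axis`
      idx <- i0:i1
      th <- (idx - i0) / rate * w
      # sensor-frame gravity before the event, rotated back through exp(-th K)
      g_pre <- as.numeric(crossprod(quat_to_matrix(q), c(0, 0, 1)))
      for (k in seq_along(idx)) {
        dq <- quat_from_axis_angle(axis, th[k])
        grav[idx[k], ] <- as.numeric(crossprod(quat_to_matrix(dq), g_pre))
      }
      omega_body[idx, ] <- matrix(rep(axis * w, each = length(idx)), ncol = 3)
      q <- quat_mult(q, quat_from_axis_angle(axis, angle))
      if (i1 < n) {
        g_post <- as.numeric(crossprod(quat_to_matrix(q), c(0, 0, 1)))
        grav[(i1 + 1L):n, ] <- matrix(rep(g_post, each = n - i1), ncol = 3)
      }
    }
  }

  # --- additive linear acceleration + gyro oscillation per event
  lin <- matrix(0, n, 3)
  gyr_ev <- matrix(0, n, 3)
  for (i in seq_len(nrow(ev))) {
    lab <- ev$label[i]; kind <- ev$kind[i]
    if (!is.na(kind) && kind == "posture") next
    i0 <- max(1L, floor(ev$start_s[i] * rate) + 1L)
    i1 <- min(n, ceiling(ev$end_s[i] * rate))
    if (i1 <= i0) next
    idx <- i0:i1
    m <- length(idx)
    tt <- (idx - i0) / rate
    ghat <- grav[i0, ]
    if (lab == "scratch") {
      f <- ev$freq_hz[i]
      if (is.na(f)) f <- stats::runif(1, scn$scratch_freq_range_hz[1],
                                      scn$scratch_freq_range_hz[2])
      a <- ev$amp_g[i]; if (is.na(a)) a <- stats::runif(1, 0.3, 1.0)
      jit <- smooth_noise(m, rate, 0.05, min(0.4, rate / 2.5 / max(tt[m], 1)))
      jit <- jit - mean(jit)
      f_inst <- f * (1 + 0.1 * pmin(pmax(jit, -1), 1))
      phase <- 2 * pi * cumsum(f_inst) / rate + stats::runif(1, 0, 2 * pi)
      env <- 0.65 + 0.35 * sin(2 * pi * stats::runif(1, 0.3, 1) * tt +
                                 stats::runif(1, 0, 2 * pi))
      s1 <- a * env * sin(phase)
      s2 <- a * env * cos(phase) * stats::runif(1, 0, 0.6)
      # mixing direction with a guaranteed gravity-aligned component
      perp <- random_unit_vec()
      perp <- perp - sum(perp * ghat) * ghat
      perp <- perp / sqrt(sum(perp^2))
      th <- stats::runif(1, pi / 9, pi / 3)     # 20..60 deg off gravity
      u1 <- cos(th) * ghat + sin(th) * perp
      u2 <- random_unit_vec()
      lin[idx, ] <- lin[idx, ] + outer(s1, u1) + outer(s2, u2)
      # low-frequency arm-drag component: the hand travels over the skin
      # while oscillating, so scratch bouts are not purely narrowband
      a_lf <- a * stats::runif(1, 0.15, 0.25)
      lin[idx, ] <- lin[idx, ] +
        outer(a_lf * smooth_noise(m, rate, 0.3, 1.5), random_unit_vec())
      wamp <- a * 250                           # deg/s wrist oscillation
      gyr_ev[idx, ] <- gyr_ev[idx, ] +
        outer(wamp * env * sin(phase + stats::runif(1, 0, 2 * pi)),
              random_unit_vec()) +
        outer(a_lf * 150 * smooth_noise(m, rate, 0.3, 1.5), random_unit_vec())
    } else {
      # smooth low-frequency arm movement (0.3-1.5 Hz band)
      a <- ev$amp_g[i]; if (is.na(a)) a <- 0.3
      for (ax in 1:3) {
        lin[idx, ax] <- lin[idx, ax] +
          a * stats::runif(1, 0.3, 1) * 0.5 * smooth_noise(m, rate, 0.3, 1.5)
      }
      for (ax in 1:3) {
        gyr_ev[idx, ax] <- gyr_ev[idx, ax] +
          a * 120 * stats::runif(1, 0.3, 1) * smooth_noise(m, rate, 0.3, 1.5)
      }
    }
  }

  accel <- grav + lin +
    matrix(stats::rnorm(3L * n, sd = scn$noise_sd_g), ncol = 3)
  gyro <- omega_body * 180 / pi + gyr_ev +
    matrix(stats::rnorm(3L * n, sd = scn$gyro_noise_sd_dps), ncol = 3)

  # --- temperature and non-wear overwrite
  temp <- scn$temp_worn_c +
    0.6 * sin(2 * pi * t / (3600 * 6) + stats::runif(1, 0, 2 * pi)) +
    0.3 * smooth_noise(n, rate, 1 / 3600, 1 / 600)
  nw <- scn$nonwear[scn$nonwear$hand == hand, , drop = FALSE]
  tau <- 180                                   # 3-min decay constant
  if (nrow(nw) > 0L) {
    worn_temp <- temp
    for (i in seq_len(nrow(nw))) {
      i0 <- max(1L, floor(nw$start_s[i] * rate) + 1L)
      i1 <- min(n, ceiling(nw$end_s[i] * rate))
      if (i1 <= i0) next
      idx <- i0:i1
      frozen <- grav[i0, ]
      accel[idx, ] <- matrix(rep(frozen, each = length(idx)), ncol = 3) +
        matrix(stats::rnorm(3L * length(idx), sd = 3e-4), ncol = 3)
      gyro[idx, ] <- matrix(stats::rnorm(3L * length(idx), sd = 0.05), ncol = 3)
      dt <- (idx - i0) / rate
      temp[idx] <- scn$temp_ambient_c +
        (temp[i0] - scn$temp_ambient_c) * exp(-dt / tau)
      if (i1 < n) {
        # recover toward the worn baseline after re-wear, same time constant
        rest <- (i1 + 1L):n
        dt2 <- (rest - i1) / rate
        temp[rest] <- worn_temp[rest] +
          (temp[i1] - worn_temp[i1]) * exp(-dt2 / tau)
      }
    }
  }

  as_recording(tibble::tibble(
    time_s = scn$start_epoch_s + t,
    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
    temp_c = temp), rate_hz = rate, hand = hand)
}

build_annotations <- function(scn) {
  dur_s <- scn$duration_h * 3600
  tso <- scn$tso
  res <- function(x) round(x, 3)               # 1-ms annotation resolution
  out <- list()
  for (h in c("left", "right")) {
    ev <- scn$events[scn$events$hand == h, , drop = FALSE]
    ev <- ev[order(ev$start_s), , drop = FALSE]
    inb <- ev[ev$start_s >= tso[1] - 1e-9 & ev$end_s <= tso[2] + 1e-9, , drop = FALSE]
    cur <- tso[1]
    rows <- list()
    if (nrow(inb) > 0L) {
      for (i in seq_len(nrow(inb))) {
        if (inb$start_s[i] > cur + 1e-3) {
          rows[[length(rows) + 1L]] <- list("in-bed still", cur, inb$start_s[i])
        }
        rows[[length(rows) + 1L]] <- list(inb$label[i], inb$start_s[i], inb$end_s[i])
        cur <- inb$end_s[i]
      }
    }
    if (tso[2] > cur + 1e-3) rows[[length(rows) + 1L]] <- list("in-bed still", cur, tso[2])
    if (tso[1] > 1e-3) rows[[length(rows) + 1L]] <- list("out-of-bed", 0, tso[1])
    if (dur_s > tso[2] + 1e-3) rows[[length(rows) + 1L]] <- list("out-of-bed", tso[2], dur_s)
    if (length(rows) > 0L) {
      out[[h]] <- tibble::tibble(
        start_s = res(vapply(rows, function(r) r[[2]], 1)),
        end_s = res(vapply(rows, function(r) r[[3]], 1)),
        label = vapply(rows, function(r) r[[1]], ""),
        hand = h)
    }
  }
  as_annotations(dplyr::bind_rows(out))
}

#' Simulate one annotated two-wrist night
#'
#' Generates both hands' 6-axis recordings (gravity along the orientation path
#' plus event oscillations plus Gaussian noise; gyroscope consistent with the
#' orientation path), the millisecond-resolution annotation track, and the
#' ground-truth TSO and non-wear intervals.
#'
#' @param scenario A [night_scenario()].
#' @return A `ns_night` list: `left`, `right` (recordings), `annotations`,
#'   `true_tso`, `true_nonwear`, `scenario`.
#' @export
simulate_night <- function(scenario) {
  stopifnot(inherits(scenario, "night_scenario"))
  with_seed(scenario$seed, {
    left <- simulate_hand(scenario, "left")
    right <- simulate_hand(scenario, "right")
    ann <- build_annotations(scenario)
    structure(list(left = left, right = right, annotations = ann,
                   true_tso = scenario$tso, true_nonwear = scenario$nonwear,
                   scenario = scenario),
              class = "ns_night")
  })
}

#' Simulate a multi-subject cohort of nights
#'
#' Each subject gets an idiosyncratic scratch style -- a personal frequency
#' inside the scenario band, a personal amplitude range, and a personal
#' finger-scratch fraction -- held fixed across that subject's nights, so that
#' leave-one-subject-out evaluation is meaningful. `severity` is the expected
#' number of scratch bouts per hour per subject (scalar recycled, or one value
#' per subject); `severity = 0` plants no scratch at all.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param nights_per_subject Scalar or per-subject vector of night counts.
#' @param duration_h Night length in hours.
#' @param severity Scratch bouts per hour (scalar or per-subject).
#' @param movement_rate_per_h Non-scratch movement bouts per hour (shared).
#' @param finger_frac Fraction of finger scratches (scalar or per-subject;
#'   `NULL` draws per subject in \[0, 0.3\]).
#' @param seed Integer master seed.
#' @param ... Passed to [night_scenario()] (e.g. `sample_rate_hz`,
#'   `noise_sd_g`).
#' @return Tibble with `subject`, `night`, `severity`, `scratch_freq_hz`,
#'   `planted_scratch_s` and a `night_data` list-column of `ns_night` objects.
#' @export
simulate_cohort <- function(n_subjects, nights_per_subject, duration_h = 8,
                            severity = 2, movement_rate_per_h = 6,
                            finger_frac = NULL, seed = 1L, ...) {
  if (n_subjects < 1) ns_abort("n_subjects must be >= 1", "ns_error_scenario")
  nights <- rep_len(nights_per_subject, n_subjects)
  with_seed(seed, {
    freq_s <- stats::runif(n_subjects, 2.2, 4.8)
    amp_lo <- stats::runif(n_subjects, 0.3, 0.5)
    amp_hi <- amp_lo + stats::runif(n_subjects, 0.2, 0.5)
    ffrac <- if (is.null(finger_frac)) stats::runif(n_subjects, 0, 0.3)
             else rep_len(finger_frac, n_subjects)
    sev <- rep_len(severity, n_subjects)
    night_seeds <- sample.int(.Machine$integer.max - 1L,
                              sum(nights), replace = FALSE)
    rows <- list()
    k <- 0L
    for (s in seq_len(n_subjects)) {
      for (nn in seq_len(nights[s])) {
        k <- k + 1L
        ns_seed <- night_seeds[k]
        sim <- with_seed(ns_seed, {
          ev <- random_schedule(duration_h, hand = "left",
                                scratch_rate_per_h = sev[s],
                                movement_rate_per_h = movement_rate_per_h,
                                freq_hz = freq_s[s],
                                hand_amp_g = c(amp_lo[s], amp_hi[s]),
                                finger_frac = ffrac[s])
          scn <- night_scenario(duration_h = duration_h, events = ev,
                                seed = ns_seed, ...)
          simulate_night(scn)
        })
        sc <- sim$scenario$events
        sc <- sc[sc$label == "scratch", , drop = FALSE]
        rows[[k]] <- tibble::tibble(
          subject = sprintf("S%02d", s), night = nn,
          severity = sev[s], scratch_freq_hz = freq_s[s],
          planted_scratch_s = sum(sc$end_s - sc$start_s),
          night_data = list(sim))
      }
    }
    dplyr::bind_rows(rows)
  })
}
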