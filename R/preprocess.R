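#' Autocalibrate a recording to local gravity
#'
#' Device-level gain and offset errors are estimated from stationary segments:
#' any 10-s epoch whose per-axis SD stays under `sd_thresh_g` contributes its
#' mean acceleration vector, and per-axis gain/offset are chosen by iterative
#' least squares so those vectors land on the unit (1 g) sphere. The
#' correction is applied as `a' = gain * a + offset`.
#'
#' Requires at least 10 minutes of stationary data spanning at least two
#' distinct orientations; otherwise identity parameters are returned with a
#' warning.
#'
#' @param recording A `ns_recording` (any rate).
#' @param epoch_s Stationary-epoch length in seconds.
#' @param sd_thresh_g Stationarity threshold on the per-axis SD (g).
#' @param n_iter Iterations of the least-squares refinement.
#' @return List with `params` (gain, offset, n_stationary_s, converged) and
#'   `recording` (calibrated copy).
#' @export
autocalibrate <- function(recording, epoch_s = 10, sd_thresh_g = 0.013,
                          n_iter = 25) {
  rate <- rec_rate(recording)
  acc <- as.matrix(recording[, c("ax", "ay", "az")])
  n_ep <- floor(nrow(acc) / (epoch_s * rate))
  identity_out <- function(msg) {
    warning(msg, call. = FALSE)
    list(params = list(gain = c(1, 1, 1), offset = c(0, 0, 0),
                       n_stationary_s = 0, converged = FALSE),
         recording = recording)
  }
  if (n_ep < 2L) return(identity_out("too little data for autocalibration; identity returned"))
  ep <- rep(seq_len(n_ep), each = epoch_s * rate)
  idx <- seq_along(ep)
  sds <- sapply(1:3, function(j) tapply(acc[idx, j], ep, stats::sd))
  mns <- sapply(1:3, function(j) tapply(acc[idx, j], ep, mean))
  still <- apply(sds, 1, max) < sd_thresh_g
  v <- mns[still, , drop = FALSE]
  if (sum(still) * epoch_s < 600) {
    return(identity_out("under 10 min of stationary data; identity calibration returned"))
  }
  u <- v / sqrt(rowSums(v^2))
  # orientation spread: largest angle to the first orientation
  ang <- acos(pmin(1, pmax(-1, u %*% u[1, ])))
  if (max(ang) < 10 * pi / 180) {
    return(identity_out("stationary data spans a single orientation; identity calibration returned"))
  }
  gain <- c(1, 1, 1); offset <- c(0, 0, 0)
  for (it in seq_len(n_iter)) {
    cal <- sweep(sweep(v, 2, gain, "*"), 2, offset, "+")
    tgt <- cal / sqrt(rowSums(cal^2))
    for (j in 1:3) {
      fit <- stats::lm.fit(cbind(1, v[, j]), tgt[, j])
      offset[j] <- fit$coefficients[1]
      gain[j] <- fit$coefficients[2]
    }
  }
  out <- recording
  out$ax <- gain[1] * recording$ax + offset[1]
  out$ay <- gain[2] * recording$ay + offset[2]
  out$az <- gain[3] * recording$az + offset[3]
  list(params = list(gain = gain, offset = offset,
                     n_stationary_s = sum(still) * epoch_s, converged = TRUE),
       recording = out)
}

#' Resample a recording onto a uniform grid
#'
#' Linear interpolation onto a uniform `target_hz` grid starting at the first
#' timestamp; output length is `floor(duration * target_hz)`. Upsampling is
#' refused.
#'
#' @param recording A `ns_recording`.
#' @param target_hz Target rate (<= native rate), default 20 Hz.
#' @return Resampled `ns_recording`.
#' @export
resample_recording <- function(recording, target_hz = 20) {
  rate <- rec_rate(recording)
  if (target_hz > rate) {
    ns_abort("resampling only downsamples: target rate exceeds native rate",
             "ns_error_rate")
  }
  dur <- nrow(recording) / rate
  m <- floor(dur * target_hz)
  t0 <- recording$time_s[1]
  tt <- t0 + (seq_len(m) - 1) / target_hz
  cols <- setdiff(names(recording), "time_s")
  out <- tibble::tibble(time_s = tt)
  for (cl in cols) {
    out[[cl]] <- stats::approx(recording$time_s, recording[[cl]], xout = tt,
                               rule = 2)$y
  }
  as_recording(out, rate_hz = target_hz, hand = rec_hand(recording))
}

butter_hp <- function(cutoff_hz, rate) {
  signal::butter(1, cutoff_hz / (rate / 2), type = "high")
}

#' Remove gravity using the accelerometer only
#'
#' Gravity cannot be separated exactly without orientation information, so the
#' standard approximation is used: a first-order Butterworth high-pass at
#' 0.25 Hz, applied forward-backward (zero phase) per axis so event timing is
#' preserved against millisecond-resolution labels. DC is removed exactly.
#'
#' @param recording A uniform-rate `ns_recording` (use after
#'   [resample_recording()]).
#' @param cutoff_hz High-pass cutoff, default 0.25 Hz.
#' @return Tibble `time_s`, `X`, `Y`, `Z`: linear acceleration in g.
#' @export
remove_gravity_accel <- function(recording, cutoff_hz = 0.25) {
  rate <- rec_rate(recording)
  n <- nrow(recording)
  if (n < 3 * rate / cutoff_hz) {
    ns_abort("signal shorter than 3x the high-pass settling time", "ns_error_short")
  }
  bf <- butter_hp(cutoff_hz, rate)
  pad <- round(30 * rate)
  out <- tibble::tibble(
    time_s = recording$time_s,
    X = zp_filter(bf, recording$ax, pad),
    Y = zp_filter(bf, recording$ay, pad),
    Z = zp_filter(bf, recording$az, pad))
  attr(out, "gravity_method") <- "accel_only"
  out
}

quat_exp_rate <- function(w, dt) {
  th <- sqrt(sum(w^2)) * dt
  if (th < 1e-12) return(c(1, w * dt / 2))
  axis <- w * dt / th
  c(cos(th / 2), sin(th / 2) * axis)
}

#' Remove gravity by gyroscope fusion
#'
#' Tracks orientation by integrating the quaternion kinematic equation
#' `dq/dt = q (0, omega) / 2` (gyroscope converted deg/s -> rad/s, exact
#' axis-angle update per step, unit renormalisation), and mitigates drift by
#' nudging the orientation toward the accelerometer-measured gravity direction
#' in stationary samples (spherical correction with gain `alpha` per sample).
#' Linear acceleration is the measurement minus the tracked sensor-frame
#' gravity.
#'
#' @param recording A uniform-rate `ns_recording` with gyroscope channels.
#' @param stationary Logical per-sample vector marking stationary samples
#'   (e.g. the complement of a movement mask upsampled to the grid). `NULL`
#'   derives a conservative mask from a rolling per-axis SD threshold.
#' @param alpha Fusion gain per sample (0 disables the correction).
#' @return List: `linear` (tibble `time_s`, `X`, `Y`, `Z` in g) and
#'   `orientation` (n x 4 matrix of unit quaternions, sensor-to-world).
#' @export
remove_gravity_fused <- function(recording, stationary = NULL, alpha = 0.02) {
  if (!has_gyro(recording)) {
    ns_abort("no gyroscope channels: use remove_gravity_accel()", "ns_error_schema")
  }
  rate <- rec_rate(recording)
  n <- nrow(recording)
  acc <- as.matrix(recording[, c("ax", "ay", "az")])
  gyr <- as.matrix(recording[, c("gx", "gy", "gz")]) * pi / 180
  dt <- 1 / rate
  if (is.null(stationary)) {
    w <- max(3L, round(rate / 2))
    sds <- cbind(roll_sd(acc[, 1], w), roll_sd(acc[, 2], w), roll_sd(acc[, 3], w))
    mx <- apply(sds, 1, max)
    stationary <- !is.na(mx) & mx < 0.02
  }
  # initial orientation from the first second's mean gravity
  g0 <- colMeans(acc[seq_len(min(n, rate)), , drop = FALSE])
  g0 <- g0 / sqrt(sum(g0^2))
  q <- quat_conj(quat_align_z(g0))            # body -> world: R(q)^T e3 = g0
  quats <- matrix(NA_real_, n, 4)
  gvec <- matrix(NA_real_, n, 3)
  e3 <- c(0, 0, 1)
  for (k in seq_len(n)) {
    if (k > 1L) {
      q <- quat_mult(q, quat_exp_rate(gyr[k - 1L, ], dt))
      q <- quat_norm(q)
    }
    gs <- as.numeric(crossprod(quat_to_matrix(q), e3))  # gravity, sensor frame
    if (alpha > 0 && isTRUE(stationary[k])) {
      gm <- acc[k, ]
      nm <- sqrt(sum(gm^2))
      if (nm > 0.5 && nm < 1.5) {
        gm <- gm / nm
        ax <- c(gs[2] * gm[3] - gs[3] * gm[2],
                gs[3] * gm[1] - gs[1] * gm[3],
                gs[1] * gm[2] - gs[2] * gm[1])
        sn <- sqrt(sum(ax^2))
        if (sn > 1e-12) {
          th <- atan2(sn, sum(gs * gm))
          # right-multiplied correction by -alpha*theta rotates the gravity
          # estimate toward the measurement by +alpha*theta
          q <- quat_norm(quat_mult(q, quat_from_axis_angle(ax / sn, -alpha * th)))
          gs <- as.numeric(crossprod(quat_to_matrix(q), e3))
        }
      }
    }
    quats[k, ] <- q
    gvec[k, ] <- gs
  }
  lin <- acc - gvec
  linear <- tibble::tibble(time_s = recording$time_s,
                           X = lin[, 1], Y = lin[, 2], Z = lin[, 3])
  attr(linear, "gravity_method") <- "fused"
  list(linear = linear, orientation = quats)
}

# Canonical sign for a principal-component projection: the sample with the
# largest absolute value is made positive. Unlike a loading-based convention
# this is invariant under rotations of the raw axes.
canonical_sign <- function(p) {
  if (length(p) == 0L) return(p)
  i <- which.max(abs(p))
  if (p[i] < 0) -p else p
}

pc_project <- function(m) {
  cv <- stats::cov(m)
  if (!all(is.finite(cv)) || sum(diag(cv)) < 1e-24) {
    return(list(pc1 = rep(0, nrow(m)), pc2 = rep(0, nrow(m)),
                evr = c(0, 0)))
  }
  eg <- eigen(cv, symmetric = TRUE)
  ctr <- sweep(m, 2, colMeans(m))
  p1 <- canonical_sign(as.numeric(ctr %*% eg$vectors[, 1]))
  p2 <- canonical_sign(as.numeric(ctr %*% eg$vectors[, 2]))
  ev <- pmax(eg$values, 0)
  list(pc1 = p1, pc2 = p2, evr = ev[1:2] / max(sum(ev), 1e-24))
}

central_diff <- function(x, rate) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d
}

#' Derive the 12 orientation-augmented channels from a 3-axis series
#'
#' From a tri-axial series (linear acceleration in g, or angular rate) the
#' channel set is `X`, `Y`, `Z`, `PC1`, `PC2` (projections on the two leading
#' principal axes of the per-tile covariance, computed over non-overlapping
#' 3-s tiles), `VM` (vector magnitude), and the first derivative of each
#' (central differences, one-sided at edges) -- 12 series. PC projections of a
#' zero-variance tile are zeros; PC sign is canonicalised on the projected
#' series so the channels are invariant under rotations of the raw axes.
#'
#' @param xyz n x 3 matrix or tibble with three columns.
#' @param rate_hz Sampling rate.
#' @param tile_s Tile length for the PC covariance, default 3 s.
#' @return Tibble with 12 channel columns.
#' @export
derive_channels <- function(xyz, rate_hz, tile_s = 3) {
  m <- as.matrix(xyz)[, 1:3, drop = FALSE]
  n <- nrow(m)
  vm <- vm3(m)
  pc1 <- numeric(n); pc2 <- numeric(n)
  tl <- max(2L, round(tile_s * rate_hz))
  starts <- seq(1L, n, by = tl)
  for (s in starts) {
    e <- min(n, s + tl - 1L)
    if (e - s < 1L) { pc1[s:e] <- 0; pc2[s:e] <- 0; next }
    pr <- pc_project(m[s:e, , drop = FALSE])
    pc1[s:e] <- pr$pc1
    pc2[s:e] <- pr$pc2
  }
  out <- tibble::tibble(
    X = m[, 1], Y = m[, 2], Z = m[, 3], PC1 = pc1, PC2 = pc2, VM = vm)
  for (cl in c("X", "Y", "Z", "PC1", "PC2", "VM")) {
    out[[paste0("d", cl)]] <- central_diff(out[[cl]], rate_hz)
  }
  out
}
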