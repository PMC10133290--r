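#' Per-channel interpretable features
#'
#' Sixteen time/frequency descriptors of one 60-sample channel -- mean, SD,
#' min, max, range, RMS, IQR, median absolute deviation, skewness, kurtosis,
#' zero-crossing rate (mean crossings per second), lag-1 autocorrelation,
#' dominant frequency in (0, 10\] Hz, power at the dominant frequency,
#' spectral entropy (natural log) and spectral centroid -- plus the 11
#' topological features of [tda_features()], 27 values per channel. Spectra
#' use a Hann window on the demeaned series. Constant windows return zero
#' frequency features and zero-guarded statistics.
#'
#' @param x Numeric channel (one analysis window).
#' @param rate_hz Sampling rate.
#' @return Named numeric vector of length 27.
#' @export
channel_features <- function(x, rate_hz = 20) {
  n <- length(x)
  mu <- mean(x)
  sdv <- stats::sd(x)
  xc <- x - mu
  # zero-crossing rate of the mean-removed series, crossings per second
  sgn <- sign(xc)
  sgn <- sgn[sgn != 0]
  zcr <- if (length(sgn) < 2L) 0 else
    sum(sgn[-1] != sgn[-length(sgn)]) * rate_hz / (n - 1)
  ac1 <- if (sdv < 1e-12) 0 else
    sum(xc[-1] * xc[-n]) / sum(xc^2)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))    # Hann
  sp <- abs(stats::fft(xc * w))^2 / sum(w^2)
  nb <- floor(n / 2)
  freqs <- (seq_len(nb)) * rate_hz / n
  p <- sp[1 + seq_len(nb)]
  band <- freqs > 0 & freqs <= 10
  pb <- p[band]; fb <- freqs[band]
  if (sum(pb) < 1e-24) {
    domf <- 0; domp <- 0; sent <- 0; scen <- 0
  } else {
    i <- which.max(pb)
    domf <- fb[i]; domp <- pb[i]
    q <- pb / sum(pb)
    q <- q[q > 0]
    sent <- -sum(q * log(q))
    scen <- sum(fb * pb) / sum(pb)
  }
  c(mean = mu, sd = sdv, min = min(x), max = max(x), range = max(x) - min(x),
    rms = sqrt(mean(x^2)), iqr = stats::IQR(x), mad = stats::mad(x),
    skew = guarded_skewness(x), kurt = guarded_kurtosis(x),
    zcr = zcr, ac1 = ac1, domfreq = domf, dompower = domp,
    spec_entropy = sent, spec_centroid = scen,
    tda_features(x))
}

channel_names <- function() {
  feats <- c("mean", "sd", "min", "max", "range", "rms", "iqr", "mad",
             "skew", "kurt", "zcr", "ac1", "domfreq", "dompower",
             "spec_entropy", "spec_centroid",
             paste0("life_", c("mean", "sd", "skew", "kurt", "entropy")),
             paste0("mid_", c("mean", "sd", "skew", "kurt", "entropy")),
             "gpc_norm")
  chans <- c("X", "Y", "Z", "PC1", "PC2", "VM",
             "dX", "dY", "dZ", "dPC1", "dPC2", "dVM")
  list(feats = feats, chans = chans)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b)
}

sensor_feature_vector <- function(slice, rate_hz, prefix) {
  m <- as.matrix(slice)[, 1:3, drop = FALSE]
  vm <- vm3(m)
  pr <- pc_project(m)
  chans <- list(X = m[, 1], Y = m[, 2], Z = m[, 3],
                PC1 = pr$pc1, PC2 = pr$pc2, VM = vm)
  for (cl in names(chans)[1:6]) {
    chans[[paste0("d", cl)]] <- central_diff(chans[[cl]], rate_hz)
  }
  per_chan <- unlist(lapply(names(chans), function(cl) {
    v <- channel_features(chans[[cl]], rate_hz)
    stats::setNames(v, paste(prefix, cl, names(v), sep = "_"))
  }))
  tilt <- atan2(sqrt(m[, 1]^2 + m[, 2]^2), m[, 3]) * 180 / pi
  cross <- c(
    corr_xy = safe_cor(m[, 1], m[, 2]),
    corr_xz = safe_cor(m[, 1], m[, 3]),
    corr_yz = safe_cor(m[, 2], m[, 3]),
    corr_dxdy = safe_cor(chans$dX, chans$dY),
    corr_dxdz = safe_cor(chans$dX, chans$dZ),
    corr_dydz = safe_cor(chans$dY, chans$dZ),
    corr_xvm = safe_cor(m[, 1], vm),
    corr_yvm = safe_cor(m[, 2], vm),
    corr_zvm = safe_cor(m[, 3], vm),
    evr1 = pr$evr[1], evr2 = pr$evr[2],
    sma = mean(abs(m[, 1]) + abs(m[, 2]) + abs(m[, 3])),
    tilt_mean = mean(tilt), tilt_sd = stats::sd(tilt))
  names(cross) <- paste(prefix, "xc", names(cross), sep = "_")
  c(per_chan, cross)
}

#' Interpretable feature vector of one window
#'
#' 12 channels x 27 per-channel features + 14 cross-channel features per
#' sensor: 338 values for accelerometer only, 676 with the gyroscope.
#'
#' @param accel 60 x 3 linear-acceleration slice (g).
#' @param gyro Optional 60 x 3 gyroscope slice (rad/s).
#' @param rate_hz Sampling rate.
#' @return Named numeric vector (length 338 or 676).
#' @export
window_features <- function(accel, gyro = NULL, rate_hz = 20) {
  out <- sensor_feature_vector(accel, rate_hz, "acc")
  if (!is.null(gyro)) {
    out <- c(out, sensor_feature_vector(gyro, rate_hz, "gyr"))
  }
  out
}

#' Catalog of interpretable feature names
#'
#' The frozen, versioned column catalog the feature matrix is built against.
#'
#' @param sensors `"accel"` or `"both"`.
#' @return Character vector of 338 or 676 names.
#' @export
feature_catalog <- function(sensors = c("accel", "both")) {
  sensors <- match.arg(sensors)
  cn <- channel_names()
  per <- function(prefix) {
    c(unlist(lapply(cn$chans, function(ch)
      paste(prefix, ch, cn$feats, sep = "_"))),
      paste(prefix, "xc",
            c("corr_xy", "corr_xz", "corr_yz", "corr_dxdy", "corr_dxdz",
              "corr_dydz", "corr_xvm", "corr_yvm", "corr_zvm", "evr1",
              "evr2", "sma", "tilt_mean", "tilt_sd"), sep = "_"))
  }
  if (sensors == "accel") per("acc") else c(per("acc"), per("gyr"))
}

#' Assemble the interpretable feature matrix of a window set
#'
#' One row per window, fixed-width named columns (338 accelerometer-only, 676
#' with gyroscope). Any non-finite value is imputed to 0 and counted in the
#' `n_imputed` attribute; column names and order follow [feature_catalog()]
#' regardless of input.
#'
#' @param windows A `ns_windows` set.
#' @param sensors `"accel"` or `"both"`.
#' @return A `ns_features` tibble: metadata columns (`hand`, `start_s`,
#'   `label`, plus `subject`/`night` if present) followed by feature columns;
#'   attribute `feature_cols` lists the feature columns.
#' @export
assemble_features <- function(windows, sensors = c("accel", "both")) {
  sensors <- match.arg(sensors)
  rate <- attr(windows, "rate_hz") %||% 20
  if (sensors == "both" &&
      (nrow(windows) > 0L && is.null(windows$gyro[[1]]))) {
    ns_abort("gyroscope features requested but windows have no gyro slices",
             "ns_error_schema")
  }
  catalog <- feature_catalog(sensors)
  meta_cols <- intersect(c("subject", "night", "hand", "start_s", "movement_s",
                           "scratch_s", "label", "edge"), names(windows))
  if (nrow(windows) == 0L) {
    ft <- tibble::as_tibble(matrix(numeric(0), 0, length(catalog),
                                   dimnames = list(NULL, catalog)))
    out <- dplyr::bind_cols(windows[meta_cols], ft)
    return(structure(out, class = c("ns_features", class(tibble::tibble())),
                     feature_cols = catalog, n_imputed = 0L, sensors = sensors))
  }
  mat <- matrix(NA_real_, nrow(windows), length(catalog),
                dimnames = list(NULL, catalog))
  for (i in seq_len(nrow(windows))) {
    g <- if (sensors == "both") windows$gyro[[i]] else NULL
    mat[i, ] <- window_features(windows$accel[[i]], g, rate)[catalog]
  }
  n_imp <- sum(!is.finite(mat))
  mat[!is.finite(mat)] <- 0
  out <- dplyr::bind_cols(windows[meta_cols], tibble::as_tibble(mat))
  structure(out, class = c("ns_features", class(tibble::tibble())),
            feature_cols = catalog, n_imputed = n_imp, sensors = sensors,
            catalog_version = "1")
}
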