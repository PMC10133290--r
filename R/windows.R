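#' Segment movement periods into labeled 3-s windows
#'
#' Training mode places 3-s windows every 1.5 s (50% overlap) over the night
#' and keeps any window with at least 1 s of detected movement -- including
#' edge windows straddling movement and non-movement. Deployment mode tiles
#' non-overlapping 3-s windows from the TSO start, applies the same >= 1-s
#' movement rule, and drops windows touching non-wear. When annotations are
#' supplied, a window is labeled `scratch` iff strictly more than 1.0 s of it
#' is annotated scratch on the same hand; otherwise labels are `NA`
#' (prediction mode).
#'
#' @param movement A `ns_movement` mask for the hand.
#' @param linear Linear-acceleration tibble from [remove_gravity_accel()] /
#'   [remove_gravity_fused()] (20 Hz).
#' @param gyro Optional n x 3 gyroscope matrix (rad/s) on the same grid.
#' @param annotations Optional `ns_annotations` (times relative to recording
#'   start).
#' @param hand Hand of the recording.
#' @param mode `"train"` or `"deploy"`.
#' @param win_s,hop_s Window and hop length (3 s / 1.5 s).
#' @param tso Optional `ns_tso` row gating deployment windows.
#' @param nonwear Optional `ns_nonwear` intervals to exclude (deployment).
#' @return A `ns_windows` tibble: `hand`, `start_s`, `movement_s`,
#'   `scratch_s`, `label`, `edge`, and list-columns `accel`, `gyro`
#'   (60 x 3 slices).
#' @export
segment_windows <- function(movement, linear, gyro = NULL, annotations = NULL,
                            hand = "left", mode = c("train", "deploy"),
                            win_s = 3, hop_s = 1.5, tso = NULL, nonwear = NULL) {
  mode <- match.arg(mode)
  rate <- attr(movement, "rate_hz") %||% 20
  n <- nrow(linear)
  dur <- n / rate
  t0 <- 0
  t1 <- dur
  if (mode == "deploy") {
    hop_s <- win_s
    if (!is.null(tso)) {
      if (!isTRUE(tso$valid[1])) {
        warning("empty TSO: no deployment windows", call. = FALSE)
        return(empty_windows(win_s, rate))
      }
      t0 <- max(t0, tso$start_s[1])
      t1 <- min(t1, tso$end_s[1])
    }
  }
  if (t1 - win_s < t0) return(empty_windows(win_s, rate))
  starts <- seq(t0, t1 - win_s, by = hop_s)
  if (length(starts) == 0L) return(empty_windows(win_s, rate))
  flags <- movement$movement
  mov_s <- vapply(starts, function(a) {
    ks <- floor(a):min(ceiling(a + win_s) - 1, length(flags) - 1)
    ks <- ks[ks >= 0 & flags[ks + 1L]]
    if (length(ks) == 0L) return(0)
    overlap_s(a, a + win_s, ks, ks + 1)
  }, numeric(1))
  keep <- mov_s >= 1
  if (!is.null(nonwear) && nrow(nonwear) > 0L) {
    nw <- vapply(starts, function(a)
      overlap_s(a, a + win_s, nonwear$start_s, nonwear$end_s), numeric(1))
    keep <- keep & nw == 0
  }
  starts <- starts[keep]
  mov_s <- mov_s[keep]
  if (length(starts) == 0L) return(empty_windows(win_s, rate))
  scr_s <- rep(NA_real_, length(starts))
  label <- rep(NA_character_, length(starts))
  if (!is.null(annotations)) {
    ann <- dplyr::filter(tibble::as_tibble(annotations),
                         .data$hand == !!hand, .data$label == "scratch")
    scr_s <- vapply(starts, function(a)
      overlap_s(a, a + win_s, ann$start_s, ann$end_s), numeric(1))
    label <- ifelse(scr_s > 1.0, "scratch", "non-scratch")
  }
  wl <- as.integer(round(win_s * rate))
  amat <- as.matrix(linear[, c("X", "Y", "Z")])
  slices_a <- lapply(starts, function(a) {
    i0 <- round(a * rate) + 1L
    amat[i0:(i0 + wl - 1L), , drop = FALSE]
  })
  slices_g <- if (is.null(gyro)) vector("list", length(starts)) else {
    gmat <- as.matrix(gyro)[, 1:3, drop = FALSE]
    lapply(starts, function(a) {
      i0 <- round(a * rate) + 1L
      gmat[i0:(i0 + wl - 1L), , drop = FALSE]
    })
  }
  out <- tibble::tibble(hand = hand, start_s = starts, movement_s = mov_s,
                        scratch_s = scr_s, label = label,
                        edge = mov_s < win_s - 1e-9,
                        accel = slices_a, gyro = slices_g)
  structure(out, class = c("ns_windows", class(tibble::tibble())),
            win_s = win_s, rate_hz = rate, mode = mode)
}

empty_windows <- function(win_s, rate) {
  structure(tibble::tibble(hand = character(), start_s = numeric(),
                           movement_s = numeric(), scratch_s = numeric(),
                           label = character(), edge = logical(),
                           accel = list(), gyro = list()),
            class = c("ns_windows", class(tibble::tibble())),
            win_s = win_s, rate_hz = rate, mode = "train")
}

#' Bind window sets (e.g. across hands or nights)
#' @param ... `ns_windows` tibbles.
#' @return A `ns_windows` tibble.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- dplyr::bind_rows(lapply(parts, tibble::as_tibble))
  structure(out, class = c("ns_windows", class(tibble::tibble())),
            win_s = attr(parts[[1]], "win_s"), rate_hz = attr(parts[[1]], "rate_hz"))
}
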