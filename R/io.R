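#' Read and write sensor and annotation files
#'
#' Sensor files are CSV with columns `timestamp` (ISO 8601 UTC with
#' millisecond precision), `ax`, `ay`, `az` (g), `gx`, `gy`, `gz` (deg/s) and
#' `temp_c`. Annotation files are CSV with `start_s`, `end_s` (seconds from
#' the start of the night's recording, millisecond precision), `label`
#' (fixed vocabulary) and `hand`. Writing then reading is lossless at the
#' declared precision.
#'
#' @param recording A `ns_recording`.
#' @param path File path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `ns_recording`.
#' @export
write_recording <- function(recording, path) {
  out <- tibble::as_tibble(recording)
  out$timestamp <- format(as.POSIXct(out$time_s, origin = "1970-01-01", tz = "UTC"),
                          "%Y-%m-%dT%H:%M:%OS3")
  keep <- intersect(c("timestamp", "ax", "ay", "az", "gx", "gy", "gz", "temp_c"),
                    names(out))
  readr::write_csv(out[keep], path, progress = FALSE)
  invisible(path)
}

#' @param hand Which wrist the file belongs to.
#' @param rate_hz Declared rate; `NULL` infers it from the median timestamp gap
#'   (a wrong declaration raises a rate-mismatch error).
#' @rdname write_recording
#' @export
read_recording <- function(path, hand = c("left", "right"), rate_hz = NULL) {
  hand <- match.arg(hand)
  if (!file.exists(path)) ns_abort(paste0("no such file: ", path), "ns_error_io")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"timestamp" %in% names(df)) {
    ns_abort("sensor file must have a 'timestamp' column", "ns_error_schema")
  }
  df$time_s <- as.numeric(as.POSIXct(df$timestamp, tz = "UTC",
                                     format = "%Y-%m-%dT%H:%M:%OS"))
  df$timestamp <- NULL
  if (is.null(rate_hz)) {
    rate_hz <- round(1 / stats::median(diff(df$time_s)))
  }
  as_recording(df, rate_hz = rate_hz, hand = hand)
}

#' @param annotations A `ns_annotations` track.
#' @rdname write_recording
#' @export
write_annotations <- function(annotations, path) {
  out <- tibble::as_tibble(annotations)
  out$start_s <- round(out$start_s, 3)
  out$end_s <- round(out$end_s, 3)
  readr::write_csv(out[c("start_s", "end_s", "label", "hand")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) ns_abort(paste0("no such file: ", path), "ns_error_io")
  as_annotations(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write one simulated night to a directory
#'
#' One sensor CSV per hand plus the annotation CSV.
#'
#' @param night A `ns_night`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_night <- function(night, dir, stem = "night") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    left = file.path(dir, paste0(stem, "_left.csv")),
    right = file.path(dir, paste0(stem, "_right.csv")),
    annotations = file.path(dir, paste0(stem, "_annotations.csv")))
  write_recording(night$left, paths[["left"]])
  write_recording(night$right, paths[["right"]])
  write_annotations(night$annotations, paths[["annotations"]])
  invisible(paths)
}

#' Estimate the clock offset between a recording and its annotation track
#'
#' Device real-time clocks drift and may be configured against a different
#' clock than the annotation source, so annotation timestamps can be off by a
#' constant number of seconds for a night. The offset is estimated at 1-s
#' resolution by maximising the normalised cross-correlation between a
#' per-second activity trace (SD of the accelerometer vector magnitude) and a
#' binary movement-annotated indicator. Within-night drift (typically under
#' +/-1 s for this device class) is deliberately not modelled: the estimate is
#' a single per-night constant.
#'
#' @param recording A `ns_recording`.
#' @param annotations A `ns_annotations` with times in seconds from recording
#'   start.
#' @param max_shift_s Search range (+/- seconds).
#' @param resolution_s Search resolution; fixed at 1 s.
#' @return Integer offset in seconds: add it to annotation times to align them
#'   with the recording.
#' @export
estimate_time_offset <- function(recording, annotations, max_shift_s = 300,
                                 resolution_s = 1) {
  rate <- rec_rate(recording)
  n_sec <- floor(nrow(recording) / rate)
  if (n_sec - max_shift_s < 600) {
    ns_abort("recording and annotations must overlap >= 10 min after any shift",
             "ns_error_align")
  }
  vm <- vm3(as.matrix(recording[, c("ax", "ay", "az")]))
  sec <- rep(seq_len(n_sec), each = rate)[seq_len(min(length(vm), n_sec * rate))]
  act <- tapply(vm[seq_along(sec)], sec, stats::sd)
  act <- as.numeric(act)
  if (stats::sd(act) < 1e-9) {
    ns_abort("flat signal: no activity to align on", "ns_error_align")
  }
  mov <- dplyr::filter(tibble::as_tibble(annotations),
                       .data$hand == rec_hand(recording),
                       .data$label %in% c("scratch", "non-scratch movement",
                                          "out-of-bed"))
  if (nrow(mov) == 0L) {
    ns_abort("no movement-annotated events to align on", "ns_error_align")
  }
  ind <- vapply(seq_len(n_sec) - 1, function(k) {
    overlap_s(k, k + 1, mov$start_s, mov$end_s) >= 0.5
  }, logical(1))
  if (!any(ind)) ns_abort("no movement-annotated events to align on", "ns_error_align")
  shifts <- seq(-max_shift_s, max_shift_s, by = resolution_s)
  score <- vapply(shifts, function(o) {
    # indicator from annotations shifted by +o sits at second k + o
    ks <- seq_len(n_sec)
    src <- ks - o
    ok <- src >= 1 & src <= n_sec
    if (sum(ok) < 600) return(-Inf)
    a <- act[ks[ok]]; b <- as.numeric(ind[src[ok]])
    if (stats::sd(b) < 1e-12 || stats::sd(a) < 1e-12) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
  shifts[which.max(score)]
}

#' Apply a time offset to an annotation track
#'
#' @inheritParams estimate_time_offset
#' @param offset_s Seconds to add to all event times.
#' @return Shifted `ns_annotations`; the applied shift is stored in the
#'   `applied_offset_s` attribute.
#' @export
shift_annotations <- function(annotations, offset_s) {
  out <- tibble::as_tibble(annotations)
  out$start_s <- out$start_s + offset_s
  out$end_s <- out$end_s + offset_s
  out <- as_annotations(out)
  attr(out, "applied_offset_s") <- offset_s
  out
}
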