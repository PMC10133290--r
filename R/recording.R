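#' Sensor recording and annotation containers
#'
#' A recording is a tibble with one row per sample and columns `time_s`
#' (seconds since epoch, monotone), `ax`, `ay`, `az` (acceleration, g),
#' optionally `gx`, `gy`, `gz` (angular rate, deg/s) and `temp_c` (device
#' temperature). The sampling rate and the wrist it was worn on travel as
#' attributes so the object can be piped through the processing verbs.
#'
#' @param data Tibble/data frame with at least `time_s`, `ax`, `ay`, `az`.
#' @param rate_hz Declared sampling rate in Hz.
#' @param hand `"left"` or `"right"`.
#' @return A `ns_recording` tibble.
#' @export
as_recording <- function(data, rate_hz, hand = c("left", "right")) {
  hand <- match.arg(hand)
  data <- tibble::as_tibble(data)
  need <- c("time_s", "ax", "ay", "az")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    ns_abort(paste0("recording is missing columns: ", paste(miss, collapse = ", ")),
             "ns_error_schema")
  }
  if (is.unsorted(data$time_s, strictly = FALSE)) {
    ns_abort("recording timestamps must be monotone non-decreasing", "ns_error_time")
  }
  if (!all(is.finite(data$ax)) || !all(is.finite(data$ay)) || !all(is.finite(data$az))) {
    ns_abort("acceleration values must be finite", "ns_error_schema")
  }
  if (nrow(data) > 1L) {
    gap <- stats::median(diff(data$time_s))
    if (abs(gap - 1 / rate_hz) > 0.1 / rate_hz) {
      ns_abort(sprintf(
        "median inter-sample gap %.4fs disagrees with declared rate %g Hz", gap, rate_hz),
        "ns_error_rate")
    }
  }
  structure(data,
            class = c("ns_recording", class(tibble::tibble())),
            rate_hz = rate_hz, hand = hand)
}

#' @export
#' @rdname as_recording
rec_rate <- function(recording) attr(recording, "rate_hz")

#' @export
#' @rdname as_recording
rec_hand <- function(recording) attr(recording, "hand")

rec_duration <- function(recording) nrow(recording) / rec_rate(recording)

has_gyro <- function(recording) {
  all(c("gx", "gy", "gz") %in% names(recording)) && !anyNA(recording$gx)
}

#' @export
#' @rdname as_recording
annotation_labels <- function() {
  c("scratch", "non-scratch movement", "in-bed still", "out-of-bed")
}

#' Build a validated annotation track
#'
#' Events are half-open `[start_s, end_s)` intervals with labels from the fixed
#' vocabulary (`scratch`, `non-scratch movement`, `in-bed still`,
#' `out-of-bed`); per hand, events must not overlap.
#'
#' @param data Tibble with `start_s`, `end_s`, `label`, `hand`.
#' @return A `ns_annotations` tibble sorted by hand then start.
#' @export
as_annotations <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("start_s", "end_s", "label", "hand")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    ns_abort(paste0("annotations missing columns: ", paste(miss, collapse = ", ")),
             "ns_error_schema")
  }
  bad <- setdiff(unique(data$label), annotation_labels())
  if (length(bad) > 0L) {
    ns_abort(paste0("unknown annotation label(s): ", paste(bad, collapse = ", ")),
             "ns_error_label")
  }
  if (any(data$start_s >= data$end_s)) {
    ns_abort("annotation events must satisfy start < end", "ns_error_time")
  }
  data <- dplyr::arrange(data, .data$hand, .data$start_s)
  for (h in unique(data$hand)) {
    ev <- dplyr::filter(data, .data$hand == h)
    if (nrow(ev) > 1L && any(ev$start_s[-1] < ev$end_s[-nrow(ev)] - 1e-9)) {
      ns_abort(sprintf("overlapping events on hand '%s'", h), "ns_error_overlap")
    }
  }
  structure(data, class = c("ns_annotations", class(tibble::tibble())))
}
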