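new_tso <- function(start_s, end_s, source, valid = TRUE, worn_h = NA_real_) {
  structure(tibble::tibble(start_s = start_s, end_s = end_s, source = source,
                           valid = valid, worn_h = worn_h),
            class = c("ns_tso", class(tibble::tibble())))
}

#' Total sleep opportunity from a reference source
#'
#' Pass-through with validation for TSO windows known from a bed sensor or
#' from annotations. Times are seconds relative to the recording start.
#'
#' @param interval `c(start_s, end_s)`.
#' @param span Optional recording span `c(0, duration_s)` the window must lie
#'   inside.
#' @return A `ns_tso` tibble (one row).
#' @export
tso_from_reference <- function(interval, span = NULL) {
  if (length(interval) != 2L || interval[2] <= interval[1]) {
    ns_abort("TSO interval must satisfy start < end", "ns_error_tso")
  }
  if (!is.null(span) && (interval[1] < span[1] - 1e-9 || interval[2] > span[2] + 1e-9)) {
    ns_abort("TSO interval outside the recording span", "ns_error_tso")
  }
  new_tso(interval[1], interval[2], "reference",
          worn_h = (interval[2] - interval[1]) / 3600)
}

#' Heuristic per-hand total sleep opportunity
#'
#' Estimates the "intend to sleep" window from wrist posture: the z-angle
#' `atan2(az, sqrt(ax^2 + ay^2))` (degrees) is computed on 5-s epoch means,
#' smoothed by a 5-min rolling median, and epochs where successive absolute
#' changes stay under 5 degrees for at least 30 min form sustained-inactivity
#' bouts. The TSO is the span from the first to the last such bout inside the
#' nighttime gate (18:00 to 12:00 by default), and non-wear time inside the
#' span is excluded from the worn-hours accounting.
#'
#' @param recording A 20 Hz calibrated `ns_recording` (gravity retained).
#' @param nonwear Optional `ns_nonwear` intervals for this hand.
#' @param night_gate `c(start_hour, end_hour)` local clock gate; spans
#'   midnight when start > end.
#' @param angle_thresh_deg,bout_min_min Bout criteria (5 degrees / 30 min).
#' @return A `ns_tso` tibble (one row); `valid = FALSE` with a warning when no
#'   sustained-inactivity bout exists in the gate.
#' @export
tso_heuristic <- function(recording, nonwear = NULL, night_gate = c(18, 12),
                          angle_thresh_deg = 5, bout_min_min = 30) {
  rate <- rec_rate(recording)
  dur_s <- nrow(recording) / rate
  nw_s <- if (is.null(nonwear) || nrow(nonwear) == 0L) 0 else
    sum(nonwear$end_s - nonwear$start_s)
  if (dur_s - nw_s < 6 * 3600) {
    ns_abort("TSO heuristic needs at least 6 h of worn data", "ns_error_short")
  }
  ep_len <- 5L * rate
  n_ep <- floor(nrow(recording) / ep_len)
  ep <- rep(seq_len(n_ep), each = ep_len)
  idx <- seq_along(ep)
  mx <- tapply(recording$ax[idx], ep, mean)
  my <- tapply(recording$ay[idx], ep, mean)
  mz <- tapply(recording$az[idx], ep, mean)
  z_ang <- atan2(mz, sqrt(mx^2 + my^2)) * 180 / pi
  zm <- stats::runmed(z_ang, k = 61, endrule = "median")   # 5-min rolling median
  still <- c(FALSE, abs(diff(zm)) < angle_thresh_deg)
  # clock gate per epoch
  ep_t <- recording$time_s[1] + (seq_len(n_ep) - 1) * 5
  hrs <- (ep_t %% 86400) / 3600
  in_gate <- if (night_gate[1] > night_gate[2]) {
    hrs >= night_gate[1] | hrs < night_gate[2]
  } else hrs >= night_gate[1] & hrs < night_gate[2]
  flags <- still & in_gate
  runs <- runs_from_flags(flags, step = 5)
  runs <- runs[runs$end_s - runs$start_s >= bout_min_min * 60, , drop = FALSE]
  if (nrow(runs) == 0L) {
    warning("no sustained-inactivity bout found: empty TSO", call. = FALSE)
    return(new_tso(NA_real_, NA_real_, paste0("heuristic-", rec_hand(recording)),
                   valid = FALSE))
  }
  start_s <- min(runs$start_s)
  end_s <- max(runs$end_s)
  nw_in <- if (is.null(nonwear) || nrow(nonwear) == 0L) 0 else
    overlap_s(start_s, end_s, nonwear$start_s, nonwear$end_s)
  new_tso(start_s, end_s, paste0("heuristic-", rec_hand(recording)),
          worn_h = (end_s - start_s - nw_in) / 3600)
}

#' Combine per-hand TSO windows
#'
#' With two valid hands the combined window is the union when the windows
#' overlap (intending to sleep is a per-subject state, so missing motion on
#' one wrist should not truncate it); discordant windows fall back to the
#' longer one with a warning. With a single valid hand -- a subject wearing
#' one device -- that hand's window is used alone.
#'
#' @param left,right `ns_tso` rows (or `NULL`).
#' @return A combined `ns_tso` row; invalid when both inputs are invalid.
#' @export
combine_hands <- function(left, right) {
  lv <- !is.null(left) && isTRUE(left$valid[1])
  rv <- !is.null(right) && isTRUE(right$valid[1])
  if (!lv && !rv) return(new_tso(NA_real_, NA_real_, "combined", valid = FALSE))
  if (lv && !rv) return(new_tso(left$start_s, left$end_s, "combined",
                                worn_h = left$worn_h))
  if (!lv && rv) return(new_tso(right$start_s, right$end_s, "combined",
                                worn_h = right$worn_h))
  overlap <- left$start_s < right$end_s && right$start_s < left$end_s
  if (overlap) {
    s <- min(left$start_s, right$start_s)
    e <- max(left$end_s, right$end_s)
    return(new_tso(s, e, "combined", worn_h = (e - s) / 3600))
  }
  warning("discordant per-hand TSO windows: using the longer one", call. = FALSE)
  if (left$end_s - left$start_s >= right$end_s - right$start_s) {
    new_tso(left$start_s, left$end_s, "combined", worn_h = left$worn_h)
  } else {
    new_tso(right$start_s, right$end_s, "combined", worn_h = right$worn_h)
  }
}
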