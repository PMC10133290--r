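# Internal helpers shared across modules.

ns_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "nightscratch_error"), ...)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Centered rolling mean/SD with window `w` samples; NA at edges.
roll_mean <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

roll_sd <- function(x, w) {
  m1 <- roll_mean(x, w)
  m2 <- roll_mean(x^2, w)
  v <- pmax(m2 - m1^2, 0) * w / (w - 1)
  sqrt(v)
}

vm3 <- function(m) sqrt(rowSums(m^2))

# Total overlap (seconds) of half-open [a, b) with intervals (vectors start, end).
overlap_s <- function(a, b, start, end) {
  if (length(start) == 0L) return(0)
  sum(pmax(0, pmin(b, end) - pmax(a, start)))
}

# Collapse a logical vector (per-second flags) into a tibble of half-open runs.
runs_from_flags <- function(flag, step = 1) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  tibble::tibble(start_s = starts[keep] * step, end_s = ends[keep] * step)
}

# Merge touching/overlapping half-open intervals given as a tibble(start_s, end_s).
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- dplyr::arrange(iv, .data$start_s)
  out_s <- iv$start_s[1]; out_e <- iv$end_s[1]
  starts <- c(); ends <- c()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start_s[i] <= out_e) {
      out_e <- max(out_e, iv$end_s[i])
    } else {
      starts <- c(starts, out_s); ends <- c(ends, out_e)
      out_s <- iv$start_s[i]; out_e <- iv$end_s[i]
    }
  }
  tibble::tibble(start_s = c(starts, out_s), end_s = c(ends, out_e))
}

guarded_skewness <- function(x) {
  if (length(x) < 2L || stats::sd(x) < 1e-12) return(0)
  e1071::skewness(x, type = 1)
}

guarded_kurtosis <- function(x) {
  if (length(x) < 2L || stats::sd(x) < 1e-12) return(0)
  e1071::kurtosis(x, type = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-phase filtering with mirror padding so startup transients do not leak
# into the retained samples.
zp_filter <- function(bf, x, pad = NULL) {
  n <- length(x)
  pad <- min(n - 1L, pad %||% 200L)
  if (pad < 1L) return(as.numeric(signal::filtfilt(bf, x)))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1L):(pad + n)]
}
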