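#' Zero-dimensional sublevel-set persistence diagram of a 1-D series
#'
#' Sweeps the values of a finite series from below: connected components of
#' the sublevel sets are born at local minima (plateaus merged into a single
#' component) and die when they merge with an older component (elder rule:
#' the component with the smaller birth survives). The essential component is
#' closed at the global maximum, giving one pair per local minimum.
#'
#' @param x Finite numeric series.
#' @return A `ns_pd` tibble: `birth`, `death`, `essential`.
#' @export
persistence_diagram <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || !all(is.finite(x))) {
    ns_abort("series must be finite and non-empty", "ns_error_pd")
  }
  core <- pd_core(x)
  ord <- order(core$birth, core$death)
  structure(tibble::new_tibble(list(birth = core$birth[ord],
                                    death = core$death[ord],
                                    essential = core$essential[ord]),
                               nrow = length(ord),
                               class = "ns_pd"))
}

# union-find sweep; returns list(birth, death, essential) unsorted
pd_core <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(birth = x[1], death = x[1], essential = TRUE))
  parent <- integer(n)
  birth <- numeric(n)
  added <- logical(n)
  births_d <- numeric(0)
  deaths_d <- numeric(0)
  ord <- order(x, seq_len(n))
  xo <- x[ord]
  i <- 1L
  while (i <= n) {
    # tie group [i, j]
    j <- i
    v <- xo[i]
    while (j < n && xo[j + 1L] == v) j <- j + 1L
    pending <- ord[i:j]
    while (length(pending) > 0L) {
      progressed <- TRUE
      while (progressed && length(pending) > 0L) {
        progressed <- FALSE
        keep <- rep(TRUE, length(pending))
        for (pi in seq_along(pending)) {
          k <- pending[pi]
          lok <- k > 1L && added[k - 1L]
          rok <- k < n && added[k + 1L]
          if (!lok && !rok) next
          # find roots with path halving
          ln <- 0L
          if (lok) {
            ln <- k - 1L
            while (parent[ln] != ln) { parent[ln] <- parent[parent[ln]]; ln <- parent[ln] }
          }
          rn <- 0L
          if (rok) {
            rn <- k + 1L
            while (parent[rn] != rn) { parent[rn] <- parent[parent[rn]]; rn <- parent[rn] }
          }
          if (ln == 0L || rn == 0L || ln == rn) {
            parent[k] <- max(ln, rn)
          } else {
            if (birth[ln] <= birth[rn]) { elder <- ln; young <- rn }
            else { elder <- rn; young <- ln }
            births_d <- c(births_d, birth[young])
            deaths_d <- c(deaths_d, v)
            parent[young] <- elder
            parent[k] <- elder
          }
          added[k] <- TRUE
          keep[pi] <- FALSE
          progressed <- TRUE
        }
        pending <- pending[keep]
      }
      if (length(pending) > 0L) {
        # lowest-index isolated sample founds a new component
        k <- min(pending)
        parent[k] <- k
        birth[k] <- v
        added[k] <- TRUE
        pending <- pending[pending != k]
      }
    }
    i <- j + 1L
  }
  list(birth = c(births_d, xo[1]),
       death = c(deaths_d, xo[n]),
       essential = c(rep(FALSE, length(births_d)), TRUE))
}

ps_core <- function(b, d) {
  l <- d - b
  m <- (b + d) / 2
  set_stats <- function(v, shift) {
    w <- if (shift) v - min(v) else v
    w <- w[w > 0]
    ent <- if (length(w) == 0L || sum(w) <= 0) 0 else {
      p <- w / sum(w)
      -sum(p * log(p))
    }
    c(mean(v),
      if (length(v) < 2L) 0 else stats::sd(v),
      guarded_skewness(v),
      guarded_kurtosis(v),
      ent)
  }
  c(set_stats(l, shift = FALSE), set_stats(m, shift = TRUE))
}

gpc_core <- function(b, d, sigma_scale = 0.5, grid_n = 256) {
  l <- d - b
  m <- (b + d) / 2
  keep <- l > 0
  if (!any(keep)) return(0)
  l <- l[keep]; m <- m[keep]
  sg <- sigma_scale * l
  lo <- min(b) - 3 * max(sg)
  hi <- max(d) + 3 * max(sg)
  tt <- seq(lo, hi, length.out = grid_n)
  G <- rep(0, grid_n)
  for (i in seq_along(l)) G <- G + l[i] * stats::dnorm(tt, m[i], sg[i])
  dt <- tt[2] - tt[1]
  sqrt(sum((G[-1]^2 + G[-grid_n]^2) / 2) * dt)
}

#' Persistence statistics of a diagram
#'
#' Summary statistics of the lifespans `l_i = d_i - b_i` and midlifes
#' `m_i = (b_i + d_i) / 2`: mean, SD, skewness, kurtosis and Shannon entropy
#' (natural log) of the normalised vector, for each of the two sets -- ten
#' values. Midlifes are shifted to be non-negative before normalising for the
#' entropy. Sets with fewer than two elements have SD/skewness/kurtosis 0; an
#' empty diagram gives ten zeros.
#'
#' @param diagram A `ns_pd` (or tibble with `birth`, `death`).
#' @return Named numeric vector of length 10
#'   (`life_mean`, ..., `mid_entropy`).
#' @export
persistence_statistics <- function(diagram) {
  nm <- c(paste0("life_", c("mean", "sd", "skew", "kurt", "entropy")),
          paste0("mid_", c("mean", "sd", "skew", "kurt", "entropy")))
  if (is.null(diagram) || nrow(diagram) == 0L) {
    return(stats::setNames(rep(0, 10), nm))
  }
  stats::setNames(ps_core(diagram$birth, diagram$death), nm)
}

#' L2 norm of the Gaussian persistence curve
#'
#' The Gaussian persistence curve places, for every diagram point with
#' positive lifespan `l_i`, a Gaussian density centred at its midlife with
#' scale `sigma_scale * l_i`, weighted by the lifespan:
#' `G(t) = sum_i l_i * dnorm(t; m_i, sigma_scale * l_i)`. The feature is the
#' L2 norm of `G` evaluated on a fixed 256-point grid spanning the diagram's
#' value range extended by three of the largest kernel scales (trapezoidal
#' rule). Empty diagrams, or diagrams with no positive lifespan, give 0.
#'
#' @param diagram A `ns_pd`.
#' @param sigma_scale Scale factor for the kernel SD, default 0.5.
#' @param grid_n Number of grid points, default 256.
#' @return Non-negative scalar.
#' @export
gaussian_persistence_curve_norm <- function(diagram, sigma_scale = 0.5,
                                            grid_n = 256) {
  if (is.null(diagram) || nrow(diagram) == 0L) return(0)
  gpc_core(diagram$birth, diagram$death, sigma_scale, grid_n)
}

#' All 11 topological features of a 1-D window
#'
#' Ten persistence statistics plus the Gaussian persistence curve norm, from
#' the 0-dimensional sublevel-set diagram of the series.
#'
#' @param x Finite numeric series.
#' @return Named numeric vector of length 11.
#' @export
tda_features <- function(x) {
  core <- pd_core(x)
  v <- c(ps_core(core$birth, core$death), gpc_core(core$birth, core$death))
  names(v) <- c(paste0("life_", c("mean", "sd", "skew", "kurt", "entropy")),
                paste0("mid_", c("mean", "sd", "skew", "kurt", "entropy")),
                "gpc_norm")
  v
}
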