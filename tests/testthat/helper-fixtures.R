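# Shared fixtures (built lazily, cached for the whole run) and independent
# oracles used across test files.

fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env, inherits = FALSE)
}

# small 4-subject cohort of short nights with separable hand scratches
mini_cohort <- function() get_fixture("mini_cohort", function() {
  simulate_cohort(4, 1, duration_h = 0.2, severity = 12,
                  movement_rate_per_h = 12, finger_frac = 0, seed = 5)
})

mini_windows <- function() get_fixture("mini_windows", function() {
  w <- cohort_windows(mini_cohort(), pipeline_config(hands = "left"))
  w
})

mini_windows_both <- function() get_fixture("mini_windows_both", function() {
  cohort_windows(mini_cohort(), pipeline_config(hands = "left", sensors = "both"))
})

mini_model <- function() get_fixture("mini_model", function() {
  train_scratch_model(mini_windows(), "accel", seed = 1, epochs = 8,
                      rfe_step = 40)
})

# one short night with a single known scratch bout (3 Hz, 0.5 g, 10 s)
bout_night <- function() get_fixture("bout_night", function() {
  ev <- tibble::tibble(label = "scratch", start_s = 100, end_s = 110,
                       hand = "left", freq_hz = 3, amp_g = 0.5,
                       kind = NA_character_)
  simulate_night(night_scenario(duration_h = 0.1, events = ev, seed = 4))
})

quiet_night <- function() get_fixture("quiet_night", function() {
  simulate_night(night_scenario(duration_h = 0.1, seed = 3))
})

# a representative movement window (60 x 3 linear-acceleration slice)
sample_window <- function() get_fixture("sample_window", function() {
  w <- mini_windows()
  w$accel[[which(w$label == "scratch")[1]]]
})

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# Independent level-sweep oracle for the 0-dimensional sublevel diagram:
# recompute connected components of every sublevel set from scratch and track
# births through run containment (a completely different route from the
# union-find sweep in the package).
oracle_pd <- function(x) {
  n <- length(x)
  if (n < 2L) {
    return(data.frame(birth = x[1], death = x[1], essential = TRUE))
  }
  vals <- sort(unique(x))
  lab <- integer(n)               # component label per index, 0 = excluded
  birth_of <- numeric(0)          # birth value per label
  next_lab <- 0L
  pb <- numeric(0); pd <- numeric(0)
  for (v in vals) {
    inc <- x <= v
    # runs of consecutive included indices
    r <- rle(inc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    new_lab <- integer(n)
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      present <- unique(lab[idx])
      present <- present[present != 0L]
      if (length(present) == 0L) {
        next_lab <- next_lab + 1L
        birth_of[next_lab] <- v
        new_lab[idx] <- next_lab
      } else {
        bs <- birth_of[present]
        keep <- present[which.min(bs)]
        dying <- sort(bs)[-1]
        pb <- c(pb, dying); pd <- c(pd, rep(v, length(dying)))
        new_lab[idx] <- keep
      }
    }
    lab <- new_lab
  }
  data.frame(birth = c(pb, min(x)), death = c(pd, max(x)),
             essential = c(rep(FALSE, length(pb)), TRUE))
}

sorted_pairs <- function(df) {
  df <- df[order(df$birth, df$death, df$essential), ]
  rownames(df) <- NULL
  df[, c("birth", "death", "essential")]
}

# build a bare 20 Hz recording from an n x 3 accel matrix
make_rec20 <- function(acc, hand = "left", gyro = NULL, temp = NULL) {
  n <- nrow(acc)
  df <- tibble::tibble(time_s = (seq_len(n) - 1) / 20,
                       ax = acc[, 1], ay = acc[, 2], az = acc[, 3])
  if (!is.null(gyro)) {
    df$gx <- gyro[, 1]; df$gy <- gyro[, 2]; df$gz <- gyro[, 3]
  }
  if (!is.null(temp)) df$temp_c <- rep_len(temp, n)
  as_recording(df, 20, hand)
}
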