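#' Default pipeline configuration
#'
#' One list validated before any stage runs; every stage reads its knobs from
#' here so a config + seed pair reproduces a run exactly.
#'
#' @param ... Overrides of the defaults.
#' @return Validated config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(sensors = "accel", target_hz = 20, calibrate = FALSE,
              gravity = "accel_only", theta_cov = 0.41, theta_sd = 0.013,
              hands = c("left", "right"), target_k = NULL, seed = 1L,
              epochs = 12, rfe_step = 25, threshold = 0.5, out_dir = NULL)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0L) {
    ns_abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
             "ns_error_config")
  }
  cfg[names(ov)] <- ov
  if (!cfg$sensors %in% c("accel", "both")) {
    ns_abort("sensors must be 'accel' or 'both'", "ns_error_config")
  }
  if (!cfg$gravity %in% c("accel_only", "fused")) {
    ns_abort("gravity must be 'accel_only' or 'fused'", "ns_error_config")
  }
  if (cfg$theta_cov <= 0 || cfg$theta_sd <= 0) {
    ns_abort("thresholds must be positive", "ns_error_config")
  }
  cfg
}

prepare_hand <- function(recording, cfg) {
  if (isTRUE(cfg$calibrate)) {
    recording <- autocalibrate(recording)$recording
  }
  rec20 <- resample_recording(recording, cfg$target_hz)
  mov <- detect_movement(rec20, cfg$theta_cov, cfg$theta_sd)
  nw <- detect_nonwear(mov, rec20)
  lin <- if (cfg$gravity == "fused" && has_gyro(rec20)) {
    stat <- !rep(mov$movement, each = cfg$target_hz)[seq_len(nrow(rec20))]
    remove_gravity_fused(rec20, stationary = stat)$linear
  } else {
    remove_gravity_accel(rec20)
  }
  gyr <- if (cfg$sensors == "both") {
    as.matrix(rec20[, c("gx", "gy", "gz")]) * pi / 180
  } else NULL
  list(rec20 = rec20, movement = mov, nonwear = nw, linear = lin, gyro = gyr)
}

#' Labeled training windows for one night
#'
#' @param night A `ns_night`.
#' @param cfg A [pipeline_config()].
#' @return A labeled `ns_windows` across the configured hands.
#' @export
night_windows <- function(night, cfg = pipeline_config()) {
  parts <- list()
  for (h in intersect(cfg$hands, c("left", "right"))) {
    p <- prepare_hand(night[[h]], cfg)
    w <- segment_windows(p$movement, p$linear, gyro = p$gyro,
                         annotations = night$annotations, hand = h,
                         mode = "train")
    if (nrow(w) > 0L) parts[[h]] <- w
  }
  if (length(parts) == 0L) return(empty_windows(3, cfg$target_hz))
  do.call(bind_windows, unname(parts))
}

#' Labeled training windows for a simulated cohort
#'
#' @param cohort Output of [simulate_cohort()].
#' @param cfg A [pipeline_config()].
#' @return A labeled `ns_windows` with `subject` and `night` columns.
#' @export
cohort_windows <- function(cohort, cfg = pipeline_config()) {
  parts <- purrr::pmap(list(cohort$subject, cohort$night, cohort$night_data),
                       function(s, nn, nd) {
    w <- night_windows(nd, cfg)
    if (nrow(w) == 0L) return(NULL)
    w$subject <- s
    w$night <- nn
    w
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- do.call(bind_windows, parts)
  out
}

stage_manifest <- function(stages) {
  tibble::tibble(stage = names(stages),
                 hash = vapply(stages, rlang::hash, ""),
                 completed_at = as.numeric(Sys.time()))
}

#' Training pipeline: cohort to evaluated model
#'
#' Chains ingest, preprocessing, movement detection, window segmentation,
#' feature engineering and model training; evaluates leave-one-subject-out
#' and then fits the final deployable model on all subjects.
#'
#' @param cohort Output of [simulate_cohort()] (or a compatible tibble with
#'   `subject`, `night`, `night_data`).
#' @param cfg A [pipeline_config()].
#' @return List: `model` (`ns_model`), `loso` (`ns_loso`), `windows`,
#'   `manifest`. Artifacts are written under `cfg$out_dir` when set.
#' @export
run_training_pipeline <- function(cohort, cfg = pipeline_config()) {
  windows <- cohort_windows(cohort, cfg)
  loso <- evaluate_loso(windows, cfg$sensors, target_k = cfg$target_k,
                        seed = cfg$seed, epochs = cfg$epochs,
                        rfe_step = cfg$rfe_step)
  model <- train_scratch_model(windows, cfg$sensors, target_k = cfg$target_k,
                               seed = cfg$seed, epochs = cfg$epochs,
                               rfe_step = cfg$rfe_step)
  manifest <- stage_manifest(list(config = cfg, windows = windows,
                                  loso = loso$summary,
                                  model = model$selected))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(loso$folds, file.path(cfg$out_dir, "loso_folds.csv"),
                     progress = FALSE)
    readr::write_csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                     progress = FALSE)
  }
  list(model = model, loso = loso, windows = windows, manifest = manifest)
}

#' Deployment pipeline: nights to per-night endpoints
#'
#' Runs the deployment flow (preprocess, movement filter, non-wear, TSO,
#' non-overlapping tiling, classification, endpoints) on each night.
#'
#' @param model A trained `ns_model`.
#' @param cohort Cohort tibble with `subject`, `night`, `night_data`.
#' @param cfg A [pipeline_config()].
#' @param use_true_tso Use each night's ground-truth TSO (reference mode)
#'   instead of the heuristic.
#' @return List: `endpoints` tibble (one row per night), `manifest`.
#' @export
run_deployment_pipeline <- function(model, cohort, cfg = pipeline_config(),
                                    use_true_tso = TRUE) {
  rows <- purrr::pmap(list(cohort$subject, cohort$night, cohort$night_data),
                      function(s, nn, nd) {
    tso <- if (use_true_tso && !is.null(nd$true_tso)) {
      tso_from_reference(nd$true_tso)
    } else NULL
    pr <- predict_night(model, nd, tso = tso, theta_cov = cfg$theta_cov,
                        theta_sd = cfg$theta_sd, threshold = cfg$threshold)
    compute_endpoints(pr, subject = s, night = nn)
  })
  endpoints <- dplyr::bind_rows(rows)
  manifest <- stage_manifest(list(config = cfg, endpoints = endpoints))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(endpoints, file.path(cfg$out_dir, "endpoints.csv"),
                     progress = FALSE)
  }
  list(endpoints = endpoints, manifest = manifest)
}
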