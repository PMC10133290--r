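#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a leave-one-subject-out evaluation
#'
#' @param x A `ns_loso`.
#' @param ... Unused.
#' @return Long tibble: `subject`, `metric`, `value`.
#' @method tidy ns_loso
#' @export
tidy.ns_loso <- function(x, ...) {
  x$folds |>
    dplyr::select("subject", "prevalence", "auc", "accuracy", "recall",
                  "specificity", "f1", "ppv", "npv") |>
    tidyr::pivot_longer(-"subject", names_to = "metric", values_to = "value")
}

#' @rdname tidy.ns_loso
#' @return For `glance()`: one row per metric with `mean` and `sd`.
#' @method glance ns_loso
#' @export
glance.ns_loso <- function(x, ...) x$summary

#' Tidy a trained ensemble model
#'
#' @param x A `ns_model`.
#' @param ... Unused.
#' @return Tibble of selected features with boosted-tree gain importance.
#' @method tidy ns_model
#' @export
tidy.ns_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster$booster)
  out <- tibble::tibble(feature = x$selected)
  out$gain <- 0
  out$gain[match(imp$Feature, out$feature)] <- imp$Gain
  dplyr::arrange(out, dplyr::desc(.data$gain))
}

#' @rdname tidy.ns_model
#' @method glance ns_model
#' @export
glance.ns_model <- function(x, ...) {
  tibble::tibble(sensors = x$sensors, n_selected = length(x$selected),
                 max_depth = x$booster$params$max_depth,
                 scale_pos_weight = x$booster$params$scale_pos_weight,
                 val_auc = x$booster$params$val_auc,
                 threshold = x$threshold, seed = x$seed)
}

#' Tidy a persistence diagram
#'
#' @param x A `ns_pd`.
#' @param ... Unused.
#' @return Tibble with `birth`, `death`, `lifespan`, `midlife`, `essential`.
#' @method tidy ns_pd
#' @export
tidy.ns_pd <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(lifespan = .data$death - .data$birth,
                  midlife = (.data$birth + .data$death) / 2)
}
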