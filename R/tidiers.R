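# broom-style tidiers for fitted/derived objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mAP distribution into one row per resample
#'
#' @param x A `map_distribution`.
#' @param ... Unused.
#' @return Tibble: `resample`, `average_precision`, condition columns.
#' @export
tidy.map_distribution <- function(x, ...) {
  cond <- x$condition
  tibble::tibble(
    compound = if (is.null(cond)) "DMSO(null)" else cond$compound,
    dose_uM = if (is.null(cond)) NA_real_ else cond$dose_uM,
    timepoint_h = if (is.null(cond)) NA_real_ else cond$timepoint_h,
    resample = seq_along(x$values),
    average_precision = x$values
  )
}

#' One-row summary of a mAP distribution
#'
#' @param x A `map_distribution`.
#' @param ... Unused.
#' @return Tibble: mean/sd/quantiles of the resampled AP values, status.
#' @export
glance.map_distribution <- function(x, ...) {
  tibble::tibble(
    n_resamples = length(x$values),
    map_mean = if (length(x$values)) mean(x$values) else NA_real_,
    map_sd = if (length(x$values) > 1) stats::sd(x$values) else NA_real_,
    map_q025 = if (length(x$values)) quantile(x$values, 0.025, names = FALSE)
               else NA_real_,
    map_q975 = if (length(x$values)) quantile(x$values, 0.975, names = FALSE)
               else NA_real_,
    status = x$status
  )
}

#' Per-class metrics of a MoA report
#'
#' @param x A `moa_report`.
#' @param ... Unused.
#' @return Tibble with one row per class: support, precision, recall, F1.
#' @export
tidy.moa_report <- function(x, ...) {
  x$per_class
}

#' One-row summary of a MoA report
#'
#' @param x A `moa_report`.
#' @param ... Unused.
#' @return Tibble: `f1_weighted`, `accuracy`, `top3_accuracy`, `n_compounds`.
#' @export
glance.moa_report <- function(x, ...) {
  tibble::tibble(
    f1_weighted = x$f1_weighted,
    accuracy = x$accuracy,
    top3_accuracy = x$top3_accuracy,
    n_compounds = x$n_compounds
  )
}

#' Coefficients of a linear MoA probe
#'
#' @param x A `moa_probe`.
#' @param ... Unused.
#' @return Tibble: `class`, `term` (feature or intercept), `estimate`.
#' @export
tidy.moa_probe <- function(x, ...) {
  purrr::map_dfr(seq_along(x$classes), function(i) {
    tibble::tibble(
      class = x$classes[i],
      term = c("(Intercept)", x$feature_names),
      estimate = c(x$intercepts[i], x$beta[i, ])
    )
  })
}
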