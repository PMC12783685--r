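# Nuclei-count activity baseline: DMSO Z-transform, percentile bootstrap CI
# of the median, and % Inhibition.

#' Z-transform nuclei counts against DMSO statistics
#'
#' Per measurement -- each (plate, timepoint) group -- counts are
#' transformed to `z = (count - mean_DMSO) / sd_DMSO` using that group's
#' DMSO wells, so DMSO-normalized counts centre at zero. FOV-level records
#' are kept unaggregated.
#'
#' @param counts A count tibble (see [validate_counts()]).
#' @return The tibble with an added `nuclei_count_z` column.
#' @export
z_transform_counts <- function(counts) {
  validate_counts(counts)
  grp <- paste(counts$Metadata_plate, counts$Metadata_timepoint_h, sep = "\r")
  z <- numeric(nrow(counts))
  for (g in unique(grp)) {
    rows <- which(grp == g)
    dmso <- rows[counts$Metadata_role[rows] == "negative_control"]
    if (length(dmso) < 2) {
      abort(paste0("measurement ", gsub("\r", " / ", g),
                   " has fewer than 2 DMSO count records"),
            class = "mapscreen_group_error")
    }
    mu <- mean(counts$nuclei_count[dmso])
    sdv <- stats::sd(counts$nuclei_count[dmso])
    if (sdv == 0) {
      abort(paste0("zero DMSO count SD in measurement ", gsub("\r", " / ", g)),
            class = "mapscreen_group_error")
    }
    z[rows] <- (counts$nuclei_count[rows] - mu) / sdv
  }
  dplyr::mutate(counts, nuclei_count_z = z)
}

#' Percentile bootstrap confidence interval for the median
#'
#' Resamples `values` with replacement `n_boot` times, takes the median of
#' each resample, and returns the `alpha/2` and `1 - alpha/2` empirical
#' quantiles of the bootstrap medians.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param alpha Two-sided miss probability (default 0.05 for a 95% CI).
#' @param seed Integer seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000, alpha = 0.05,
                                seed = 1L) {
  n <- length(values)
  if (n < 2) {
    abort("bootstrap_median_ci requires at least 2 values",
          class = "mapscreen_domain_error")
  }
  meds <- with_stream(seed, "boot_median", expr = {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    row_medians(matrix(values[idx], nrow = n_boot))
  })
  ci <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  c(lo = ci[1], hi = ci[2])
}

# Row medians without an extra dependency.
row_medians <- function(m) {
  apply(m, 1, stats::median)
}

#' Activity call from normalized nuclei counts
#'
#' Pools all FOV-level Z-transformed counts of one (compound, dose,
#' timepoint) condition -- every replicate, without prior aggregation --
#' bootstraps the 95% CI for their median, and calls the condition active
#' when the CI's upper bound is below zero (DMSO-normalized counts centre
#' at zero by construction).
#'
#' @param counts_z Output of [z_transform_counts()].
#' @param compound,dose_uM,timepoint_h The condition.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param alpha CI miss probability (default 0.05).
#' @param seed Integer seed.
#' @return One-row tibble: `ci_low`, `ci_high`, `is_active`, provenance.
#' @export
call_count_activity <- function(counts_z, compound, dose_uM, timepoint_h,
                                n_boot = 10000, alpha = 0.05, seed = 1L) {
  if (!"nuclei_count_z" %in% names(counts_z)) {
    abort("counts must be Z-transformed first (z_transform_counts)",
          class = "mapscreen_contract_error")
  }
  rows <- condition_wells(counts_z, compound, dose_uM, timepoint_h)
  if (length(rows) < 2) {
    abort("condition has fewer than 2 normalized count records",
          class = "mapscreen_domain_error")
  }
  ci <- bootstrap_median_ci(counts_z$nuclei_count_z[rows], n_boot = n_boot,
                            alpha = alpha,
                            seed = hash_seed(seed, compound, dose_uM,
                                             timepoint_h))
  tibble::tibble(
    compound = compound, dose_uM = dose_uM, timepoint_h = timepoint_h,
    median_z = stats::median(counts_z$nuclei_count_z[rows]),
    ci_low = ci[["lo"]], ci_high = ci[["hi"]],
    is_active = ci[["hi"]] < 0,
    n_records = length(rows), n_boot = n_boot, seed = seed
  )
}

#' Count-based activity calls for every treatment condition
#'
#' @param counts_z Output of [z_transform_counts()].
#' @inheritParams call_count_activity
#' @return Tibble with one row per (compound, dose, timepoint).
#' @export
count_activity_map <- function(counts_z, n_boot = 10000, alpha = 0.05,
                               seed = 1L) {
  counts_z |>
    dplyr::filter(.data$Metadata_role == "treatment") |>
    dplyr::distinct(compound = .data$Metadata_compound,
                    dose_uM = .data$Metadata_dose_uM,
                    timepoint_h = .data$Metadata_timepoint_h) |>
    dplyr::arrange(.data$compound, .data$dose_uM, .data$timepoint_h) |>
    purrr::pmap_dfr(function(compound, dose_uM, timepoint_h) {
      call_count_activity(counts_z, compound, dose_uM, timepoint_h,
                          n_boot = n_boot, alpha = alpha, seed = seed)
    })
}

#' Percent inhibition of a viability metric relative to DMSO
#'
#' `%Inhibition = 100 * (mean(Metric_DMSO) - Metric_compound) /
#' mean(Metric_DMSO)`, where the metric is typically a nuclei count or a
#' confluency fraction.
#'
#' @param compound_metric Scalar metric value for the compound well(s).
#' @param dmso_metrics Numeric vector of DMSO metric values.
#' @return Percent inhibition (0 when the compound equals the DMSO mean,
#'   100 when the metric is fully suppressed).
#' @export
inhibition_effect <- function(compound_metric, dmso_metrics) {
  m <- mean(dmso_metrics)
  if (m == 0) {
    abort("mean DMSO metric is zero", class = "mapscreen_domain_error")
  }
  100 * (m - compound_metric) / m
}
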