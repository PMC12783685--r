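#' @importFrom rlang .data abort warn inform
#' @importFrom stats median sd quantile rnorm rpois runif var predict setNames
#' @importFrom utils head
NULL

# Reserved metadata columns, in canonical order. Everything else is a feature.
METADATA_COLS <- c(
  "Metadata_plate", "Metadata_replica", "Metadata_well", "Metadata_fov",
  "Metadata_timepoint_h", "Metadata_compound", "Metadata_dose_uM",
  "Metadata_moa", "Metadata_role"
)

#' Feature column names of a profile table
#'
#' Every column whose name does not start with `Metadata_` is a feature.
#' Column order is preserved.
#'
#' @param profiles A profile tibble.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(profiles) {
  setdiff(names(profiles), grep("^Metadata_", names(profiles), value = TRUE))
}

#' Extract the feature matrix of a profile table
#'
#' @param profiles A profile tibble.
#' @return Numeric matrix, one row per profile row.
#' @export
feature_matrix <- function(profiles) {
  as.matrix(profiles[feature_names(profiles)])
}

#' Validate a profile table
#'
#' Checks the reserved metadata columns, requires at least one feature column,
#' requires all feature values to be finite numerics, and checks well-id
#' syntax (row letter plus two-digit column, e.g. "A01") and the DMSO
#' conventions: `Metadata_role == "negative_control"` iff the compound is
#' DMSO, and DMSO rows carry a missing dose.
#'
#' @param profiles A tibble to validate.
#' @return `profiles`, invisibly, if valid; otherwise an error.
#' @export
validate_profiles <- function(profiles) {
  missing_cols <- setdiff(METADATA_COLS, names(profiles))
  if (length(missing_cols) > 0) {
    abort(
      paste0("profile table is missing metadata column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "mapscreen_schema_error"
    )
  }
  feats <- feature_names(profiles)
  if (length(feats) == 0) {
    abort("profile table has no feature columns",
          class = "mapscreen_schema_error")
  }
  for (f in feats) {
    col <- profiles[[f]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      abort(
        paste0("feature column '", f, "' is not numeric (first bad row: ",
               ifelse(is.na(bad), 1L, bad), ")"),
        class = "mapscreen_parse_error"
      )
    }
    if (anyNA(col) || any(!is.finite(col))) {
      abort(paste0("feature column '", f, "' contains NA or non-finite values"),
            class = "mapscreen_validation_error")
    }
  }
  bad_wells <- !grepl("^[A-P][0-9]{2}$", profiles$Metadata_well)
  if (any(bad_wells)) {
    abort(paste0("malformed well id(s), e.g. '",
                 profiles$Metadata_well[which(bad_wells)[1]],
                 "' (expected row letter + 2-digit column, like 'A01')"),
          class = "mapscreen_validation_error")
  }
  is_dmso <- profiles$Metadata_compound == "DMSO"
  is_neg <- profiles$Metadata_role == "negative_control"
  if (any(is_dmso != is_neg)) {
    abort("Metadata_role must be 'negative_control' exactly for DMSO rows",
          class = "mapscreen_validation_error")
  }
  if (any(!is.na(profiles$Metadata_dose_uM[is_dmso]))) {
    abort("DMSO rows must carry a missing Metadata_dose_uM",
          class = "mapscreen_validation_error")
  }
  if (any(is.na(profiles$Metadata_dose_uM[!is_dmso]))) {
    abort("treatment rows must carry a numeric Metadata_dose_uM",
          class = "mapscreen_validation_error")
  }
  invisible(profiles)
}

#' Granularity of a profile table
#'
#' `"fov"` when per-field-of-view rows are present (non-missing
#' `Metadata_fov`), `"well"` when all rows are well-aggregated.
#'
#' @param profiles A profile tibble.
#' @return `"fov"` or `"well"`.
#' @export
profile_granularity <- function(profiles) {
  if (all(is.na(profiles$Metadata_fov))) "well" else "fov"
}

#' Read a profile table from CSV or Parquet
#'
#' The file must contain the nine reserved metadata columns
#' (`Metadata_plate`, `Metadata_replica`, `Metadata_well`, `Metadata_fov`,
#' `Metadata_timepoint_h`, `Metadata_compound`, `Metadata_dose_uM`,
#' `Metadata_moa`, `Metadata_role`) plus at least one numeric feature column.
#'
#' @param path File path.
#' @param format `"csv"` or `"parquet"`; defaults to the file extension.
#' @return A validated profile tibble.
#' @export
read_profiles <- function(path, format = c("auto", "csv", "parquet")) {
  format <- resolve_format(path, match.arg(format))
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mapscreen_io_error")
  }
  tbl <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    dplyr::as_tibble(arrow::read_parquet(path))
  }
  tbl <- coerce_profile_types(tbl)
  validate_profiles(tbl)
  tbl
}

#' Write a profile table to CSV or Parquet
#'
#' @param profiles A valid profile tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"parquet"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("auto", "csv", "parquet")) {
  format <- resolve_format(path, match.arg(format))
  if (nrow(profiles) > 0) validate_profiles(profiles)
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(profiles, path, progress = FALSE)
    } else {
      arrow::write_parquet(profiles, path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write '", path, "': ", conditionMessage(ok)),
          class = "mapscreen_io_error")
  }
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("parquet", "pq")) "parquet" else "csv"
}

# Stabilise column types after I/O: readr may read an all-NA dose column as
# logical, or a numeric-looking plate id as numeric.
coerce_profile_types <- function(tbl) {
  chr_cols <- intersect(
    c("Metadata_plate", "Metadata_replica", "Metadata_well",
      "Metadata_compound", "Metadata_moa", "Metadata_role"),
    names(tbl)
  )
  for (cc in chr_cols) tbl[[cc]] <- as.character(tbl[[cc]])
  for (nc in intersect(c("Metadata_timepoint_h", "Metadata_dose_uM"), names(tbl))) {
    tbl[[nc]] <- as.numeric(tbl[[nc]])
  }
  if ("Metadata_fov" %in% names(tbl)) {
    tbl$Metadata_fov <- as.integer(tbl$Metadata_fov)
  }
  # a zero-row CSV leaves feature columns typeless (logical); make them numeric
  if (nrow(tbl) == 0) {
    for (f in setdiff(names(tbl), grep("^Metadata_", names(tbl), value = TRUE))) {
      tbl[[f]] <- as.numeric(tbl[[f]])
    }
  }
  tbl
}

#' Aggregate a per-FOV (or per-tile) profile table to well level
#'
#' Collapses all rows sharing (plate, replica, well, timepoint) to one row
#' per well using the chosen statistic per feature. Treatment metadata must
#' be consistent within each well group.
#'
#' @param profiles A profile tibble at fov granularity.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return A well-level profile tibble (`Metadata_fov` is `NA`).
#' @export
aggregate_to_well <- function(profiles, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  validate_profiles(profiles)
  if (profile_granularity(profiles) == "well") return(profiles)
  stat_fun <- if (statistic == "median") stats::median else base::mean

  key_cols <- c("Metadata_plate", "Metadata_replica", "Metadata_well",
                "Metadata_timepoint_h")
  treat_cols <- c("Metadata_compound", "Metadata_dose_uM", "Metadata_moa",
                  "Metadata_role")
  feats <- feature_names(profiles)

  conflicts <- profiles |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(key_cols, treat_cols)))) |>
    dplyr::count(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(
      paste0("conflicting treatment metadata within well group ",
             paste(unlist(conflicts[1, key_cols]), collapse = "/")),
      class = "mapscreen_integrity_error"
    )
  }

  profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key_cols, treat_cols)))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(feats), stat_fun),
      .groups = "drop"
    ) |>
    dplyr::mutate(Metadata_fov = NA_integer_) |>
    dplyr::select(dplyr::all_of(c(METADATA_COLS, feats)))
}

#' Read a nuclei-count table from CSV or Parquet
#'
#' Same metadata schema as profile tables, with a `nuclei_count` column
#' (non-negative integers) and an optional `confluency` column in `[0, 1]`.
#'
#' @inheritParams read_profiles
#' @return A validated count tibble.
#' @export
read_counts <- function(path, format = c("auto", "csv", "parquet")) {
  format <- resolve_format(path, match.arg(format))
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "mapscreen_io_error")
  }
  tbl <- if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    dplyr::as_tibble(arrow::read_parquet(path))
  }
  tbl <- coerce_profile_types(tbl)
  validate_counts(tbl)
  tbl
}

#' Validate a nuclei-count table
#'
#' @param counts A count tibble.
#' @return `counts`, invisibly, if valid.
#' @export
validate_counts <- function(counts) {
  missing_cols <- setdiff(c(METADATA_COLS, "nuclei_count"), names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0("count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mapscreen_schema_error")
  }
  if (any(counts$nuclei_count < 0) || anyNA(counts$nuclei_count)) {
    abort("nuclei_count must be non-negative and non-missing",
          class = "mapscreen_validation_error")
  }
  if ("confluency" %in% names(counts)) {
    cf <- counts$confluency
    if (any(cf < 0 | cf > 1, na.rm = TRUE)) {
      abort("confluency must lie in [0, 1]",
            class = "mapscreen_validation_error")
    }
  }
  dup <- counts |>
    dplyr::count(.data$Metadata_plate, .data$Metadata_replica,
                 .data$Metadata_well, .data$Metadata_fov,
                 .data$Metadata_timepoint_h) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("duplicate (plate, replica, well, fov, timepoint) record in count table",
          class = "mapscreen_validation_error")
  }
  invisible(counts)
}
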