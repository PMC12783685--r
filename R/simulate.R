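# Deterministic child RNG streams ---------------------------------------------

# Polynomial rolling hash of a key string, folded with the master seed into a
# 31-bit seed. Keyed streams make draws for one purpose/level independent of
# how many compounds or plates exist elsewhere in the design.
hash_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_stream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(hash_seed(seed, ...))
  force(expr)
}

# Generator configuration -----------------------------------------------------

#' Configuration for the synthetic plate-embedding generator
#'
#' Defaults describe a scaled-down version of a multi-replica brightfield
#' screen: 10 mechanism-of-action (MoA) classes with 3 compounds each laid
#' out on 2 shared-layout 384-well plates, run in 3 complete experimental
#' replicas, imaged at 4 fields of view and 5 timepoints (4--20 h), dosed at
#' 0.156, 0.625, 2.5 and 10 uM. Treatment effects follow a Hill dose
#' response times a linear time ramp along a compound-specific unit
#' direction; additive plate, replica and (replica, fov) offsets emulate
#' technical batch effects; per-FOV nuclei counts are Poisson with a
#' dose-dependent inhibition of the mean.
#'
#' @param n_moa Number of MoA classes.
#' @param compounds_per_moa Compounds per class.
#' @param n_plates Plates per replica (plate layouts are shared across
#'   replicas, as when the same randomization plate is re-run).
#' @param n_replicas Complete experimental runs.
#' @param wells_per_compound_per_plate Technical replicate wells per
#'   (compound, dose) on each plate.
#' @param n_dmso_wells_per_plate Negative-control wells per plate.
#' @param n_fov Fields of view per well.
#' @param doses_uM Dose grid in micromolar, strictly positive, ascending.
#' @param timepoints_h Imaging timepoints in hours.
#' @param D Embedding dimension.
#' @param sigma_plate,sigma_replica,sigma_fov Standard deviations of the
#'   isotropic Gaussian batch offsets drawn once per plate, per replica and
#'   per (replica, fov).
#' @param sigma_noise Per-record Gaussian noise standard deviation.
#' @param emax_range Range (lo, hi) of the uniform per-compound maximal
#'   effect size.
#' @param ec50_uM Hill EC50 in micromolar.
#' @param hill Hill coefficient.
#' @param direction_jitter Within-MoA spread of compound effect directions
#'   (0 = all compounds in a class share one direction).
#' @param count_base Poisson mean nuclei count per FOV for untreated wells.
#' @param count_inhibition_emax Maximal fractional count inhibition at full
#'   effect, in `[0, 1]`.
#' @param seed Master seed; all draws derive from keyed child streams.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_moa = 10,
                             compounds_per_moa = 3,
                             n_plates = 2,
                             n_replicas = 3,
                             wells_per_compound_per_plate = 2,
                             n_dmso_wells_per_plate = 32,
                             n_fov = 4,
                             doses_uM = c(0.156, 0.625, 2.5, 10),
                             timepoints_h = c(4, 8, 12, 16, 20),
                             D = 64,
                             sigma_plate = 0.5,
                             sigma_replica = 1,
                             sigma_fov = 0.5,
                             sigma_noise = 1,
                             emax_range = c(2, 6),
                             ec50_uM = 0.625,
                             hill = 1,
                             direction_jitter = 0.2,
                             count_base = 150,
                             count_inhibition_emax = 0.6,
                             seed = 1L) {
  cfg <- list(
    n_moa = n_moa, compounds_per_moa = compounds_per_moa,
    n_plates = n_plates, n_replicas = n_replicas,
    wells_per_compound_per_plate = wells_per_compound_per_plate,
    n_dmso_wells_per_plate = n_dmso_wells_per_plate,
    n_fov = n_fov, doses_uM = doses_uM, timepoints_h = timepoints_h,
    D = D, sigma_plate = sigma_plate, sigma_replica = sigma_replica,
    sigma_fov = sigma_fov, sigma_noise = sigma_noise,
    emax_range = emax_range, ec50_uM = ec50_uM, hill = hill,
    direction_jitter = direction_jitter,
    count_base = count_base, count_inhibition_emax = count_inhibition_emax,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  counts <- c(cfg$n_moa, cfg$compounds_per_moa, cfg$n_plates, cfg$n_replicas,
              cfg$wells_per_compound_per_plate, cfg$n_dmso_wells_per_plate,
              cfg$n_fov)
  if (any(counts < 1)) {
    abort("all design counts must be >= 1", class = "mapscreen_config_error")
  }
  if (cfg$D < 2) {
    abort("feature dimension D must be >= 2", class = "mapscreen_config_error")
  }
  if (any(cfg$doses_uM <= 0) || is.unsorted(cfg$doses_uM, strictly = TRUE)) {
    abort("doses must be strictly positive and sorted ascending",
          class = "mapscreen_config_error")
  }
  if (cfg$emax_range[1] > cfg$emax_range[2]) {
    abort("emax_range lo must not exceed hi", class = "mapscreen_config_error")
  }
  sig <- c(cfg$sigma_plate, cfg$sigma_replica, cfg$sigma_fov, cfg$sigma_noise)
  if (any(sig < 0)) {
    abort("sigma_* must be non-negative", class = "mapscreen_config_error")
  }
  if (cfg$count_inhibition_emax < 0 || cfg$count_inhibition_emax > 1) {
    abort("count_inhibition_emax must lie in [0, 1]",
          class = "mapscreen_config_error")
  }
  invisible(cfg)
}

#' Treatment effect magnitude at a dose and timepoint
#'
#' Hill-form dose response times a linear time ramp:
#' \deqn{e(dose, t) = \frac{dose^h}{dose^h + EC50^h} \cdot \frac{t}{\max t}}
#' so `e` lies in `[0, 1]`, reaching 0.5 at the EC50 at the final timepoint.
#'
#' @param dose_uM Dose in micromolar, positive.
#' @param timepoint_h Timepoint in hours, positive.
#' @param config A [generator_config()].
#' @return Effect magnitude in `[0, 1]`.
#' @export
effect_magnitude <- function(dose_uM, timepoint_h, config) {
  if (any(dose_uM <= 0) || any(timepoint_h <= 0)) {
    abort("dose and timepoint must be positive", class = "mapscreen_domain_error")
  }
  hillterm <- dose_uM^config$hill / (dose_uM^config$hill + config$ec50_uM^config$hill)
  hillterm * pmin(timepoint_h / max(config$timepoints_h), 1)
}

# Deterministic well layout for one plate: compounds x doses each get
# `wells_per_compound_per_plate` wells, then DMSO wells; positions shuffled
# within the plate by a plate-keyed stream.
plate_layout <- function(cfg, plate_id, compounds) {
  trt <- tidyr::expand_grid(
    compound = compounds$compound_id,
    dose_uM = cfg$doses_uM
  ) |>
    dplyr::slice(rep(seq_len(dplyr::n()), each = cfg$wells_per_compound_per_plate))
  layout <- dplyr::bind_rows(
    trt,
    tibble::tibble(compound = "DMSO", dose_uM = NA_real_) |>
      dplyr::slice(rep(1L, cfg$n_dmso_wells_per_plate))
  )
  n_wells <- nrow(layout)
  if (n_wells > 384) {
    abort(paste0("plate layout needs ", n_wells, " wells; max is 384"),
          class = "mapscreen_config_error")
  }
  pos <- with_stream(cfg$seed, "layout", plate_id, expr = sample.int(384, n_wells))
  layout$well <- sprintf("%s%02d", LETTERS[((pos - 1) %/% 24) + 1],
                         ((pos - 1) %% 24) + 1)
  layout$plate <- plate_id
  layout
}

#' Generate a synthetic screen: profiles, nuclei counts and ground truth
#'
#' Simulates per-FOV embedding profiles under the generative model
#' \deqn{x_r = e(dose_r, t_r)\,emax_c\,u_c + b_{plate} + b_{replica} +
#'   b_{replica,fov} + \epsilon_r}
#' where `u_c` is a compound-specific unit direction clustered by MoA,
#' batch offsets are drawn once per level from isotropic Gaussians, and
#' DMSO rows have the treatment term zeroed. Nuclei counts are
#' `Poisson(count_base * (1 - count_inhibition_emax * e(dose, t)))`.
#'
#' @param config A [generator_config()].
#' @return A list with elements `profiles` (fov-level profile tibble),
#'   `counts` (count tibble), `truth` (per (compound, dose, timepoint)
#'   ground-truth tibble with `is_active` flags), `directions`
#'   (compound-by-D matrix of effect directions) and `batch_offsets`
#'   (the realized per-plate, per-replica and per-(replica, fov) offset
#'   vectors, for parameter-recovery checks).
#' @export
generate_dataset <- function(config) {
  cfg <- validate_generator_config(config)
  D <- cfg$D

  n_compounds <- cfg$n_moa * cfg$compounds_per_moa
  moa_labels <- sprintf("MoA_%02d", seq_len(cfg$n_moa))
  compounds <- tibble::tibble(
    compound_id = sprintf("CPD_%03d", seq_len(n_compounds)),
    moa_label = rep(moa_labels, each = cfg$compounds_per_moa)
  )

  # MoA base directions and per-compound jittered unit directions
  moa_dirs <- t(vapply(moa_labels, function(m) {
    v <- with_stream(cfg$seed, "moa_dir", m, expr = rnorm(D))
    v / sqrt(sum(v^2))
  }, numeric(D)))
  dirs <- t(vapply(seq_len(n_compounds), function(i) {
    v <- moa_dirs[match(compounds$moa_label[i], moa_labels), ] +
      cfg$direction_jitter *
        with_stream(cfg$seed, "cpd_dir", compounds$compound_id[i], expr = rnorm(D))
    v / sqrt(sum(v^2))
  }, numeric(D)))
  rownames(dirs) <- compounds$compound_id

  compounds$emax <- vapply(compounds$compound_id, function(cid) {
    with_stream(cfg$seed, "emax", cid,
                expr = runif(1, cfg$emax_range[1], cfg$emax_range[2]))
  }, numeric(1))

  # Batch offsets: one vector per plate, per replica, per (replica, fov)
  plates <- sprintf("P%02d", seq_len(cfg$n_plates))
  replicas <- sprintf("R%d", seq_len(cfg$n_replicas))
  b_plate <- t(vapply(plates, function(p) {
    with_stream(cfg$seed, "b_plate", p, expr = rnorm(D, sd = cfg$sigma_plate))
  }, numeric(D)))
  b_replica <- t(vapply(replicas, function(r) {
    with_stream(cfg$seed, "b_replica", r, expr = rnorm(D, sd = cfg$sigma_replica))
  }, numeric(D)))
  repfov <- tidyr::expand_grid(replica = replicas, fov = seq_len(cfg$n_fov))
  b_fov <- t(vapply(seq_len(nrow(repfov)), function(i) {
    with_stream(cfg$seed, "b_fov", repfov$replica[i], repfov$fov[i],
                expr = rnorm(D, sd = cfg$sigma_fov))
  }, numeric(D)))
  rownames(b_fov) <- paste(repfov$replica, repfov$fov, sep = ":")

  layouts <- dplyr::bind_rows(lapply(plates, plate_layout, cfg = cfg,
                                     compounds = compounds))

  meta <- tidyr::expand_grid(
    replica = replicas,
    timepoint_h = cfg$timepoints_h,
    fov = seq_len(cfg$n_fov),
    layouts
  )

  cpd_idx <- match(meta$compound, compounds$compound_id)  # NA for DMSO
  e_vals <- ifelse(
    is.na(meta$dose_uM), 0,
    effect_magnitude(ifelse(is.na(meta$dose_uM), 1, meta$dose_uM),
                     meta$timepoint_h, cfg)
  )
  mag <- ifelse(is.na(cpd_idx), 0, e_vals * compounds$emax[cpd_idx])

  dir_rows <- matrix(0, nrow(meta), D)
  trt <- !is.na(cpd_idx)
  dir_rows[trt, ] <- dirs[cpd_idx[trt], , drop = FALSE]

  noise <- with_stream(cfg$seed, "noise",
                       expr = matrix(rnorm(nrow(meta) * D, sd = cfg$sigma_noise),
                                     nrow(meta), D))
  feats <- mag * dir_rows +
    b_plate[match(meta$plate, plates), , drop = FALSE] +
    b_replica[match(meta$replica, replicas), , drop = FALSE] +
    b_fov[match(paste(meta$replica, meta$fov, sep = ":"), rownames(b_fov)), ,
          drop = FALSE] +
    noise
  colnames(feats) <- sprintf("emb_%03d", seq_len(D))

  profiles <- tibble::tibble(
    Metadata_plate = meta$plate,
    Metadata_replica = meta$replica,
    Metadata_well = meta$well,
    Metadata_fov = as.integer(meta$fov),
    Metadata_timepoint_h = meta$timepoint_h,
    Metadata_compound = meta$compound,
    Metadata_dose_uM = meta$dose_uM,
    Metadata_moa = ifelse(is.na(cpd_idx), NA_character_,
                          compounds$moa_label[cpd_idx]),
    Metadata_role = ifelse(meta$compound == "DMSO", "negative_control",
                           "treatment")
  ) |>
    dplyr::bind_cols(tibble::as_tibble(feats))

  lambda <- cfg$count_base * (1 - cfg$count_inhibition_emax * e_vals)
  ncounts <- with_stream(cfg$seed, "counts",
                         expr = rpois(nrow(meta), lambda))
  counts <- profiles |>
    dplyr::select(dplyr::all_of(METADATA_COLS)) |>
    dplyr::mutate(
      nuclei_count = as.integer(ncounts),
      confluency = pmin(1, .data$nuclei_count / (2 * cfg$count_base))
    )

  truth <- tidyr::expand_grid(
    compound_id = compounds$compound_id,
    dose_uM = cfg$doses_uM,
    timepoint_h = cfg$timepoints_h
  ) |>
    dplyr::left_join(compounds, by = "compound_id") |>
    dplyr::mutate(
      e = effect_magnitude(.data$dose_uM, .data$timepoint_h, cfg),
      effect_magnitude = .data$emax * .data$e,
      is_active = .data$effect_magnitude >= cfg$sigma_noise / 2
    ) |>
    dplyr::select(dplyr::all_of(c("compound_id", "moa_label", "dose_uM",
                                  "timepoint_h", "emax", "e",
                                  "effect_magnitude", "is_active")))

  validate_profiles(profiles)
  list(profiles = profiles, counts = counts, truth = truth, directions = dirs,
       batch_offsets = list(plate = b_plate, replica = b_replica, fov = b_fov))
}
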