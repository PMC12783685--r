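# Shared fixtures, generated once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

# Hand-built profile tibble: metadata defaults plus explicit feature columns.
make_profiles <- function(features, plate = "P01", replica = "R1",
                          well = NULL, fov = 1L, timepoint_h = 20,
                          compound = "DMSO", dose_uM = NA_real_,
                          moa = NA_character_) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (is.null(well)) well <- sprintf("A%02d", seq_len(n))
  tibble::tibble(
    Metadata_plate = rep_len(plate, n),
    Metadata_replica = rep_len(replica, n),
    Metadata_well = rep_len(well, n),
    Metadata_fov = as.integer(rep_len(fov, n)),
    Metadata_timepoint_h = rep_len(timepoint_h, n),
    Metadata_compound = rep_len(compound, n),
    Metadata_dose_uM = rep_len(dose_uM, n),
    Metadata_moa = rep_len(moa, n),
    Metadata_role = ifelse(rep_len(compound, n) == "DMSO",
                           "negative_control", "treatment")
  ) |>
    dplyr::bind_cols(tibble::as_tibble(features))
}

# Small mixed screen: batch effects + moderate treatment signal.
fix_screen <- function() {
  cached("screen", {
    cfg <- generator_config(
      n_moa = 2, compounds_per_moa = 3, n_plates = 2, n_replicas = 3,
      wells_per_compound_per_plate = 2, n_dmso_wells_per_plate = 8,
      n_fov = 4, doses_uM = c(0.625, 2.5), timepoints_h = c(10, 20),
      D = 16, seed = 42, emax_range = c(4, 6)
    )
    ds <- generate_dataset(cfg)
    list(cfg = cfg, ds = ds)
  })
}

# Strong-effect screen: every condition's effect magnitude >= 3 * sigma_noise,
# full 3-positive / 31-negative scheme satisfiable.
fix_strong <- function() {
  cached("strong", {
    cfg <- generator_config(
      n_moa = 4, compounds_per_moa = 3, n_plates = 2, n_replicas = 3,
      wells_per_compound_per_plate = 2, n_dmso_wells_per_plate = 32,
      n_fov = 4, doses_uM = c(2.5, 10), timepoints_h = c(16, 20),
      D = 32, seed = 11, emax_range = c(5, 7), ec50_uM = 0.625,
      direction_jitter = 0.15
    )
    ds <- generate_dataset(cfg)
    well <- aggregate_to_well(
      normalize_profiles(ds$profiles, "mad_harmony_fov", seed = 1)
    )
    list(cfg = cfg, ds = ds, well = well)
  })
}

# Zero-effect screen (emax = 0): compounds are DMSO in law. 96 wells per
# condition so the conditional mAP distribution (given the realized wells)
# approximates its marginal law, which is what the null-calibration check
# compares against.
fix_null <- function() {
  cached("nulleffect", {
    cfg <- generator_config(
      n_moa = 3, compounds_per_moa = 1, n_plates = 2, n_replicas = 3,
      wells_per_compound_per_plate = 16, n_dmso_wells_per_plate = 64,
      n_fov = 4, doses_uM = 2.5, timepoints_h = 20,
      D = 32, seed = 21, emax_range = c(0, 0)
    )
    ds <- generate_dataset(cfg)
    well <- aggregate_to_well(
      normalize_profiles(ds$profiles, "mad_harmony_fov", seed = 1)
    )
    list(cfg = cfg, ds = ds, well = well)
  })
}

# Strong-signal MoA screen for classification recovery.
fix_moa <- function() {
  cached("moa", {
    cfg <- generator_config(
      n_moa = 10, compounds_per_moa = 3, n_plates = 2, n_replicas = 3,
      wells_per_compound_per_plate = 2, n_dmso_wells_per_plate = 8,
      n_fov = 4, doses_uM = c(0.625, 2.5, 10), timepoints_h = c(16, 20),
      D = 32, seed = 5, emax_range = c(5, 7), direction_jitter = 0.1
    )
    ds <- generate_dataset(cfg)
    well <- aggregate_to_well(
      normalize_profiles(ds$profiles, "mad_harmony_fov", seed = 1)
    )
    list(cfg = cfg, ds = ds, well = well,
         truth = dplyr::distinct(ds$truth, compound_id, moa_label))
  })
}

dmso_only <- function(profiles) {
  dplyr::filter(profiles, Metadata_role == "negative_control")
}
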