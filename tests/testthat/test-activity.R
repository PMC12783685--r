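# Brute-force AP oracle: explicit precision-at-k accumulation.
ap_oracle <- function(labels) {
  total <- 0
  npos <- 0
  for (k in seq_along(labels)) {
    if (labels[k] == 1) {
      npos <- npos + 1
      total <- total + sum(labels[1:k]) / k
    }
  }
  total / npos
}

test_that("average precision matches its definition on canonical cases", {
  expect_equal(average_precision(c(1, 1, 1, rep(0, 31))), 1)
  expect_equal(average_precision(c(0, 1)), 0.5)
  expect_equal(average_precision(c(1, 0, 1)), (1 + 2 / 3) / 2)
  expect_error(average_precision(c(0, 0)), class = "mapscreen_domain_error")
  expect_error(average_precision(c(0, 2)), class = "mapscreen_domain_error")
})

test_that("average precision equals the brute-force oracle on all 20 arrangements", {
  positions <- combn(6, 3)
  for (j in seq_len(ncol(positions))) {
    labels <- rep(0, 6)
    labels[positions[, j]] <- 1
    expect_equal(average_precision(labels), ap_oracle(labels),
                 tolerance = 1e-12)
  }
})

test_that("candidates rank by similarity with the chosen metric", {
  expect_identical(
    rank_candidates(c(1, 0), rbind(c(1, 0)), rbind(c(0, 1)), "cosine"),
    c(1L, 0L)
  )
  # negative euclidean ranks collinear points by distance
  q <- c(0, 0)
  pos <- rbind(c(1, 0))
  neg <- rbind(c(2, 0), c(3, 0))
  expect_identical(
    rank_candidates(q, pos, neg, "negative_euclidean"), c(1L, 0L, 0L)
  )
  expect_error(
    rank_candidates(c(0, 0), rbind(c(1, 0)), rbind(c(0, 1)), "cosine"),
    class = "mapscreen_domain_error"
  )
})

test_that("exact similarity ties are broken uniformly at random", {
  # all candidates identical to the query: the single positive's rank
  # should be uniform over the 4 slots
  q <- c(1, 1)
  pos <- rbind(c(1, 1))
  neg <- rbind(c(1, 1), c(1, 1), c(1, 1))
  ranks <- vapply(1:2000, function(s) {
    which(rank_candidates(q, pos, neg, "cosine", tie_seed = s) == 1L)
  }, integer(1))
  tab <- tabulate(ranks, 4)
  chisq <- sum((tab - 500)^2 / 500)
  expect_lt(chisq, qchisq(0.999, df = 3))
  expect_true(all(tab > 0))
})

test_that("Cohen's d follows the pooled-SD definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 2), c(1, 3)), -1 / sqrt(2), tolerance = 1e-12)
  set.seed(77)
  for (i in 1:25) {
    a <- rnorm(sample(3:20, 1))
    b <- rnorm(sample(3:20, 1))
    expect_equal(cohens_d(a, b), -cohens_d(b, a), tolerance = 1e-12)
  }
  expect_warning(d <- cohens_d(c(1, 1), c(0, 0)),
                 class = "mapscreen_degenerate_scale")
  expect_identical(d, Inf)
  expect_error(cohens_d(1, c(1, 2)), class = "mapscreen_domain_error")
})

test_that("mAP resampling yields bounded values of the configured length", {
  scr <- fix_screen()
  w <- aggregate_to_well(normalize_profiles(scr$ds$profiles,
                                            "mad_harmony_fov", seed = 1))
  sc <- pair_scheme(n_pos = 3, n_neg = 5, n_resamples = 200, seed = 7)
  cd <- sample_map_distribution(w, "CPD_001", 2.5, 20, sc)
  expect_identical(cd$status, "ok")
  expect_length(cd$values, 200)
  expect_true(all(cd$values >= 0 & cd$values <= 1))
  # deterministic given the scheme seed
  cd2 <- sample_map_distribution(w, "CPD_001", 2.5, 20, sc)
  expect_identical(cd$values, cd2$values)
})

test_that("resampling honours the plate and replica constraints", {
  scr <- fix_screen()
  w <- aggregate_to_well(normalize_profiles(scr$ds$profiles, "mad"))
  sc <- pair_scheme(n_pos = 3, n_neg = 5, n_resamples = 50, seed = 3)
  cd <- sample_map_distribution(w, "CPD_002", 2.5, 20, sc, log_draws = TRUE)
  for (draw in cd$draws) {
    q <- draw$query
    expect_true(all(w$Metadata_plate[draw$positives] != w$Metadata_plate[q]))
    expect_true(all(w$Metadata_replica[draw$positives] != w$Metadata_replica[q]))
    expect_true(all(w$Metadata_plate[draw$negatives] == w$Metadata_plate[q]))
    expect_true(all(w$Metadata_replica[draw$negatives] == w$Metadata_replica[q]))
    expect_true(all(w$Metadata_role[draw$negatives] == "negative_control"))
    expect_false(q %in% draw$negatives)
  }
  nd <- sample_null_distribution(w, 20, sc, log_draws = TRUE)
  for (draw in nd$draws) {
    q <- draw$query
    expect_true(all(w$Metadata_plate[draw$positives] != w$Metadata_plate[q]))
    expect_true(all(w$Metadata_replica[draw$positives] != w$Metadata_replica[q]))
    expect_false(q %in% draw$negatives)
  }
})

test_that("conditions without cross-replica positives are skipped, not errored", {
  # single replica: no positive can come from a different replica
  p <- make_profiles(
    matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("emb_001", "emb_002"))),
    well = sprintf("A%02d", 1:20),
    compound = c(rep("CPD_1", 4), rep("DMSO", 16)),
    dose_uM = c(rep(1, 4), rep(NA, 16)),
    fov = NA_integer_
  )
  sc <- pair_scheme(n_pos = 3, n_neg = 5, n_resamples = 10, seed = 1)
  cd <- sample_map_distribution(p, "CPD_1", 1, 20, sc)
  expect_identical(cd$status, "insufficient replicates")
})

test_that("the null distribution matches a random-ranking permutation oracle", {
  # no batch structure, no treatment: ranking against the query is uniform
  cfg <- generator_config(n_moa = 1, compounds_per_moa = 1, n_plates = 2,
                          n_replicas = 3, wells_per_compound_per_plate = 2,
                          n_dmso_wells_per_plate = 16, n_fov = 2,
                          doses_uM = 2.5, timepoints_h = 20, D = 8,
                          sigma_plate = 0, sigma_replica = 0, sigma_fov = 0,
                          seed = 17)
  ds <- generate_dataset(cfg)
  w <- aggregate_to_well(ds$profiles)  # raw features: pure isotropic noise
  sc <- pair_scheme(n_pos = 3, n_neg = 10, n_resamples = 1000, seed = 5)
  nd <- sample_null_distribution(w, 20, sc)
  # Monte-Carlo oracle over random permutations of 3 positives in 13
  set.seed(1234)
  oracle <- replicate(20000, {
    labels <- sample(c(rep(1, 3), rep(0, 10)))
    ap_oracle(labels)
  })
  se <- sqrt(var(oracle) / 20000 + var(nd$values) / length(nd$values))
  expect_lt(abs(mean(nd$values) - mean(oracle)), 3 * se)
})

test_that("strong effects saturate the mAP distribution", {
  strong <- fix_strong()
  sc <- pair_scheme(n_resamples = 300, seed = 5)
  cd <- sample_map_distribution(strong$well, "CPD_001", 10, 20, sc)
  expect_gt(mean(cd$values), 0.95)
})

test_that("activity calls implement the effect-size threshold rule", {
  sc <- pair_scheme(n_resamples = 50, seed = 1)
  mk <- function(vals, cond = list(compound = "X", dose_uM = 1,
                                   timepoint_h = 20)) {
    structure(list(values = vals, condition = cond, scheme = sc,
                   status = "ok"), class = "map_distribution")
  }
  null <- mk(seq(0, 1, length.out = 50), cond = NULL)
  same <- call_activity(mk(seq(0, 1, length.out = 50)), null)
  expect_equal(same$map_es, 0)
  expect_false(same$is_active)
  hot <- call_activity(mk(rep(c(0.999, 1), 25)), null)
  expect_true(hot$is_active)
  # threshold sweep: active count non-increasing in threshold
  es <- hot$map_es
  counts <- vapply(c(0.2, 0.8, 2, es + 1), function(th) {
    sum(call_activity(mk(rep(c(0.999, 1), 25)), null, th)$is_active)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # mismatched schemes are a contract error
  other <- structure(list(values = rep(0.5, 60), condition = NULL,
                          scheme = pair_scheme(n_resamples = 60, seed = 1),
                          status = "ok"), class = "map_distribution")
  expect_error(call_activity(mk(rep(0.5, 50)), other),
               class = "mapscreen_contract_error")
})

test_that("DMSO scores as inactive against its own null", {
  nul <- fix_null()
  a <- sample_null_distribution(nul$well, 20, pair_scheme(seed = 7))
  b <- sample_null_distribution(nul$well, 20, pair_scheme(seed = 104729))
  expect_lt(abs(cohens_d(a$values, b$values)), 0.15)
})

test_that("median mAP-ES is non-decreasing in dose on the strong fixture", {
  strong <- fix_strong()
  calls <- cached("strong_calls", {
    activity_map(strong$well, pair_scheme(seed = 7))
  })
  med <- calls |>
    dplyr::filter(status == "ok") |>
    dplyr::group_by(dose_uM) |>
    dplyr::summarise(med_es = median(map_es)) |>
    dplyr::arrange(dose_uM)
  expect_true(all(diff(med$med_es) >= 0))
})
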