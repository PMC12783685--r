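# Two linearly separable classes plus DMSO, laid out across plates/replicas.
separable_profiles <- function(n_per = 12, gap = 6, seed = 41) {
  set.seed(seed)
  D <- 4
  mk <- function(center, compound, moa, role_dose) {
    X <- matrix(rnorm(n_per * D, sd = 0.3), n_per, D,
                dimnames = list(NULL, sprintf("emb_%03d", 1:D)))
    X <- X + rep(center, each = n_per)
    make_profiles(X, compound = compound,
                  replica = rep(c("R1", "R2"), length.out = n_per),
                  well = sprintf("%s%02d", LETTERS[1:n_per], 1),
                  dose_uM = if (compound == "DMSO") NA_real_ else 10,
                  moa = if (compound == "DMSO") NA_character_ else moa,
                  fov = NA_integer_)
  }
  dplyr::bind_rows(
    mk(c(gap, 0, 0, 0), "CPD_A", "MoA_A"),
    mk(c(0, gap, 0, 0), "CPD_B", "MoA_B"),
    mk(c(0, 0, 0, 0), "DMSO", NA)
  ) |>
    dplyr::mutate(Metadata_well = sprintf("%s%02d",
                                          rep(LETTERS[1:12], 3),
                                          rep(1:3, each = n_per)))
}

test_that("probes separate linearly separable classes perfectly", {
  p <- separable_profiles()
  probe <- train_probe(p, 10, 20)
  expect_setequal(probe$classes, c("DMSO", "MoA_A", "MoA_B"))
  preds <- predict(probe, p)
  labels <- c("DMSO", "MoA_A", "MoA_B")[
    apply(as.matrix(preds[, probe$classes]), 1, which.max)]
  expect_identical(labels[match(c("CPD_A", "CPD_B"), preds$compound)],
                   c("MoA_A", "MoA_B"))
  # probability rows are simplex points
  expect_equal(rowSums(as.matrix(preds[, probe$classes])), rep(1, nrow(preds)),
               tolerance = 1e-9)
  # deterministic refit
  probe2 <- train_probe(p, 10, 20)
  expect_identical(probe$beta, probe2$beta)
})

test_that("pure-noise features yield near-prior predictions", {
  set.seed(55)
  p <- separable_profiles(gap = 0)
  probe <- train_probe(p, 10, 20, lambda = 1)
  preds <- predict(probe, p)
  P <- as.matrix(preds[, probe$classes])
  # with heavy regularization and no signal, probabilities stay near priors
  priors <- c(DMSO = 1 / 3, MoA_A = 1 / 3, MoA_B = 1 / 3)
  expect_lt(max(abs(sweep(P, 2, priors[colnames(P)]))), 0.2)
})

test_that("training requires at least two surviving classes", {
  p <- separable_profiles() |>
    dplyr::filter(Metadata_role == "negative_control")
  expect_error(train_probe(p, 10, 20), class = "mapscreen_domain_error")
})

test_that("activity filtering removes inactive compounds from training", {
  p <- separable_profiles()
  calls <- tibble::tibble(
    compound = c("CPD_A", "CPD_B"), dose_uM = 10, timepoint_h = 20,
    is_active = c(TRUE, FALSE)
  )
  probe <- train_probe(p, 10, 20, activity_calls = calls)
  expect_setequal(probe$classes, c("DMSO", "MoA_A"))
})

test_that("incremental aggregation is a weighted simplex average", {
  mk_pred <- function(dose, pA) {
    tibble::tibble(compound = c("CPD_A", "CPD_B"), dose_uM = dose,
                   timepoint_h = 20, MoA_A = pA, MoA_B = 1 - pA)
  }
  a <- mk_pred(1, c(0.9, 0.2))
  b <- mk_pred(10, c(0.5, 0.6))
  # single condition, weight 1: identity
  one <- incremental_aggregate(list(a), upto_dose_index = 1)
  expect_equal(one$MoA_A, a$MoA_A)
  # weights (1, 0): first condition only
  w10 <- incremental_aggregate(list(a, b), weights = c(1, 0))
  expect_equal(w10$MoA_A, a$MoA_A)
  # identical sets, uniform weights: unchanged
  same <- incremental_aggregate(list(a, a))
  expect_equal(same$MoA_A, a$MoA_A)
  # genuine average
  avg <- incremental_aggregate(list(a, b))
  expect_equal(avg$MoA_A, (a$MoA_A + b$MoA_A) / 2)
  expect_equal(avg$MoA_A + avg$MoA_B, rep(1, 2))
  # dose truncation excludes the higher dose
  low <- incremental_aggregate(list(a, b), upto_dose_index = 1)
  expect_equal(low$MoA_A, a$MoA_A)
  expect_error(incremental_aggregate(list(a, b), weights = c(0, 0)),
               class = "mapscreen_contract_error")
  expect_error(incremental_aggregate(list(a, b), upto_dose_index = 0),
               class = "mapscreen_contract_error")
})

test_that("MoA evaluation matches hand-computed confusion arithmetic", {
  agg <- tibble::tibble(
    compound = sprintf("C%d", 1:6),
    label = c("A", "A", "B", "B", "C", "A"),
    top3 = lapply(1:6, function(i) c("A", "B", "C"))
  )
  truth <- setNames(c("A", "A", "B", "C", "C", "C"), agg$compound)
  rep <- evaluate_moa(agg, truth)
  # brute-force per-class precision/recall
  # A: tp=2, pred=3, support=2 -> P=2/3, R=1, F1=0.8
  # B: tp=1, pred=2, support=1 -> P=1/2, R=1, F1=2/3
  # C: tp=1, pred=1, support=3 -> P=1, R=1/3, F1=1/2
  expect_equal(rep$accuracy, 4 / 6)
  f1w <- (0.8 * 2 + (2 / 3) * 1 + 0.5 * 3) / 6
  expect_equal(rep$f1_weighted, f1w)
  expect_equal(rep$top3_accuracy, 1)  # truth always within the fixed top3
  expect_equal(sum(rep$confusion_matrix), 6)
  expect_equal(unname(rowSums(rep$confusion_matrix)[c("A", "B", "C")]),
               c(2, 1, 3))
})

test_that("perfect and constant predictors give the boundary metrics", {
  cpds <- sprintf("C%02d", 1:20)
  truth <- setNames(rep(sprintf("M%d", 1:10), 2), cpds)
  perfect <- tibble::tibble(compound = cpds, label = unname(truth[cpds]),
                            top3 = lapply(truth[cpds], function(x) x))
  repp <- evaluate_moa(perfect, truth)
  expect_equal(repp$f1_weighted, 1)
  expect_equal(repp$accuracy, 1)
  expect_equal(repp$top3_accuracy, 1)
  cm <- repp$confusion_matrix
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  constant <- tibble::tibble(compound = cpds, label = "M1",
                             top3 = lapply(cpds, function(x) "M1"))
  expect_equal(evaluate_moa(constant, truth)$accuracy, 0.1)
  expect_error(evaluate_moa(perfect, truth[1:3]),
               class = "mapscreen_contract_error")
})

test_that("compound folds partition compounds with stratification", {
  compounds <- tibble::tibble(
    compound_id = sprintf("C%02d", 1:30),
    moa_label = rep(sprintf("M%d", 1:10), each = 3)
  )
  folds <- suppressWarnings(make_compound_folds(compounds, k = 5, seed = 3))
  expect_setequal(folds$compound_id, compounds$compound_id)
  expect_equal(nrow(folds), 30)
  expect_true(all(folds$fold %in% 1:5))
  # deterministic
  folds2 <- suppressWarnings(make_compound_folds(compounds, k = 5, seed = 3))
  expect_identical(dplyr::arrange(folds, compound_id),
                   dplyr::arrange(folds2, compound_id))
  expect_error(make_compound_folds(compounds, k = 1),
               class = "mapscreen_config_error")
})

test_that("cross-validation never leaks a compound between train and test", {
  moa <- fix_moa()
  cv <- cached("moa_cv", suppressWarnings(
    moa_crossvalidate(moa$well, k = 5, seed = 3)
  ))
  # each evaluated compound appears exactly once per condition
  for (p in cv$cond_preds) {
    expect_false(any(duplicated(p$compound)))
  }
  # folds partition the compound set
  expect_equal(sort(unique(cv$folds$compound_id)),
               sort(unique(moa$truth$compound_id)))
  expect_false(any(duplicated(cv$folds$compound_id)))
})

test_that("McNemar's test matches its formula and the exact fallback", {
  truth <- rep("x", 40)
  a <- truth
  expect_equal(mcnemar_test(a, a, truth)$statistic, 0)
  expect_equal(mcnemar_test(a, a, truth)$p_value, 1)
  # b = 10, c = 0 -> statistic 10 (small sample: exact p)
  b_lab <- c(rep("y", 10), rep("x", 30))
  res <- mcnemar_test(a, b_lab, truth)
  expect_equal(res$statistic, 10)
  expect_identical(res$method, "exact_binomial")
  expect_equal(res$p_value, 2 * (0.5^10), tolerance = 1e-12)
  # b + c = 6: compare against enumerated two-sided binomial tail
  a2 <- c(rep("x", 4), rep("y", 2), rep("x", 34))
  b2 <- c(rep("y", 4), rep("x", 2), rep("x", 34))
  res2 <- mcnemar_test(a2, b2, truth)
  expect_equal(res2$b, 4)  # a correct where b is wrong
  expect_equal(res2$c, 2)
  expect_equal(res2$statistic, (4 - 2)^2 / 6)
  exact <- sum(dbinom(0:6, 6, 0.5)[dbinom(0:6, 6, 0.5) <=
                                     dbinom(4, 6, 0.5) + 1e-12])
  expect_equal(res2$p_value, exact, tolerance = 1e-9)
  # large discordance uses the chi-squared reference
  a3 <- c(rep("y", 30), rep("x", 10))
  res3 <- mcnemar_test(a3, rep("x", 40), truth)
  expect_identical(res3$method, "chi_squared")
  expect_equal(res3$p_value, pchisq(30, 1, lower.tail = FALSE))
})
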