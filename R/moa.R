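# Mechanism-of-action classification with per-condition linear probes and
# incremental dose/timepoint aggregation of softmax outputs.

#' Train a linear MoA probe for one (dose, timepoint) condition
#'
#' Fits a multinomial logistic model with ridge (L2) regularization on
#' standardized well-level features. Training wells are those of compounds
#' called active at this condition (when `activity_calls` is supplied;
#' otherwise all compounds), plus all DMSO wells at the timepoint, which
#' form their own "DMSO" class so weak phenotypes can be predicted as
#' vehicle-like.
#'
#' @param profiles Well-level normalized profile tibble.
#' @param dose_uM,timepoint_h The training condition.
#' @param activity_calls Optional [activity_map()] output used to filter
#'   training compounds to active ones at this condition.
#' @param lambda Ridge penalty (default 1e-3).
#' @param seed Integer seed (fit is deterministic; recorded for provenance).
#' @return A `moa_probe` object with the class labels, coefficient matrix,
#'   intercepts and the feature standardization learned on training data.
#' @export
train_probe <- function(profiles, dose_uM, timepoint_h, activity_calls = NULL,
                        lambda = 1e-3, seed = 1L) {
  trt_rows <- which(profiles$Metadata_role == "treatment" &
                      profiles$Metadata_dose_uM == dose_uM &
                      profiles$Metadata_timepoint_h == timepoint_h)
  if (!is.null(activity_calls)) {
    active <- activity_calls |>
      dplyr::filter(.data$dose_uM == !!dose_uM,
                    .data$timepoint_h == !!timepoint_h,
                    .data$is_active)
    trt_rows <- trt_rows[profiles$Metadata_compound[trt_rows] %in%
                           active$compound]
  }
  dmso_rows <- which(profiles$Metadata_role == "negative_control" &
                       profiles$Metadata_timepoint_h == timepoint_h)
  rows <- c(trt_rows, dmso_rows)
  y <- c(profiles$Metadata_moa[trt_rows], rep("DMSO", length(dmso_rows)))
  if (length(unique(y)) < 2) {
    abort("fewer than 2 classes survive activity filtering",
          class = "mapscreen_domain_error")
  }
  X <- feature_matrix(profiles)[rows, , drop = FALSE]
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  # fit along a short descending path: coordinate descent needs warm starts
  # to converge at small penalties
  fit <- with_stream(seed, "probe", dose_uM, timepoint_h, expr = {
    glmnet::glmnet(Xs, factor(y), family = "multinomial", alpha = 0,
                   lambda = lambda * c(1000, 100, 10, 1),
                   standardize = FALSE)
  })
  classes <- fit$classnames
  cf <- stats::coef(fit, s = lambda)
  beta <- t(vapply(classes, function(cl) as.numeric(cf[[cl]])[-1],
                   numeric(ncol(Xs))))
  intercepts <- vapply(classes, function(cl) as.numeric(cf[[cl]])[1],
                       numeric(1))
  structure(
    list(classes = classes, beta = beta, intercepts = intercepts,
         center = ctr, scale = scl, lambda = lambda,
         condition = list(dose_uM = dose_uM, timepoint_h = timepoint_h),
         feature_names = feature_names(profiles), seed = seed),
    class = "moa_probe"
  )
}

#' @export
print.moa_probe <- function(x, ...) {
  cat("<moa_probe> ", length(x$classes), " classes, ",
      ncol(x$beta), " features; condition ", x$condition$dose_uM, " uM / ",
      x$condition$timepoint_h, " h\n", sep = "")
  invisible(x)
}

probe_softmax <- function(probe, X) {
  Xs <- scale(X[, probe$feature_names, drop = FALSE],
              center = probe$center, scale = probe$scale)
  scores <- Xs %*% t(probe$beta) + rep(probe$intercepts, each = nrow(Xs))
  scores <- scores - apply(scores, 1, max)
  e <- exp(scores)
  p <- e / rowSums(e)
  colnames(p) <- probe$classes
  p
}

#' Per-compound class probabilities from one probe
#'
#' Applies the probe's softmax to every well of its condition in
#' `profiles` and averages the softmax outputs over each compound's wells,
#' giving one probability row per compound.
#'
#' @param object A `moa_probe`.
#' @param profiles Well-level profile tibble to predict on.
#' @param compounds Optional subset of compounds to evaluate.
#' @param ... Unused.
#' @return Tibble: `compound`, `dose_uM`, `timepoint_h`, one probability
#'   column per class (rows sum to 1).
#' @export
predict.moa_probe <- function(object, profiles, compounds = NULL, ...) {
  if (!all(object$feature_names %in% names(profiles))) {
    abort("profile features do not match probe features",
          class = "mapscreen_contract_error")
  }
  rows <- which(profiles$Metadata_role == "treatment" &
                  profiles$Metadata_dose_uM == object$condition$dose_uM &
                  profiles$Metadata_timepoint_h == object$condition$timepoint_h)
  if (!is.null(compounds)) {
    rows <- rows[profiles$Metadata_compound[rows] %in% compounds]
  }
  if (length(rows) == 0) {
    return(tibble::tibble(compound = character(0),
                          dose_uM = numeric(0), timepoint_h = numeric(0)))
  }
  p <- probe_softmax(object, as.matrix(profiles[rows, object$feature_names]))
  tibble::tibble(compound = profiles$Metadata_compound[rows]) |>
    dplyr::bind_cols(tibble::as_tibble(p)) |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop") |>
    dplyr::mutate(dose_uM = object$condition$dose_uM,
                  timepoint_h = object$condition$timepoint_h,
                  .after = "compound")
}

#' Train probes and predict for every (dose, timepoint) condition
#'
#' @param train_profiles,eval_profiles Well-level profile tibbles; probes
#'   are trained on the first and applied to the second.
#' @param activity_calls Optional activity filter for training compounds.
#' @param compounds Optional subset of compounds to evaluate.
#' @inheritParams train_probe
#' @return List of per-condition prediction tibbles (see
#'   [predict.moa_probe()]), ordered by ascending dose then timepoint.
#'   Conditions where training fails (fewer than 2 surviving classes) are
#'   dropped with a message.
#' @export
predict_conditions <- function(train_profiles, eval_profiles,
                               activity_calls = NULL, compounds = NULL,
                               lambda = 1e-3, seed = 1L) {
  conditions <- train_profiles |>
    dplyr::filter(.data$Metadata_role == "treatment") |>
    dplyr::distinct(dose_uM = .data$Metadata_dose_uM,
                    timepoint_h = .data$Metadata_timepoint_h) |>
    dplyr::arrange(.data$dose_uM, .data$timepoint_h)
  out <- purrr::pmap(conditions, function(dose_uM, timepoint_h) {
    probe <- tryCatch(
      train_probe(train_profiles, dose_uM, timepoint_h,
                  activity_calls = activity_calls, lambda = lambda,
                  seed = seed),
      mapscreen_domain_error = function(e) NULL
    )
    if (is.null(probe)) {
      inform(paste0("condition ", dose_uM, " uM / ", timepoint_h,
                    " h skipped: fewer than 2 classes after filtering"))
      return(NULL)
    }
    predict(probe, eval_profiles, compounds = compounds)
  })
  purrr::compact(out)
}

#' Incrementally aggregate per-condition MoA predictions across doses
#'
#' Final probabilities for each compound are the weighted average of its
#' per-condition softmax rows over all conditions whose dose index (in the
#' ascending sorted dose grid) does not exceed `upto_dose_index`; every
#' timepoint of an included dose contributes. Labels are ranked by
#' descending aggregated probability.
#'
#' @param cond_preds List of per-condition prediction tibbles from
#'   [predict_conditions()].
#' @param weights `"uniform"` or a non-negative numeric vector, one weight
#'   per included condition, not all zero.
#' @param upto_dose_index Highest dose rank to include (default: all).
#' @return Tibble: `compound`, aggregated probability columns, `label`
#'   (argmax) and `top3` (list column of the 3 highest-probability labels).
#' @export
incremental_aggregate <- function(cond_preds, weights = "uniform",
                                  upto_dose_index = Inf) {
  doses <- sort(unique(vapply(cond_preds, function(p) p$dose_uM[1],
                              numeric(1))))
  keep <- vapply(cond_preds, function(p) {
    match(p$dose_uM[1], doses) <= upto_dose_index
  }, logical(1))
  included <- cond_preds[keep]
  if (length(included) == 0) {
    abort("no conditions included at this dose index",
          class = "mapscreen_contract_error")
  }
  if (identical(weights, "uniform")) {
    w <- rep(1, length(included))
  } else {
    w <- as.numeric(weights)
    if (length(w) != length(included) || any(w < 0) || sum(w) == 0) {
      abort("weights must be non-negative, one per included condition, not all zero",
            class = "mapscreen_contract_error")
    }
  }
  class_cols <- setdiff(names(included[[1]]),
                        c("compound", "dose_uM", "timepoint_h"))
  stacked <- purrr::imap_dfr(included, function(p, i) {
    dplyr::mutate(p, .w = w[[i]])
  })
  agg <- stacked |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(class_cols),
                    ~ sum(.x * .data$.w) / sum(.data$.w)),
      .groups = "drop"
    )
  P <- as.matrix(agg[class_cols])
  ord <- t(apply(P, 1, order, decreasing = TRUE))
  agg |>
    dplyr::mutate(
      label = class_cols[ord[, 1]],
      top3 = lapply(seq_len(nrow(P)),
                    function(i) class_cols[ord[i, seq_len(min(3, ncol(P)))]])
    )
}

#' Evaluate MoA predictions against ground truth
#'
#' Computes support-weighted F1, accuracy, top-3 accuracy, per-class F1 and
#' the confusion matrix over all classes (including the DMSO class).
#'
#' @param aggregated Output of [incremental_aggregate()] (needs `compound`,
#'   `label`, `top3`).
#' @param truth Named character vector or tibble (`compound_id`,
#'   `moa_label`) mapping every evaluated compound to its true class.
#' @return A `moa_report`: list with `f1_weighted`, `accuracy`,
#'   `top3_accuracy`, `per_class` tibble and `confusion_matrix`.
#' @export
evaluate_moa <- function(aggregated, truth) {
  if (is.data.frame(truth)) {
    truth <- setNames(truth$moa_label, truth$compound_id)
  }
  unknown <- setdiff(aggregated$compound, names(truth))
  if (length(unknown) > 0) {
    abort(paste0("no truth label for compound(s): ",
                 paste(head(unknown, 3), collapse = ", ")),
          class = "mapscreen_contract_error")
  }
  y_true <- unname(truth[aggregated$compound])
  y_pred <- aggregated$label
  classes <- sort(union(union(y_true, y_pred), "DMSO"))
  cm <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  per_class <- purrr::map_dfr(classes, function(cl) {
    tp <- cm[cl, cl]
    support <- sum(cm[cl, ])
    prec_den <- sum(cm[, cl])
    prec <- if (prec_den == 0) 0 else tp / prec_den
    rec <- if (support == 0) 0 else tp / support
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble::tibble(class = cl, support = support, precision = prec,
                   recall = rec, f1 = f1)
  })
  scored <- per_class[per_class$support > 0, ]
  top3_hit <- mapply(function(tr, t3) tr %in% t3, y_true, aggregated$top3)
  structure(
    list(
      f1_weighted = sum(scored$f1 * scored$support) / sum(scored$support),
      accuracy = sum(diag(as.matrix(cm))) / length(y_true),
      top3_accuracy = mean(top3_hit),
      per_class = per_class,
      confusion_matrix = unclass(as.matrix(cm)),
      n_compounds = length(y_true)
    ),
    class = "moa_report"
  )
}

#' @export
print.moa_report <- function(x, ...) {
  cat("<moa_report> ", x$n_compounds, " compounds\n",
      "  F1-weighted: ", signif(x$f1_weighted, 4),
      "  accuracy: ", signif(x$accuracy, 4),
      "  top-3: ", signif(x$top3_accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Stratified compound-level cross-validation folds
#'
#' Assigns each compound to one of `k` folds, stratified by MoA class, so
#' all wells and conditions of a compound share a fold and replicate
#' structure never leaks between train and test.
#'
#' @param compounds Tibble with `compound_id` and `moa_label`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Tibble `compound_id`, `moa_label`, `fold`.
#' @export
make_compound_folds <- function(compounds, k = 5, seed = 1L) {
  if (k < 2) abort("k must be >= 2", class = "mapscreen_config_error")
  small <- compounds |>
    dplyr::count(.data$moa_label) |>
    dplyr::filter(.data$n < k)
  if (nrow(small) > 0) {
    warn(paste0("class(es) with fewer than k compounds; folds are best-effort: ",
                paste(small$moa_label, collapse = ", ")),
         class = "mapscreen_stratification_warning")
  }
  with_stream(seed, "folds", expr = {
    compounds |>
      dplyr::group_by(.data$moa_label) |>
      dplyr::mutate(fold = sample(rep_len(sample.int(k), dplyr::n()))) |>
      dplyr::ungroup()
  })
}

#' Compound-stratified k-fold cross-validated MoA classification
#'
#' Splits compounds into `k` MoA-stratified folds, retrains per-condition
#' probes on each training split, predicts the held-out compounds at every
#' condition, and aggregates incrementally across the full dose grid.
#'
#' @param profiles Well-level normalized profile tibble.
#' @param activity_calls Optional activity filter applied to training.
#' @param k Folds (default 5).
#' @param lambda Ridge penalty for the probes.
#' @param seed Integer seed (fold assignment and probes).
#' @return List: `folds`, `cond_preds` (per-condition out-of-fold
#'   predictions), `aggregated` (full-dose incremental aggregation over all
#'   out-of-fold compounds).
#' @export
moa_crossvalidate <- function(profiles, activity_calls = NULL, k = 5,
                              lambda = 1e-3, seed = 1L) {
  compounds <- profiles |>
    dplyr::filter(.data$Metadata_role == "treatment") |>
    dplyr::distinct(compound_id = .data$Metadata_compound,
                    moa_label = .data$Metadata_moa)
  folds <- make_compound_folds(compounds, k = k, seed = seed)
  per_fold <- lapply(seq_len(k), function(f) {
    test_cpds <- folds$compound_id[folds$fold == f]
    if (length(test_cpds) == 0) return(list())
    train <- profiles |>
      dplyr::filter(.data$Metadata_role == "negative_control" |
                      !(.data$Metadata_compound %in% test_cpds))
    predict_conditions(train, profiles, activity_calls = activity_calls,
                       compounds = test_cpds, lambda = lambda, seed = seed)
  })
  # merge fold prediction lists condition-wise
  cond_key <- function(p) paste(p$dose_uM[1], p$timepoint_h[1])
  all_keys <- unique(unlist(lapply(per_fold, function(l) {
    vapply(l, cond_key, character(1))
  })))
  cond_preds <- lapply(all_keys, function(key) {
    dplyr::bind_rows(lapply(per_fold, function(l) {
      hit <- l[vapply(l, cond_key, character(1)) == key]
      if (length(hit) == 0) NULL else hit[[1]]
    }))
  })
  doses <- vapply(cond_preds, function(p) p$dose_uM[1], numeric(1))
  tps <- vapply(cond_preds, function(p) p$timepoint_h[1], numeric(1))
  cond_preds <- cond_preds[order(doses, tps)]
  list(folds = folds, cond_preds = cond_preds,
       aggregated = incremental_aggregate(cond_preds))
}

#' McNemar's test for paired classifier comparison
#'
#' Counts discordant compounds between two classifiers (`b`: A correct and
#' B wrong; `c`: A wrong and B correct) and computes the chi-squared
#' statistic `(b - c)^2 / (b + c)` without continuity correction on one
#' degree of freedom. When `b + c < 25` the p-value comes from the exact
#' two-sided binomial test instead.
#'
#' @param labels_a,labels_b Predicted labels from the two classifiers, in
#'   the same compound order.
#' @param truth True labels, same order.
#' @return One-row tibble: `statistic`, `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(labels_a, labels_b, truth) {
  if (length(labels_a) != length(labels_b) ||
      length(labels_a) != length(truth)) {
    abort("labels_a, labels_b and truth must have equal length",
          class = "mapscreen_contract_error")
  }
  ok_a <- labels_a == truth
  ok_b <- labels_b == truth
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  n <- b + cc
  if (n == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, b = b, c = cc,
                          method = "degenerate"))
  }
  statistic <- (b - cc)^2 / n
  if (n < 25) {
    p <- stats::binom.test(b, n, 0.5)$p.value
    method <- "exact_binomial"
  } else {
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
    method <- "chi_squared"
  }
  tibble::tibble(statistic = statistic, p_value = p, b = b, c = cc,
                 method = method)
}
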