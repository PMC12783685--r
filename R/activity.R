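# Resampled mean-average-precision activity metric with DMSO null
# distribution and Cohen's d effect size.

#' Pair-sampling scheme for mAP resampling
#'
#' Defaults follow the multi-replica retrieval design: each resample draws
#' one query well, 3 positive wells of the same treatment from a different
#' plate and a different experimental replica, and 31 DMSO wells from the
#' query's own measurement; 1000 resamples form the mAP distribution.
#'
#' @param n_pos Positives per resample (default 3).
#' @param n_neg Negatives per resample (default 31).
#' @param n_resamples Number of resamples (default 1000).
#' @param similarity `"cosine"` or `"negative_euclidean"`.
#' @param seed Integer seed; per-condition child streams derive from it.
#' @return A `pair_scheme` list.
#' @export
pair_scheme <- function(n_pos = 3, n_neg = 31, n_resamples = 1000,
                        similarity = c("cosine", "negative_euclidean"),
                        seed = 1L) {
  similarity <- match.arg(similarity)
  if (n_pos < 1 || n_neg < 1 || n_resamples < 1) {
    abort("n_pos, n_neg and n_resamples must all be >= 1",
          class = "mapscreen_config_error")
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         n_resamples = as.integer(n_resamples), similarity = similarity,
         seed = as.integer(seed)),
    class = "pair_scheme"
  )
}

same_scheme <- function(a, b) {
  identical(a[c("n_pos", "n_neg", "n_resamples", "similarity")],
            b[c("n_pos", "n_neg", "n_resamples", "similarity")])
}

#' Average precision of a ranked binary label sequence
#'
#' `AP = (1/P) * sum over positive ranks k of precision@k`, where
#' `precision@k` is the fraction of positives among the first `k` items.
#'
#' @param ranked_labels Binary (0/1) vector, best-ranked first.
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(ranked_labels) {
  labels <- as.integer(ranked_labels)
  if (!all(labels %in% c(0L, 1L))) {
    abort("ranked_labels must be binary", class = "mapscreen_domain_error")
  }
  P <- sum(labels)
  if (P == 0) {
    abort("ranked_labels contains no positives", class = "mapscreen_domain_error")
  }
  k <- seq_along(labels)
  prec_at_k <- cumsum(labels) / k
  sum(prec_at_k[labels == 1L]) / P
}

similarity_to <- function(query, candidates, similarity) {
  if (similarity == "cosine") {
    qn <- sqrt(sum(query^2))
    cn <- sqrt(rowSums(candidates^2))
    if (qn == 0 || any(cn == 0)) {
      abort("zero-norm vector under cosine similarity",
            class = "mapscreen_domain_error")
    }
    as.vector(candidates %*% query) / (cn * qn)
  } else {
    -sqrt(rowSums(sweep(candidates, 2, query)^2))
  }
}

#' Rank positive and negative candidates against a query
#'
#' Candidates are sorted by descending similarity to the query; exact
#' similarity ties are broken by a seeded random shuffle applied before the
#' stable sort, so tied candidates appear in uniformly random order.
#'
#' @param query Numeric feature vector.
#' @param positives,negatives Matrices (rows = candidates) of the same
#'   dimension as `query`.
#' @param similarity `"cosine"` or `"negative_euclidean"`.
#' @param tie_seed Seed for the tie-breaking shuffle.
#' @return Binary label vector in ranked order (1 = positive).
#' @export
rank_candidates <- function(query, positives, negatives,
                            similarity = c("cosine", "negative_euclidean"),
                            tie_seed = 1L) {
  similarity <- match.arg(similarity)
  positives <- rbind(positives)
  negatives <- rbind(negatives)
  candidates <- rbind(positives, negatives)
  labels <- c(rep(1L, nrow(positives)), rep(0L, nrow(negatives)))
  sims <- similarity_to(query, candidates, similarity)
  perm <- with_stream(tie_seed, "tie_break", expr = sample.int(length(sims)))
  ord <- perm[order(sims[perm], decreasing = TRUE)]  # stable within ties
  labels[ord]
}

new_map_distribution <- function(values, condition, scheme, status = "ok",
                                 draws = NULL) {
  structure(
    list(values = values, condition = condition, scheme = scheme,
         status = status, draws = draws),
    class = "map_distribution"
  )
}

#' @export
print.map_distribution <- function(x, ...) {
  cond <- if (is.null(x$condition)) "DMSO null" else {
    paste0(x$condition$compound, " @ ", x$condition$dose_uM, " uM, ",
           x$condition$timepoint_h, " h")
  }
  cat("<map_distribution> ", cond, " [", x$status, "]\n", sep = "")
  if (x$status == "ok") {
    cat("  ", length(x$values), " resamples; mean AP = ",
        signif(mean(x$values), 4), "\n", sep = "")
  }
  invisible(x)
}

# Shared resampling engine. `query_idx` indexes candidate query wells;
# `pos_pool` maps each query index to its eligible positive well rows;
# `neg_pool` maps each query index to its eligible negative (DMSO) rows.
resample_map <- function(X, query_idx, pos_pool, neg_pool, scheme, stream_key,
                         log_draws = FALSE) {
  values <- numeric(scheme$n_resamples)
  draws <- if (log_draws) vector("list", scheme$n_resamples) else NULL
  with_stream(scheme$seed, "map_resample", stream_key, expr = {
    for (r in seq_len(scheme$n_resamples)) {
      qi <- query_idx[[sample.int(length(query_idx), 1)]]
      pos <- pos_pool[[as.character(qi)]]
      neg <- neg_pool[[as.character(qi)]]
      pos_s <- pos[sample.int(length(pos), scheme$n_pos)]
      neg_s <- neg[sample.int(length(neg), scheme$n_neg)]
      labels <- rank_candidates(
        X[qi, ], X[pos_s, , drop = FALSE], X[neg_s, , drop = FALSE],
        similarity = scheme$similarity,
        tie_seed = hash_seed(scheme$seed, stream_key, r)
      )
      values[r] <- average_precision(labels)
      if (log_draws) draws[[r]] <- list(query = qi, positives = pos_s,
                                        negatives = neg_s)
    }
  })
  list(values = values, draws = draws)
}

condition_wells <- function(profiles, compound, dose_uM, timepoint_h) {
  which(profiles$Metadata_compound == compound &
          !is.na(profiles$Metadata_dose_uM) &
          profiles$Metadata_dose_uM == dose_uM &
          profiles$Metadata_timepoint_h == timepoint_h)
}

dmso_wells_at <- function(profiles, timepoint_h) {
  which(profiles$Metadata_role == "negative_control" &
          profiles$Metadata_timepoint_h == timepoint_h)
}

# Eligible positives: same condition, different plate AND different replica.
# Eligible negatives: DMSO wells from the query's own measurement
# (same plate, same replica, same timepoint), excluding the query itself.
build_pools <- function(profiles, cand_idx, dmso_idx, scheme) {
  plates <- profiles$Metadata_plate
  reps <- profiles$Metadata_replica
  pos_pool <- list()
  neg_pool <- list()
  eligible <- integer(0)
  for (qi in cand_idx) {
    pos <- cand_idx[plates[cand_idx] != plates[qi] &
                      reps[cand_idx] != reps[qi]]
    neg <- dmso_idx[plates[dmso_idx] == plates[qi] &
                      reps[dmso_idx] == reps[qi]]
    neg <- setdiff(neg, qi)
    if (length(pos) < scheme$n_pos) next
    if (length(neg) < scheme$n_neg) {
      abort(paste0("plate ", plates[qi], " (replica ", reps[qi],
                   ") has fewer than ", scheme$n_neg, " DMSO wells"),
            class = "mapscreen_sampling_error")
    }
    eligible <- c(eligible, qi)
    pos_pool[[as.character(qi)]] <- pos
    neg_pool[[as.character(qi)]] <- neg
  }
  list(eligible = eligible, pos_pool = pos_pool, neg_pool = neg_pool)
}

#' Resampled mAP distribution for one treatment condition
#'
#' Repeats `n_resamples` times: draw a query well of the condition, draw
#' `n_pos` same-treatment wells from a different plate and a different
#' experimental replica, draw `n_neg` DMSO wells from the query's own
#' measurement, rank all candidates by similarity to the query, and record
#' the average precision of the ranking.
#'
#' @param profiles A normalized, well-level profile tibble.
#' @param compound,dose_uM,timepoint_h The treatment condition.
#' @param scheme A [pair_scheme()].
#' @param log_draws Record the sampled indices of every resample (for
#'   auditing the sampling constraints).
#' @return A `map_distribution`; status `"insufficient replicates"` when no
#'   query well has enough cross-plate, cross-replica positives.
#' @export
sample_map_distribution <- function(profiles, compound, dose_uM, timepoint_h,
                                    scheme = pair_scheme(),
                                    log_draws = FALSE) {
  cand <- condition_wells(profiles, compound, dose_uM, timepoint_h)
  condition <- list(compound = compound, dose_uM = dose_uM,
                    timepoint_h = timepoint_h)
  if (length(cand) == 0) {
    return(new_map_distribution(numeric(0), condition, scheme,
                                status = "no wells"))
  }
  dmso_idx <- dmso_wells_at(profiles, timepoint_h)
  pools <- build_pools(profiles, cand, dmso_idx, scheme)
  if (length(pools$eligible) == 0) {
    return(new_map_distribution(numeric(0), condition, scheme,
                                status = "insufficient replicates"))
  }
  X <- feature_matrix(profiles)
  res <- resample_map(X, pools$eligible, pools$pos_pool, pools$neg_pool,
                      scheme,
                      stream_key = paste(compound, dose_uM, timepoint_h),
                      log_draws = log_draws)
  new_map_distribution(res$values, condition, scheme, draws = res$draws)
}

#' Null mAP distribution from DMSO wells
#'
#' Same resampling as [sample_map_distribution()] with DMSO playing the
#' treatment role: the query is a random DMSO well, positives are `n_pos`
#' DMSO wells from different plates and different replicas, negatives are
#' `n_neg` DMSO wells from the query's own measurement. Stratified per
#' timepoint, pooled over plates and replicas.
#'
#' @inheritParams sample_map_distribution
#' @return A `map_distribution` with `condition = NULL` marking the null.
#' @export
sample_null_distribution <- function(profiles, timepoint_h,
                                     scheme = pair_scheme(),
                                     log_draws = FALSE) {
  dmso_idx <- dmso_wells_at(profiles, timepoint_h)
  if (length(unique(profiles$Metadata_replica[dmso_idx])) < 2) {
    abort("null distribution requires DMSO wells in at least 2 replicas",
          class = "mapscreen_sampling_error")
  }
  pools <- build_pools(profiles, dmso_idx, dmso_idx, scheme)
  if (length(pools$eligible) == 0) {
    return(new_map_distribution(numeric(0), NULL, scheme,
                                status = "insufficient replicates"))
  }
  X <- feature_matrix(profiles)
  res <- resample_map(X, pools$eligible, pools$pos_pool, pools$neg_pool,
                      scheme, stream_key = paste("null", timepoint_h),
                      log_draws = log_draws)
  new_map_distribution(res$values, NULL, scheme, draws = res$draws)
}

#' Cohen's d effect size between two samples
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled standard deviation
#' from unbiased sample variances. A zero pooled SD yields a signed
#' infinity (sign of the mean difference, 0 for equal means) with a
#' warning.
#'
#' @param a,b Numeric vectors of length >= 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) {
    abort("cohens_d requires at least 2 values per sample",
          class = "mapscreen_domain_error")
  }
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  diff <- mean(a) - mean(b)
  if (sp == 0) {
    warn("zero pooled SD in cohens_d; returning signed infinity",
         class = "mapscreen_degenerate_scale")
    return(sign(diff) * Inf)
  }
  diff / sp
}

#' Call phenotypic activity from a treatment and a null mAP distribution
#'
#' The mAP effect size (mAP-ES) is Cohen's d between the condition's mAP
#' distribution and the DMSO null distribution; the condition is active
#' when `mAP-ES >= threshold` (default 0.8, a conventionally large effect
#' size).
#'
#' @param compound_dist,null_dist `map_distribution` objects computed under
#'   the same scheme.
#' @param threshold Activity threshold on the effect size (default 0.8).
#' @return One-row tibble: condition, `map_es`, `threshold`, `is_active`,
#'   and sampling provenance.
#' @export
call_activity <- function(compound_dist, null_dist, threshold = 0.8) {
  if (!same_scheme(compound_dist$scheme, null_dist$scheme)) {
    abort("compound and null distributions use different pair schemes",
          class = "mapscreen_contract_error")
  }
  es <- cohens_d(compound_dist$values, null_dist$values)
  cond <- compound_dist$condition
  tibble::tibble(
    compound = cond$compound,
    dose_uM = cond$dose_uM,
    timepoint_h = cond$timepoint_h,
    map_mean = mean(compound_dist$values),
    map_es = es,
    threshold = threshold,
    is_active = es >= threshold,
    n_pos = compound_dist$scheme$n_pos,
    n_neg = compound_dist$scheme$n_neg,
    n_resamples = compound_dist$scheme$n_resamples,
    seed = compound_dist$scheme$seed
  )
}

#' Activity calls for every (compound, dose, timepoint) condition
#'
#' Computes one DMSO null distribution per timepoint and one mAP
#' distribution per evaluable condition, and calls activity at the given
#' effect-size threshold. Conditions without enough cross-replica positives
#' are reported with a `status` instead of a call.
#'
#' @param profiles A normalized, well-level profile tibble.
#' @param scheme A [pair_scheme()].
#' @param threshold Effect-size threshold (default 0.8).
#' @return Tibble with one row per condition: `map_es`, `is_active`,
#'   `status` (`"ok"` or a skip reason), and provenance columns.
#' @export
activity_map <- function(profiles, scheme = pair_scheme(), threshold = 0.8) {
  conditions <- profiles |>
    dplyr::filter(.data$Metadata_role == "treatment") |>
    dplyr::distinct(compound = .data$Metadata_compound,
                    dose_uM = .data$Metadata_dose_uM,
                    timepoint_h = .data$Metadata_timepoint_h) |>
    dplyr::arrange(.data$compound, .data$dose_uM, .data$timepoint_h)

  nulls <- lapply(
    setNames(nm = unique(conditions$timepoint_h)),
    function(tp) sample_null_distribution(profiles, tp, scheme)
  )

  purrr::pmap_dfr(conditions, function(compound, dose_uM, timepoint_h) {
    cd <- sample_map_distribution(profiles, compound, dose_uM, timepoint_h,
                                  scheme)
    nd <- nulls[[as.character(timepoint_h)]]
    if (cd$status != "ok" || nd$status != "ok") {
      return(tibble::tibble(
        compound = compound, dose_uM = dose_uM, timepoint_h = timepoint_h,
        map_mean = NA_real_, map_es = NA_real_, threshold = threshold,
        is_active = NA, n_pos = scheme$n_pos, n_neg = scheme$n_neg,
        n_resamples = scheme$n_resamples, seed = scheme$seed,
        status = if (cd$status != "ok") cd$status else nd$status
      ))
    }
    dplyr::mutate(call_activity(cd, nd, threshold), status = "ok")
  })
}

#' Sensitivity and specificity of activity calls against ground truth
#'
#' @param calls Output of [activity_map()].
#' @param truth Ground-truth tibble with `compound_id`, `dose_uM`,
#'   `timepoint_h`, `is_active` (e.g. from [generate_dataset()]).
#' @return One-row tibble: `sensitivity`, `specificity`, counts.
#' @export
activity_performance <- function(calls, truth) {
  joined <- calls |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::inner_join(
      truth |>
        dplyr::select(compound = "compound_id", "dose_uM", "timepoint_h",
                      truth_active = "is_active"),
      by = c("compound", "dose_uM", "timepoint_h")
    )
  tibble::tibble(
    n_conditions = nrow(joined),
    n_truth_active = sum(joined$truth_active),
    sensitivity = mean(joined$is_active[joined$truth_active]),
    specificity = mean(!joined$is_active[!joined$truth_active])
  )
}
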