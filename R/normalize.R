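# Robust MAD normalization against DMSO, and batch integration over
# replica / field-of-view covariates.

MAD_CONSISTENCY <- 1.4826  # Gaussian-consistent robust scale factor

#' Robust per-measurement normalization against DMSO wells
#'
#' For every measurement -- one (plate, timepoint) group -- each feature is
#' centred on the median of that group's DMSO wells and scaled by
#' `1.4826 * MAD` of the DMSO wells. Features whose DMSO MAD is exactly zero
#' are centred but left unscaled (divide by 1), with a warning naming the
#' feature.
#'
#' @param profiles A profile tibble (any granularity).
#' @param consistency Scale consistency constant, default 1.4826.
#' @return Normalized profile tibble; row order and metadata untouched.
#' @export
mad_robustize <- function(profiles, consistency = MAD_CONSISTENCY) {
  validate_profiles(profiles)
  feats <- feature_names(profiles)
  X <- feature_matrix(profiles)
  grp <- paste(profiles$Metadata_plate, profiles$Metadata_timepoint_h, sep = "\r")
  degenerate <- character(0)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    dmso <- rows[profiles$Metadata_role[rows] == "negative_control"]
    if (length(dmso) < 2) {
      gl <- strsplit(g, "\r", fixed = TRUE)[[1]]
      abort(paste0("measurement (plate ", gl[1], ", timepoint ", gl[2],
                   " h) has fewer than 2 DMSO records"),
            class = "mapscreen_group_error")
    }
    med <- apply(X[dmso, , drop = FALSE], 2, stats::median)
    madv <- apply(X[dmso, , drop = FALSE], 2, stats::mad,
                  constant = consistency)
    zero <- madv == 0
    if (any(zero)) {
      degenerate <- union(degenerate, feats[zero])
      madv[zero] <- 1
    }
    X[rows, ] <- sweep(sweep(X[rows, , drop = FALSE], 2, med), 2, madv, "/")
  }
  if (length(degenerate) > 0) {
    warn(paste0("zero DMSO MAD; centred but not scaled: ",
                paste(degenerate, collapse = ", ")),
         class = "mapscreen_degenerate_scale")
  }
  profiles[feats] <- tibble::as_tibble(X)
  profiles
}

#' Batch integration by iterative soft clustering with mixture correction
#'
#' Removes additive batch structure associated with categorical covariates
#' (experimental replica, field of view) while preserving within-cluster
#' biological variation. The algorithm alternates (i) diversity-penalised
#' soft k-means assignment of profiles to clusters on the cosine-normalized
#' features and (ii) a per-cluster ridge regression of the features on the
#' one-hot covariate design, subtracting the assignment-weighted batch
#' component from each profile. Iteration stops when the root-mean-square
#' correction falls below `tol`.
#'
#' @param profiles A profile tibble, already MAD-normalized.
#' @param covariates Character vector of covariates to integrate over, a
#'   subset of `c("replica", "fov")`.
#' @param seed Integer seed; output is deterministic given it.
#' @param nclust Number of soft clusters (default: `min(8, n/20)`, at least 2).
#' @param theta Diversity penalty strength per covariate (default 2).
#' @param sigma Soft assignment width (default 0.1).
#' @param lambda Ridge penalty on batch coefficients (default 1).
#' @param max_iter Maximum alternation rounds (default 20).
#' @param tol Convergence threshold: the alternation stops once the RMS of
#'   the applied correction falls below `tol` times the RMS of the feature
#'   matrix (default 0.01).
#' @return Profile tibble of identical shape with corrected features.
#' @export
harmony_correct <- function(profiles, covariates = c("replica", "fov"),
                            seed = 1L, nclust = NULL, theta = 2,
                            sigma = 0.1, lambda = 1, max_iter = 20,
                            tol = 0.01) {
  validate_profiles(profiles)
  covariates <- match.arg(covariates, c("replica", "fov"), several.ok = TRUE)
  batch_cols <- lapply(covariates, function(cv) {
    vals <- switch(cv,
      replica = profiles$Metadata_replica,
      fov = as.character(profiles$Metadata_fov)
    )
    if (length(unique(vals)) < 2) {
      abort(paste0("covariate '", cv, "' has a single level"),
            class = "mapscreen_covariate_error")
    }
    stats::model.matrix(~ f - 1, data.frame(f = factor(vals)))
  })
  Phi <- do.call(cbind, batch_cols)           # n x B one-hot blocks
  n_levels_per_cov <- vapply(batch_cols, ncol, integer(1))

  Z <- feature_matrix(profiles)
  n <- nrow(Z)
  if (is.null(nclust)) nclust <- max(2, min(8, floor(n / 20)))
  nclust <- min(nclust, n - 1)

  cosnorm <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)
  Zcos <- cosnorm(Z)
  km <- with_stream(seed, "harmony_init",
                    expr = stats::kmeans(Zcos, centers = nclust,
                                         nstart = 3, iter.max = 25))
  Y <- cosnorm(km$centers)

  Phi_star <- cbind(Intercept = 1, Phi)
  ridge <- diag(c(0, rep(lambda, ncol(Phi))))
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    # soft assignment with diversity penalty per covariate block
    d2 <- 2 * (1 - Zcos %*% t(Y))             # squared cosine distance
    R <- exp(-d2 / sigma)
    R <- R / pmax(rowSums(R), 1e-300)
    off <- 0L
    for (bi in seq_along(n_levels_per_cov)) {
      blk <- off + seq_len(n_levels_per_cov[bi])
      Phib <- Phi[, blk, drop = FALSE]
      O <- t(R) %*% Phib + 1                  # observed cluster x batch
      E <- outer(colSums(R), colMeans(Phib)) + 1  # expected under full mixing
      pen <- (E / O)^theta
      R <- R * (Phib %*% t(pen))
      off <- off + n_levels_per_cov[bi]
    }
    R <- R / pmax(rowSums(R), 1e-300)

    Y <- cosnorm(t(R) %*% Zcos)

    # mixture correction: per-cluster ridge on the covariate design
    correction <- matrix(0, n, ncol(Z))
    for (k in seq_len(nclust)) {
      rk <- R[, k]
      A <- t(Phi_star * rk) %*% Phi_star + ridge
      W <- solve(A, t(Phi_star * rk) %*% Z)
      batch_part <- Phi %*% W[-1, , drop = FALSE]
      correction <- correction + rk * batch_part
    }
    Z <- Z - correction
    Zcos <- cosnorm(Z)
    if (sqrt(mean(correction^2)) < tol * max(sqrt(mean(Z^2)), 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged && max_iter > 1) {
    warn("batch integration did not converge; returning best iterate",
         class = "mapscreen_convergence_warning")
  }
  profiles[feature_names(profiles)] <- tibble::as_tibble(
    `colnames<-`(Z, feature_names(profiles))
  )
  profiles
}

#' Batch-mixing diagnostic: cross-validated covariate probe accuracy
#'
#' Fits a linear (multinomial ridge) classifier predicting a batch
#' covariate from the feature vectors under k-fold cross-validation and
#' returns the held-out accuracy. Well-mixed data scores near chance
#' (1 / number of levels); residual batch structure scores higher. Usually
#' run on DMSO wells only, where no treatment signal can stand in for
#' batch identity.
#'
#' @param profiles A profile tibble.
#' @param covariate `"replica"`, `"plate"` or `"fov"`.
#' @param k Cross-validation folds (default 5).
#' @param lambda Ridge penalty (default 1e-2).
#' @param seed Integer seed for the fold split.
#' @return Held-out classification accuracy in `[0, 1]`.
#' @export
covariate_probe_accuracy <- function(profiles, covariate = c("replica", "plate", "fov"),
                                     k = 5, lambda = 1e-2, seed = 1L) {
  covariate <- match.arg(covariate)
  y <- factor(switch(covariate,
    replica = profiles$Metadata_replica,
    plate = profiles$Metadata_plate,
    fov = as.character(profiles$Metadata_fov)
  ))
  if (nlevels(y) < 2) {
    abort(paste0("covariate '", covariate, "' has a single level"),
          class = "mapscreen_covariate_error")
  }
  X <- feature_matrix(profiles)
  fold <- with_stream(seed, "probe_folds", expr = sample(rep_len(seq_len(k), nrow(X))))
  hits <- unlist(lapply(seq_len(k), function(f) {
    fit <- glmnet::glmnet(X[fold != f, , drop = FALSE], y[fold != f],
                          family = "multinomial", alpha = 0,
                          lambda = lambda * c(1000, 100, 10, 1),
                          standardize = FALSE)
    pred <- predict(fit, X[fold == f, , drop = FALSE], type = "class",
                    s = lambda)
    pred == as.character(y[fold == f])
  }))
  mean(hits)
}

#' Normalize a profile table
#'
#' The full normalization pipeline: robust MAD normalization of every
#' measurement (plate at a timepoint) against its own DMSO wells, then --
#' for the batch-integrated variants -- a single global pass of
#' [harmony_correct()] on the concatenated table with the method's
#' covariates: experimental replica for `"mad_harmony"`, replica plus field
#' of view for `"mad_harmony_fov"`.
#'
#' @param profiles A profile tibble.
#' @param method `"mad"`, `"mad_harmony"` or `"mad_harmony_fov"`.
#' @param seed Seed for the batch-integration stage.
#' @param ... Further arguments passed to [harmony_correct()].
#' @return Normalized profile tibble, same shape and metadata as the input.
#' @export
normalize_profiles <- function(profiles,
                               method = c("mad", "mad_harmony", "mad_harmony_fov"),
                               seed = 1L, ...) {
  method <- match.arg(method)
  out <- mad_robustize(profiles)
  if (method == "mad_harmony") {
    out <- harmony_correct(out, covariates = "replica", seed = seed, ...)
  } else if (method == "mad_harmony_fov") {
    out <- harmony_correct(out, covariates = c("replica", "fov"),
                           seed = seed, ...)
  }
  out
}
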