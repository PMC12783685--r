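# Self-supervised training-objective mathematics at desk scale:
# cross-batch DINO centering, Barlow Twins decorrelation, combined loss and
# the cross-replica plane-agnostic crop sampler. Pure functions only -- no
# training loop, optimizer or backbone.

#' Per-batch teacher center bank
#'
#' One center vector per experimental batch (replica), updated by an
#' exponential moving average of that batch's teacher outputs. Keeping the
#' centers separate per batch lets teacher centering remove batch-specific
#' logit offsets instead of a single global offset.
#'
#' @param batch_ids Character vector of batch identifiers.
#' @param K Projection-head dimension.
#' @param momentum EMA momentum in `[0, 1]` (default 0.9).
#' @return A `center_bank`: list of zero-initialized centers plus momentum.
#' @export
center_bank <- function(batch_ids, K, momentum = 0.9) {
  if (momentum < 0 || momentum > 1) {
    abort("momentum must lie in [0, 1]", class = "mapscreen_config_error")
  }
  structure(
    list(centers = setNames(lapply(batch_ids, function(b) numeric(K)),
                            batch_ids),
         momentum = momentum, K = as.integer(K)),
    class = "center_bank"
  )
}

#' Update one batch's center by EMA of teacher outputs
#'
#' `center[b] <- m * center[b] + (1 - m) * mean(teacher rows)`; centers of
#' other batches are untouched. An empty row set is a warning no-op.
#'
#' @param bank A [center_bank()].
#' @param batch_id The batch to update.
#' @param teacher_logits Matrix of teacher outputs (rows from that batch).
#' @return The updated bank.
#' @export
update_centers <- function(bank, batch_id, teacher_logits) {
  if (!batch_id %in% names(bank$centers)) {
    abort(paste0("unknown batch id: ", batch_id),
          class = "mapscreen_contract_error")
  }
  teacher_logits <- rbind(teacher_logits)
  if (nrow(teacher_logits) == 0) {
    warn("empty teacher batch; centers unchanged",
         class = "mapscreen_empty_batch")
    return(bank)
  }
  m <- bank$momentum
  bank$centers[[batch_id]] <-
    m * bank$centers[[batch_id]] + (1 - m) * colMeans(teacher_logits)
  bank
}

softmax_rows <- function(M) {
  M <- M - apply(M, 1, max)
  e <- exp(M)
  e / rowSums(e)
}

#' Cross-batch DINO distillation loss
#'
#' Each teacher row is centred by the center vector of its own batch,
#' sharpened at temperature `teacher_temp` and treated as a fixed
#' (gradient-stopped) target; the loss is the mean cross-entropy between
#' these targets and the student softmax at temperature `student_temp`.
#'
#' @param student_logits,teacher_logits `N x K` matrices.
#' @param batch_ids Batch identifier per row.
#' @param bank A [center_bank()] holding every referenced batch.
#' @param student_temp,teacher_temp Softmax temperatures (defaults 0.1 and
#'   0.04).
#' @return Scalar loss.
#' @export
dino_cross_batch_loss <- function(student_logits, teacher_logits, batch_ids,
                                  bank, student_temp = 0.1,
                                  teacher_temp = 0.04) {
  student_logits <- rbind(student_logits)
  teacher_logits <- rbind(teacher_logits)
  if (!all(dim(student_logits) == dim(teacher_logits)) ||
      nrow(student_logits) != length(batch_ids)) {
    abort("student/teacher/batch shapes do not agree",
          class = "mapscreen_contract_error")
  }
  missing_b <- setdiff(unique(batch_ids), names(bank$centers))
  if (length(missing_b) > 0) {
    abort(paste0("batch id(s) not in center bank: ",
                 paste(missing_b, collapse = ", ")),
          class = "mapscreen_contract_error")
  }
  centers <- do.call(rbind, bank$centers[batch_ids])
  targets <- softmax_rows((teacher_logits - centers) / teacher_temp)
  logp <- log(softmax_rows(student_logits / student_temp))
  mean(-rowSums(targets * logp))
}

#' Barlow Twins redundancy-reduction loss
#'
#' Columns of both views are standardized over the batch; the
#' cross-correlation matrix `C = (1/N) zA' zB` is pushed towards the
#' identity: `loss = sum_i (1 - C_ii)^2 + lambda * sum_{i != j} C_ij^2`.
#'
#' @param zA,zB `N x F` embedding matrices of two augmented views.
#' @param lambda Off-diagonal coefficient (default 0.5, favouring strong
#'   decorrelation).
#' @param sd_floor Added to per-feature SDs so degenerate toy batches do
#'   not divide by zero (default 1e-12).
#' @return Scalar loss.
#' @export
barlow_twins_loss <- function(zA, zB, lambda = 0.5, sd_floor = 1e-12) {
  zA <- rbind(zA); zB <- rbind(zB)
  N <- nrow(zA)
  if (N < 2 || !all(dim(zA) == dim(zB))) {
    abort("barlow_twins_loss needs two equally shaped views with N >= 2",
          class = "mapscreen_domain_error")
  }
  std <- function(M) {
    mu <- colMeans(M)
    # population SD over the batch, as in the batch-norm formulation
    sdv <- sqrt(colMeans(sweep(M, 2, mu)^2)) + sd_floor
    sweep(sweep(M, 2, mu), 2, sdv, "/")
  }
  C <- crossprod(std(zA), std(zB)) / N
  sum((1 - diag(C))^2) + lambda * (sum(C^2) - sum(diag(C)^2))
}

#' Combined self-supervised loss
#'
#' Weighted sum of the distillation and decorrelation terms; the default
#' weights implement a 1:1 ratio.
#'
#' @param dino,barlow Scalar loss values.
#' @param dino_weight,barlow_weight Non-negative weights (defaults 1, 1).
#' @return Scalar combined loss.
#' @export
combined_loss <- function(dino, barlow, dino_weight = 1, barlow_weight = 1) {
  if (!is.finite(dino) || !is.finite(barlow)) {
    abort("loss terms must be finite", class = "mapscreen_domain_error")
  }
  dino_weight * dino + barlow_weight * barlow
}

#' Crop specification for cross-batch, plane-agnostic augmentation
#'
#' @param n_global Global crops per sample (default 2).
#' @param locals_per_global Local crops per global-crop source (default 3).
#' @param n_planes Available focal planes per z-stack (default 3).
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(n_global = 2, locals_per_global = 3, n_planes = 3) {
  structure(list(n_global = n_global, locals_per_global = locals_per_global,
                 n_planes = n_planes),
            class = "crop_spec")
}

#' Sample cross-batch, plane-agnostic crops for one treatment condition
#'
#' Draws the two global crops from two distinct experimental replicas of
#' the same (compound, dose, timepoint); each global-crop source image
#' additionally yields `locals_per_global` local crops; every crop's focal
#' plane is drawn uniformly from the available z-planes.
#'
#' @param replica_ids Replicas available for the condition (>= 2).
#' @param spec A [crop_spec()].
#' @param seed Integer seed.
#' @return Tibble of crop annotations: `crop` (`"global"`/`"local"`),
#'   `global_index`, `source_replica`, `plane` (0-based), `scale`.
#' @export
sample_cross_batch_crops <- function(replica_ids, spec = crop_spec(),
                                     seed = 1L) {
  replica_ids <- unique(replica_ids)
  if (length(replica_ids) < 2) {
    abort("cross-batch sampling requires >= 2 replicas",
          class = "mapscreen_sampling_error")
  }
  with_stream(seed, "crops", expr = {
    srcs <- sample(replica_ids, spec$n_global, replace = FALSE)
    rows <- lapply(seq_len(spec$n_global), function(g) {
      global <- tibble::tibble(
        crop = "global", global_index = g, source_replica = srcs[g],
        plane = sample.int(spec$n_planes, 1) - 1L, scale = "global"
      )
      locals <- tibble::tibble(
        crop = "local", global_index = g, source_replica = srcs[g],
        plane = sample.int(spec$n_planes, spec$locals_per_global,
                           replace = TRUE) - 1L,
        scale = "local"
      )
      dplyr::bind_rows(global, locals)
    })
    dplyr::bind_rows(rows)
  })
}
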