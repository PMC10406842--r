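#' Cross-cell average baseline (AVG)
#'
#' Predicts a track as the per-bin arithmetic mean of the target assay in
#' all other cell types with a training-split observation, on the arcsinh
#' scale. The target cell's own track never contributes.
#'
#' @param tensor a [signal_tensor()].
#' @param target length-2 vector `(cell, assay)` (indices or ids).
#' @return numeric vector of per-bin predictions.
#' @export
avg_predictor <- function(tensor, target) {
  idx <- .resolve_target(tensor, target)
  obs <- .split_matrix(tensor, "train")
  donors <- which(obs[, idx[2]])
  donors <- setdiff(donors, idx[1])
  if (!length(donors)) {
    stop("no other cell type observes assay `", tensor$assay_ids[idx[2]],
         "` in the training split")
  }
  v <- tensor$values[donors, idx[2], , drop = FALSE]
  colMeans(matrix(v, nrow = length(donors)))
}

#' Training-individual track baseline
#'
#' Predicts a track in the target individual as a verbatim copy of the
#' corresponding track in the training individual.
#'
#' @param training_tensor the training individual's [signal_tensor()].
#' @param target length-2 vector `(cell, assay)`.
#' @return numeric vector (the copied track).
#' @export
training_individual_track <- function(training_tensor, target) {
  idx <- .resolve_target(training_tensor, target)
  if (!training_tensor$observed[idx[1], idx[2]]) {
    stop("track (", training_tensor$cell_ids[idx[1]], ", ",
         training_tensor$assay_ids[idx[2]],
         ") is not observed in the training individual")
  }
  as.numeric(training_tensor$values[idx[1], idx[2], ])
}

#' Within-individual average baseline
#'
#' The individualized AVG predictor: per-bin mean of the target assay over
#' all tissues of the target individual except the target tissue.
#'
#' @param tensor the target individual's [signal_tensor()].
#' @param target length-2 vector `(tissue, assay)`.
#' @param exclude optional additional tissue indices to exclude (e.g. the
#'   held-out tissue when it differs from the target).
#' @return numeric vector of per-bin predictions.
#' @export
individual_avg_predictor <- function(tensor, target, exclude = integer(0)) {
  idx <- .resolve_target(tensor, target)
  donors <- which(tensor$observed[, idx[2]])
  donors <- setdiff(donors, c(idx[1], exclude))
  if (!length(donors)) {
    stop("no other tissue observes assay `", tensor$assay_ids[idx[2]], "`")
  }
  v <- tensor$values[donors, idx[2], , drop = FALSE]
  colMeans(matrix(v, nrow = length(donors)))
}

.resolve_target <- function(tensor, target) {
  stopifnot(inherits(tensor, "signal_tensor"), length(target) == 2L)
  if (is.character(target)) {
    idx <- c(match(target[1], tensor$cell_ids), match(target[2], tensor$assay_ids))
    if (any(is.na(idx))) stop("unknown cell/assay id in target")
  } else {
    idx <- as.integer(target)
  }
  d <- dim(tensor$values)
  if (idx[1] < 1 || idx[1] > d[1] || idx[2] < 1 || idx[2] > d[2]) {
    stop("target index out of range")
  }
  idx
}

#' Tensor-factorization baseline
#'
#' Minimal single-resolution tensor completion: each entry is modelled as
#' `sum_r c_ir * a_jr * b_kr + intercept`, with embeddings fit by Adam on
#' observed training entries under squared error. A reference predictor for
#' synthetic benchmarking (a deliberately simple stand-in for multi-scale
#' factorization models).
#'
#' @param tensor a [signal_tensor()].
#' @param rank embedding dimension.
#' @param epochs optimization epochs over all observed entries.
#' @param learning_rate Adam learning rate.
#' @param seed RNG seed.
#' @param params optional warm start (`factorization_params`).
#' @param freeze one of "none" or "all_but_bins" (two-stage refit of
#'   genomic-location embeddings only, for a new region).
#' @return object of class `factorization_params` with `cell_factors`,
#'   `assay_factors`, `bin_factors`, `intercept`, and a `loss_history`.
#' @export
fit_factorization_baseline <- function(tensor, rank = 8L, epochs = 200L,
                                       learning_rate = 0.02, seed = 1L,
                                       params = NULL, freeze = c("none", "all_but_bins")) {
  freeze <- match.arg(freeze)
  stopifnot(inherits(tensor, "signal_tensor"))
  obs <- .split_matrix(tensor, "train")
  d <- dim(tensor$values)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(params)) {
    params <- list(
      cell_factors = matrix(stats::rnorm(d[1] * rank, sd = 0.1), d[1], rank),
      assay_factors = matrix(stats::rnorm(d[2] * rank, sd = 0.1), d[2], rank),
      bin_factors = matrix(stats::rnorm(d[3] * rank, sd = 0.1), d[3], rank),
      intercept = 0
    )
    class(params) <- "factorization_params"
  } else {
    stopifnot(inherits(params, "factorization_params"))
    if (nrow(params$bin_factors) != d[3]) {
      rank <- ncol(params$bin_factors)
      params$bin_factors <- matrix(stats::rnorm(d[3] * rank, sd = 0.1), d[3], rank)
    }
  }
  rank <- ncol(params$cell_factors)
  tracks <- which(obs, arr.ind = TRUE)
  n_tr <- nrow(tracks)
  # flatten observed entries: value matrix [n_tracks x n_bins]
  y <- matrix(0, n_tr, d[3])
  for (t in seq_len(n_tr)) y[t, ] <- tensor$values[tracks[t, 1], tracks[t, 2], ]
  state <- .adam_init(params[c("cell_factors", "assay_factors", "bin_factors", "intercept")])
  loss_history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ca <- params$cell_factors[tracks[, 1], , drop = FALSE] *
      params$assay_factors[tracks[, 2], , drop = FALSE]   # n_tr x rank
    pred <- tcrossprod(ca, params$bin_factors) + params$intercept  # n_tr x n_bins
    resid <- pred - y
    loss_history[ep] <- mean(resid^2)
    if (!is.finite(loss_history[ep])) stop("factorization diverged at epoch ", ep)
    scale_ <- 2 / length(resid)
    g_ca <- scale_ * (resid %*% params$bin_factors)      # n_tr x rank
    g_cell <- rowsum(g_ca * params$assay_factors[tracks[, 2], , drop = FALSE],
                     tracks[, 1], reorder = FALSE)
    g_assay <- rowsum(g_ca * params$cell_factors[tracks[, 1], , drop = FALSE],
                      tracks[, 2], reorder = FALSE)
    gc_full <- matrix(0, d[1], rank)
    gc_full[as.integer(rownames(g_cell)), ] <- g_cell
    ga_full <- matrix(0, d[2], rank)
    ga_full[as.integer(rownames(g_assay)), ] <- ga_full[as.integer(rownames(g_assay)), ] + g_assay
    g_bin <- scale_ * crossprod(resid, ca)               # n_bins x rank
    g_int <- scale_ * sum(resid)
    grads <- list(cell_factors = gc_full, assay_factors = ga_full,
                  bin_factors = g_bin, intercept = g_int)
    if (freeze == "all_but_bins") {
      grads$cell_factors[] <- 0
      grads$assay_factors[] <- 0
      grads$intercept <- 0
    }
    step <- .adam_step(params[names(grads)], grads, state, learning_rate)
    params[names(grads)] <- step$params
    state <- step$state
  }
  params$loss_history <- loss_history
  params
}

#' Predict from the factorization baseline
#'
#' @param params a `factorization_params`.
#' @param cell,assay indices (1-based).
#' @param bins optional bin indices (default all).
#' @return numeric vector of predictions.
#' @export
predict_factorization <- function(params, cell, assay, bins = NULL) {
  stopifnot(inherits(params, "factorization_params"))
  bf <- if (is.null(bins)) params$bin_factors else params$bin_factors[bins, , drop = FALSE]
  as.numeric(bf %*% (params$cell_factors[cell, ] * params$assay_factors[assay, ]) +
               params$intercept)
}
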