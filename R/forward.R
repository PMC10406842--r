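# Forward pass of the factorized self-attention imputer.
#
# A "slice" is the n_c x n_a matrix of local arcsinh signal at one genomic
# bin. Each encoder embeds its entities' local signal vectors (rows for
# cells, columns for assays) through a shared affine+ReLU map scaled by
# 1/n_obs, adds a learned global embedding, and contextualizes the result
# with one transformer-style self-attention block (no layer normalisation).
# The decoder MLP maps a concatenated (cell, assay) embedding pair to the
# predicted signal value.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# add a bias row-vector to every row (fast sweep replacement)
.addb <- function(x, b) x + rep(b, each = nrow(x))

#' Construct a signal slice
#'
#' @param values `n_c x n_a` matrix of local arcsinh signal; must be 0
#'   wherever `input_visible` is FALSE (masking-by-zero contract).
#' @param track_observed logical matrix; which tracks exist at all.
#' @param input_visible logical matrix; observed AND not currently masked.
#'   Defaults to `track_observed`.
#' @return an object of class `signal_slice`.
#' @export
signal_slice <- function(values, track_observed,
                         input_visible = track_observed) {
  stopifnot(is.matrix(values), is.matrix(track_observed), is.matrix(input_visible))
  if (!all(dim(values) == dim(track_observed)) ||
      !all(dim(values) == dim(input_visible))) {
    stop("slice matrices must share dimensions")
  }
  if (any(input_visible & !track_observed)) {
    stop("input_visible must imply track_observed")
  }
  if (any(values[!input_visible] != 0)) {
    stop("slice values must be 0 where not visible")
  }
  structure(
    list(values = values, track_observed = track_observed,
         input_visible = input_visible),
    class = "signal_slice"
  )
}

# shared encoder arithmetic: rows of `y` are entity signal vectors,
# `visible` the matching visibility matrix
.encode_pre <- function(y, visible, enc) {
  n_obs <- rowSums(visible)
  z <- .addb(y %*% enc$phi_W, enc$phi_b)
  s <- relu(z)
  scale <- 1 / n_obs
  scale[n_obs == 0] <- 0
  s * scale + enc$u
}

#' Pre-attention cell embeddings
#'
#' Row `i` is `(1/n_obs_i) * ReLU(affine(y_i)) + u_i` where `y_i` is cell
#' i's visible-zeroed assay signal vector and `n_obs_i` its number of
#' visible entries; a fully masked cell falls back to its global embedding.
#'
#' @param slice a [signal_slice()].
#' @param params a `model_params` object.
#' @param config a [model_config()].
#' @return `n_cells x embed_dim` matrix.
#' @export
embed_cells <- function(slice, params, config) {
  stopifnot(inherits(slice, "signal_slice"))
  if (nrow(slice$values) != params$n_cells || ncol(slice$values) != params$n_assays) {
    stop("slice is ", nrow(slice$values), "x", ncol(slice$values),
         " but model expects ", params$n_cells, "x", params$n_assays)
  }
  .encode_pre(slice$values, slice$input_visible, params$cell)
}

#' Pre-attention assay embeddings
#'
#' Mirrors [embed_cells()] on the transposed slice: row `j` embeds assay
#' j's visible-zeroed cell signal vector.
#'
#' @inheritParams embed_cells
#' @return `n_assays x embed_dim` matrix.
#' @export
embed_assays <- function(slice, params, config) {
  stopifnot(inherits(slice, "signal_slice"))
  if (nrow(slice$values) != params$n_cells || ncol(slice$values) != params$n_assays) {
    stop("slice is ", nrow(slice$values), "x", ncol(slice$values),
         " but model expects ", params$n_cells, "x", params$n_assays)
  }
  .encode_pre(t(slice$values), t(slice$input_visible), params$assay)
}

# multi-head attention + FFN with residuals, optionally returning the
# intermediate quantities needed for backpropagation
.sab_forward <- function(h0, sp, config, keep_cache = FALSE) {
  n <- nrow(h0)
  d <- config$embed_dim
  nh <- config$n_heads
  dh <- d %/% nh
  q <- .addb(h0 %*% sp$Wq, sp$bq)
  k <- .addb(h0 %*% sp$Wk, sp$bk)
  v <- .addb(h0 %*% sp$Wv, sp$bv)
  o <- matrix(0, n, d)
  attn <- vector("list", nh)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    scores <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) / sqrt(dh)
    # stabilized softmax; ties.method must be deterministic (no RNG use)
    scores <- scores - scores[cbind(seq_len(n), max.col(scores, ties.method = "first"))]
    e <- exp(scores)
    a <- e / rowSums(e)
    o[, cols] <- a %*% v[, cols, drop = FALSE]
    if (keep_cache) attn[[h]] <- a
  }
  m <- .addb(o %*% sp$Wo, sp$bo)
  h1 <- h0 + m
  z1 <- .addb(h1 %*% sp$W1, sp$b1)
  r1 <- relu(z1)
  h2 <- h1 + .addb(r1 %*% sp$W2, sp$b2)
  if (!keep_cache) return(h2)
  list(out = h2, h0 = h0, q = q, k = k, v = v, o = o, attn = attn,
       h1 = h1, z1 = z1, r1 = r1)
}

#' Transformer-style self-attention block
#'
#' Multi-head scaled-dot-product self-attention (heads concatenated and
#' linearly projected) with a residual connection, followed by a per-token
#' feed-forward network with a second residual. No layer normalisation.
#'
#' @param embeddings `n x embed_dim` matrix of pre-attention embeddings.
#' @param sab_params the `sab` parameter list of one encoder side.
#' @param config a [model_config()].
#' @return `n x embed_dim` matrix of contextualized embeddings.
#' @export
self_attention_block <- function(embeddings, sab_params, config) {
  stopifnot(is.matrix(embeddings), ncol(embeddings) == config$embed_dim,
            nrow(embeddings) >= 1L)
  .sab_forward(embeddings, sab_params, config)
}

# decoder forward on a matrix of [c_i ; a_j] rows; dropout only in training
.decoder_forward <- function(x, dec, config, training = FALSE, keep_cache = FALSE) {
  n_layers <- length(dec$W)
  acts <- list(x)
  zs <- list()
  masks <- list()
  p <- config$dropout_rate
  for (l in seq_len(n_layers - 1L)) {
    z <- .addb(acts[[l]] %*% dec$W[[l]], dec$b[[l]])
    r <- relu(z)
    if (training && p > 0) {
      keep <- matrix(stats::runif(length(r)) >= p, nrow(r), ncol(r))
      r <- r * keep / (1 - p)
      masks[[l]] <- keep
    }
    zs[[l]] <- z
    acts[[l + 1L]] <- r
  }
  out <- .addb(acts[[n_layers]] %*% dec$W[[n_layers]], dec$b[[n_layers]])
  if (!keep_cache) return(drop(out))
  list(out = drop(out), acts = acts, zs = zs, masks = masks)
}

#' Decode a (cell, assay) embedding pair to a signal value
#'
#' @param cell_embedding,assay_embedding numeric vectors of length
#'   `embed_dim` (contextualized representations).
#' @param params a `model_params` object.
#' @param config a [model_config()].
#' @param training logical; dropout is active only when TRUE.
#' @return scalar predicted arcsinh signal.
#' @export
decode <- function(cell_embedding, assay_embedding, params, config,
                   training = FALSE) {
  d <- config$embed_dim
  if (length(cell_embedding) != d || length(assay_embedding) != d) {
    stop("embeddings must have length embed_dim = ", d)
  }
  x <- matrix(c(cell_embedding, assay_embedding), 1L)
  .decoder_forward(x, params$decoder, config, training = training)
}

#' Impute values at one genomic bin
#'
#' Computes the contextualized embedding sets once for the slice, then
#' decodes every requested (cell, assay) target; targets need not be
#' observed tracks.
#'
#' @param slice a [signal_slice()].
#' @param targets integer matrix with columns `cell`, `assay` (1-based), or
#'   a 2-column matrix.
#' @param params,config model parameters and configuration.
#' @param training logical; enables decoder dropout.
#' @return numeric vector of predictions, one per target row.
#' @export
impute_slice <- function(slice, targets, params, config, training = FALSE) {
  targets <- matrix(as.integer(targets), ncol = 2L)
  if (nrow(targets) == 0L) return(numeric(0))
  if (any(targets[, 1L] < 1L | targets[, 1L] > params$n_cells) ||
      any(targets[, 2L] < 1L | targets[, 2L] > params$n_assays)) {
    stop("target index out of range")
  }
  ce <- self_attention_block(embed_cells(slice, params, config), params$cell$sab, config)
  ae <- self_attention_block(embed_assays(slice, params, config), params$assay$sab, config)
  x <- cbind(ce[targets[, 1L], , drop = FALSE], ae[targets[, 2L], , drop = FALSE])
  preds <- .decoder_forward(x, params$decoder, config, training = training)
  as.numeric(preds)
}

#' Impute a full-length track
#'
#' Applies [impute_slice()] at every bin with all observed tracks (or all
#' training-split tracks, via `visible`) as input context. Deterministic in
#' evaluation mode.
#'
#' @param tensor a [signal_tensor()].
#' @param target length-2 integer vector `(cell, assay)`; may be an
#'   unobserved track.
#' @param params,config model parameters and configuration.
#' @param visible optional logical matrix overriding the input context
#'   (defaults to `tensor$observed`, i.e. every observed track is context).
#' @param bins optional integer vector of bins to impute (default all).
#' @return numeric vector of imputed arcsinh signal, one value per bin.
#' @export
impute_track <- function(tensor, target, params, config, visible = NULL,
                         bins = NULL) {
  impute_tracks(tensor, matrix(as.integer(target), ncol = 2L), params,
                config, visible = visible, bins = bins)[, 1L]
}

#' Impute several tracks in one pass
#'
#' Shares the per-bin embedding computation across all targets, so imputing
#' a whole test set costs barely more than imputing one track.
#'
#' @inheritParams impute_track
#' @param targets integer matrix with one (cell, assay) row per track.
#' @return numeric matrix `n_bins x n_targets`.
#' @export
impute_tracks <- function(tensor, targets, params, config, visible = NULL,
                          bins = NULL) {
  stopifnot(inherits(tensor, "signal_tensor"))
  if (is.null(visible)) visible <- tensor$observed
  if (is.null(bins)) bins <- seq_len(dim(tensor$values)[3])
  targets <- matrix(as.integer(targets), ncol = 2L)
  vis <- visible & tensor$observed
  out <- matrix(0, length(bins), nrow(targets))
  for (b in seq_along(bins)) {
    vals <- tensor$values[, , bins[b]]
    vals[!vis] <- 0
    sl <- signal_slice(vals, tensor$observed, vis)
    out[b, ] <- impute_slice(sl, targets, params, config, training = FALSE)
  }
  out
}
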