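#' Model architecture configuration
#'
#' The full-scale default architecture: 256-dimensional cell and
#' assay embeddings, 4 attention heads, a position-wise feed-forward network
#' with one 128-unit hidden layer and 256-dimensional output inside the
#' self-attention block, a decoder MLP with 2 ReLU hidden layers of 2048
#' units, dropout 0.3 on decoder hidden layers, and no layer normalisation.
#' Desk-scale experiments shrink `embed_dim`/`decoder_hidden`; the structure
#' is unchanged.
#'
#' @param embed_dim embedding dimension for cells and assays (divisible by
#'   `n_heads`).
#' @param n_heads number of attention heads.
#' @param attn_hidden hidden width of the feed-forward network inside the
#'   self-attention block.
#' @param attn_out output width of that network; must equal `embed_dim` so
#'   the residual connection is well-typed.
#' @param decoder_hidden width of decoder MLP hidden layers.
#' @param decoder_layers number of decoder hidden layers.
#' @param dropout_rate dropout on decoder hidden layers, in `[0, 1)`;
#'   training mode only.
#' @param layer_norm logical; layer normalisation is removed from the
#'   attention block in this architecture, so the default is `FALSE` (TRUE
#'   is not implemented).
#' @return an object of class `model_config`.
#' @export
model_config <- function(embed_dim = 256L, n_heads = 4L, attn_hidden = 128L,
                         attn_out = embed_dim, decoder_hidden = 2048L,
                         decoder_layers = 2L, dropout_rate = 0.3,
                         layer_norm = FALSE) {
  embed_dim <- as.integer(embed_dim)
  n_heads <- as.integer(n_heads)
  if (embed_dim %% n_heads != 0L) {
    stop("`embed_dim` (", embed_dim, ") must be divisible by `n_heads` (", n_heads, ")")
  }
  if (as.integer(attn_out) != embed_dim) {
    stop("`attn_out` must equal `embed_dim` (residual connection)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("`dropout_rate` must be in [0, 1)")
  if (isTRUE(layer_norm)) stop("layer normalisation is not part of this architecture")
  structure(
    list(
      embed_dim = embed_dim, n_heads = n_heads,
      attn_hidden = as.integer(attn_hidden), attn_out = as.integer(attn_out),
      decoder_hidden = as.integer(decoder_hidden),
      decoder_layers = as.integer(decoder_layers),
      dropout_rate = dropout_rate, layer_norm = FALSE
    ),
    class = "model_config"
  )
}

# uniform fan-in init, as used by standard dense-layer implementations
.init_mat <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.init_encoder <- function(input_dim, n_entities, config) {
  d <- config$embed_dim
  list(
    phi_W = .init_mat(input_dim, d),
    phi_b = rep(0, d),
    u = matrix(stats::rnorm(n_entities * d, sd = 0.1), n_entities, d),
    sab = list(
      Wq = .init_mat(d, d), bq = rep(0, d),
      Wk = .init_mat(d, d), bk = rep(0, d),
      Wv = .init_mat(d, d), bv = rep(0, d),
      Wo = .init_mat(d, d), bo = rep(0, d),
      W1 = .init_mat(d, config$attn_hidden), b1 = rep(0, config$attn_hidden),
      W2 = .init_mat(config$attn_hidden, config$attn_out), b2 = rep(0, config$attn_out)
    )
  )
}

#' Initialise model parameters
#'
#' Weight matrices are drawn uniform with fan-in scaling, biases start at 0,
#' global cell/assay embeddings `u` are small Gaussian. Deterministic given
#' `seed`.
#'
#' @param n_cells,n_assays tensor dimensions the model binds to.
#' @param config a [model_config()].
#' @param seed integer RNG seed.
#' @return an object of class `model_params`: nested list with `cell` and
#'   `assay` encoder parameters (signal-embedding affine map, global
#'   embeddings `u`, self-attention block) and `decoder` MLP weights.
#' @export
init_model_params <- function(n_cells, n_assays, config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- config$embed_dim
  widths <- c(2L * d, rep(config$decoder_hidden, config$decoder_layers), 1L)
  decoder <- list(W = list(), b = list())
  for (l in seq_len(length(widths) - 1L)) {
    decoder$W[[l]] <- .init_mat(widths[l], widths[l + 1L])
    decoder$b[[l]] <- rep(0, widths[l + 1L])
  }
  structure(
    list(
      cell = .init_encoder(n_assays, n_cells, config),
      assay = .init_encoder(n_cells, n_assays, config),
      decoder = decoder,
      n_cells = as.integer(n_cells), n_assays = as.integer(n_assays)
    ),
    class = "model_params"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Save / load a model checkpoint
#'
#' A checkpoint holds the configuration, all parameters and the positional
#' index ordering (cell and assay identifiers); embeddings are positional,
#' so the ordering is part of the contract.
#'
#' @param params a `model_params` object.
#' @param config the [model_config()] used to build it.
#' @param path file path.
#' @param cell_ids,assay_ids character vectors fixing the index order.
#' @export
save_checkpoint <- function(params, config, path, cell_ids = NULL, assay_ids = NULL) {
  saveRDS(list(
    format = "edice_checkpoint", version = 1L,
    config = config, params = params,
    cell_ids = cell_ids, assay_ids = assay_ids
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with `params`, `config`,
#'   `cell_ids`, `assay_ids`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "edice_checkpoint")) stop("not an edice checkpoint")
  obj[c("params", "config", "cell_ids", "assay_ids")]
}
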