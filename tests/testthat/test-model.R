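test_that("model_config validates structural constraints", {
  expect_error(model_config(embed_dim = 10, n_heads = 4), "divisible")
  expect_error(model_config(attn_out = 128L, embed_dim = 256L), "residual")
  expect_error(model_config(dropout_rate = 1), "dropout")
  cfg <- model_config()
  expect_equal(cfg$embed_dim, 256L)
  expect_equal(cfg$n_heads, 4L)
  expect_equal(cfg$decoder_hidden, 2048L)
  expect_false(cfg$layer_norm)
})

test_that("embed_cells applies the scaled signal embedding plus globals", {
  cfg <- tiny_config()
  sl <- tiny_slice()
  params <- init_model_params(4, 3, cfg, seed = 5)

  # fully masked cell falls back to its global embedding
  vis <- sl$input_visible
  vis[2, ] <- FALSE
  vals <- sl$values
  vals[2, ] <- 0
  sl2 <- signal_slice(vals, sl$track_observed, vis & sl$track_observed)
  emb <- embed_cells(sl2, params, cfg)
  expect_equal(emb[2, ], params$cell$u[2, ])

  # zero weights collapse to b / n_obs + u
  p0 <- params
  p0$cell$phi_W[] <- 0
  p0$cell$phi_b <- abs(rnorm(cfg$embed_dim))
  emb0 <- embed_cells(sl, p0, cfg)
  for (i in 1:4) {
    n_obs <- sum(sl$input_visible[i, ])
    if (n_obs == 0) {
      expect_equal(emb0[i, ], p0$cell$u[i, ])  # zero-scaling convention
    } else {
      expect_equal(emb0[i, ], p0$cell$phi_b / n_obs + p0$cell$u[i, ])
    }
  }

  # dense-algebra oracle on a hand-built 2x3 case
  cfg2 <- model_config(embed_dim = 4, n_heads = 2, attn_hidden = 3,
                       attn_out = 4, decoder_hidden = 5, decoder_layers = 1,
                       dropout_rate = 0)
  p2 <- init_model_params(2, 3, cfg2, seed = 1)
  vals <- matrix(c(1, 0, 2, 0.5, 0, 0), 2, 3)
  vis <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2, 3)
  sl3 <- signal_slice(vals, vis)
  got <- embed_cells(sl3, p2, cfg2)
  for (i in 1:2) {
    expected <- pmax(vals[i, ] %*% p2$cell$phi_W + p2$cell$phi_b, 0) /
      sum(vis[i, ]) + p2$cell$u[i, ]
    expect_equal(got[i, ], as.numeric(expected), tolerance = 1e-12)
  }
})

test_that("embed_assays mirrors embed_cells under transposition", {
  cfg <- tiny_config()
  sl <- tiny_slice()
  params <- init_model_params(4, 3, cfg, seed = 5)

  # fully masked assay
  vis <- sl$input_visible
  vis[, 3] <- FALSE
  vals <- sl$values
  vals[, 3] <- 0
  sl2 <- signal_slice(vals, sl$track_observed, vis & sl$track_observed)
  expect_equal(embed_assays(sl2, params, cfg)[3, ], params$assay$u[3, ])

  # structural symmetry: transpose the slice and swap parameter sets
  swapped <- params
  swapped$cell <- params$assay
  swapped$assay <- params$cell
  swapped$n_cells <- params$n_assays
  swapped$n_assays <- params$n_cells
  tsl <- signal_slice(t(sl$values), t(sl$track_observed), t(sl$input_visible))
  expect_equal(embed_cells(tsl, swapped, cfg), embed_assays(sl, params, cfg))
})

test_that("self_attention_block matches the brute-force oracle", {
  set.seed(31)
  cfg <- tiny_config()
  for (rep_ in 1:20) {
    n <- sample(1:5, 1)
    h0 <- matrix(rnorm(n * 8), n, 8)
    sp <- random_sab_params(8, 6)
    got <- self_attention_block(h0, sp, cfg)
    want <- oracle_sab(h0, sp, 2)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("self-attention residuals carry identity under zero updates", {
  cfg <- tiny_config()
  set.seed(3)
  sp <- random_sab_params(8, 6)
  sp$Wv[] <- 0; sp$bv[] <- 0
  sp$Wo[] <- 0; sp$bo[] <- 0
  sp$W2[] <- 0; sp$b2[] <- 0
  h0 <- matrix(rnorm(4 * 8), 4, 8)
  expect_equal(self_attention_block(h0, sp, cfg), h0)

  # n == 1: softmax over one key is 1, output fully determined by the token
  sp2 <- random_sab_params(8, 6)
  h1 <- matrix(rnorm(8), 1, 8)
  expect_equal(self_attention_block(h1, sp2, cfg), oracle_sab(h1, sp2, 2),
               tolerance = 1e-9)
})

test_that("decode evaluates the MLP and is deterministic at inference", {
  cfg <- tiny_config(dropout = 0.3)
  params <- init_model_params(3, 3, cfg, seed = 9)

  # all-zero decoder with final bias beta gives constant beta
  pz <- params
  for (l in seq_along(pz$decoder$W)) pz$decoder$W[[l]][] <- 0
  pz$decoder$b[[length(pz$decoder$b)]] <- 0.75
  expect_equal(decode(rnorm(8), rnorm(8), pz, cfg), 0.75)

  # one-hidden-unit hand-set chain (config with a single hidden layer)
  cfg1 <- model_config(embed_dim = 2, n_heads = 1, attn_hidden = 2,
                       attn_out = 2, decoder_hidden = 1, decoder_layers = 1,
                       dropout_rate = 0)
  p1 <- init_model_params(2, 2, cfg1, seed = 1)
  p1$decoder$W[[1]] <- matrix(c(1, -1, 2, 0.5), 4, 1)
  p1$decoder$b[[1]] <- 0.1
  p1$decoder$W[[2]] <- matrix(3, 1, 1)
  p1$decoder$b[[2]] <- -0.2
  ce <- c(1, 2); ae <- c(0.5, -1)
  h <- max(sum(c(ce, ae) * c(1, -1, 2, 0.5)) + 0.1, 0)
  expect_equal(decode(ce, ae, p1, cfg1), 3 * h - 0.2)

  # dropout disabled at inference: bit-identical repeated calls
  ce <- rnorm(8); ae <- rnorm(8)
  expect_identical(decode(ce, ae, params, cfg), decode(ce, ae, params, cfg))
  expect_error(decode(rnorm(4), rnorm(8), params, cfg), "embed_dim")
})

test_that("impute_slice factorizes through per-entity embeddings", {
  cfg <- tiny_config()
  sl <- tiny_slice()
  params <- init_model_params(4, 3, cfg, seed = 2)

  expect_identical(impute_slice(sl, matrix(integer(0), ncol = 2), params, cfg),
                   numeric(0))
  expect_error(impute_slice(sl, cbind(5, 1), params, cfg), "out of range")

  # prediction depends on the slice only through (c_i, a_j): recompute via
  # explicit embedding + decode and compare
  targets <- rbind(c(1, 2), c(1, 3), c(4, 2))
  got <- impute_slice(sl, targets, params, cfg)
  ce <- self_attention_block(embed_cells(sl, params, cfg), params$cell$sab, cfg)
  ae <- self_attention_block(embed_assays(sl, params, cfg), params$assay$sab, cfg)
  for (t in seq_len(nrow(targets))) {
    expect_equal(got[t],
                 decode(ce[targets[t, 1], ], ae[targets[t, 2], ], params, cfg),
                 tolerance = 1e-12)
  }
})

test_that("masked and missing entries have zero influence", {
  cfg <- tiny_config()
  params <- init_model_params(4, 3, cfg, seed = 8)
  set.seed(21)
  observed <- matrix(TRUE, 4, 3)
  visible <- matrix(stats::runif(12) > 0.4, 4, 3)
  vals1 <- matrix(abs(rnorm(12)), 4, 3)
  vals2 <- vals1
  vals2[!visible] <- vals2[!visible] + 100  # corrupt hidden entries
  vals1[!visible] <- 0
  vals2[!visible] <- 0                      # re-zeroed per the contract
  sl1 <- signal_slice(vals1, observed, visible)
  sl2 <- signal_slice(vals2, observed, visible)
  targets <- which(visible == visible, arr.ind = TRUE)  # all pairs
  expect_identical(impute_slice(sl1, targets, params, cfg),
                   impute_slice(sl2, targets, params, cfg))
  # the validator itself refuses un-zeroed hidden entries
  bad <- vals1
  bad[!visible][1] <- 5
  expect_error(signal_slice(bad, observed, visible), "0")
})

test_that("cell permutation equivariance holds exactly", {
  cfg <- tiny_config()
  sl <- tiny_slice(nc = 5, na_ = 3, seed = 12)
  params <- init_model_params(5, 3, cfg, seed = 4)
  perm <- c(3, 1, 5, 2, 4)
  params_p <- params
  params_p$cell$u <- params$cell$u[perm, ]
  sl_p <- signal_slice(sl$values[perm, ], sl$track_observed[perm, ],
                       sl$input_visible[perm, ])
  ce <- self_attention_block(embed_cells(sl, params, cfg), params$cell$sab, cfg)
  ce_p <- self_attention_block(embed_cells(sl_p, params_p, cfg),
                               params$cell$sab, cfg)
  expect_equal(ce_p, ce[perm, ], tolerance = 1e-12)
})

test_that("hand-derived gradients agree with finite differences", {
  cfg <- model_config(embed_dim = 8, n_heads = 2, attn_hidden = 6,
                      attn_out = 8, decoder_hidden = 7, decoder_layers = 2,
                      dropout_rate = 0)
  set.seed(42)
  nc <- 4; na_ <- 3
  params <- init_model_params(nc, na_, cfg, seed = 3)
  visible <- matrix(runif(nc * na_) > 0.3, nc, na_)
  vals <- matrix(abs(rnorm(nc * na_)), nc, na_)
  vals[!visible] <- 0
  targets <- cbind(c(1, 2, 4), c(2, 3, 1))
  y <- abs(rnorm(3))

  loss_fn <- function(p) {
    fw <- edice:::.forward_slice_cached(vals, visible, targets, p, cfg)
    mean((fw$preds - y)^2)
  }
  fw <- edice:::.forward_slice_cached(vals, visible, targets, params, cfg)
  g <- edice:::.backward_slice(fw, 2 * (fw$preds - y) / 3, params, cfg)

  get_leaf <- function(tree, path) { for (k in path) tree <- tree[[k]]; tree }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1) { tree[[path[[1]]]] <- val; return(tree) }
    tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
    tree
  }
  paths <- list(
    list("cell", "phi_W"), list("cell", "u"), list("cell", "sab", "Wq"),
    list("cell", "sab", "Wv"), list("cell", "sab", "W1"),
    list("assay", "phi_b"), list("assay", "sab", "Wk"),
    list("assay", "sab", "Wo"), list("assay", "sab", "W2"),
    list("decoder", "W", 1), list("decoder", "b", 2), list("decoder", "W", 3)
  )
  for (path in paths) {
    leaf <- get_leaf(params, path)
    gleaf <- get_leaf(g, path)
    for (ii in sample(length(leaf), min(3, length(leaf)))) {
      eps <- 1e-6
      lp <- leaf; lp[ii] <- lp[ii] + eps
      lm <- leaf; lm[ii] <- lm[ii] - eps
      num <- (loss_fn(set_leaf(params, path, lp)) -
                loss_fn(set_leaf(params, path, lm))) / (2 * eps)
      expect_equal(gleaf[ii], num, tolerance = 1e-5,
                   label = paste(unlist(path), collapse = "/"))
    }
  }
})

test_that("impute_track has the right shape and is deterministic", {
  spec <- small_spec(n_bins = 60L)
  gen <- generate_tensor(spec)
  cfg <- tiny_config(dropout = 0.3)
  params <- init_model_params(spec$n_cells, spec$n_assays, cfg, seed = 6)
  trk1 <- impute_track(gen$tensor, c(1, 4), params, cfg)
  trk2 <- impute_track(gen$tensor, c(1, 4), params, cfg)
  expect_length(trk1, 60L)
  expect_identical(trk1, trk2)
})

test_that("checkpoints round-trip parameters and index order", {
  cfg <- tiny_config()
  params <- init_model_params(3, 2, cfg, seed = 13)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(params, cfg, path, cell_ids = c("a", "b", "c"),
                  assay_ids = c("x", "y"))
  back <- load_checkpoint(path)
  expect_identical(back$params, params)
  expect_identical(back$cell_ids, c("a", "b", "c"))
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds",
                                                     lines = "x")),
               "checkpoint|RDS|unknown", ignore.case = TRUE)
})
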