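# Reverse-mode gradients for one slice, hand-derived and verified against
# finite differences in the test suite. The structure mirrors forward.R:
# decoder backward feeds d(embedding) into each self-attention block
# backward, which feeds d(pre-attention embedding) into the encoder affine
# map backward. Input signal gradients are never needed (inputs are data).

.zero_like <- function(p) {
  rapply(p, function(x) if (is.numeric(x)) x * 0 else x, how = "replace")
}

# full forward with caches; targets is a t x 2 integer matrix
.forward_slice_cached <- function(vals, visible, targets, params, config,
                                  training = FALSE) {
  n_obs_c <- rowSums(visible)
  n_obs_a <- colSums(visible)
  enc_pre <- function(y, n_obs, enc) {
    z <- .addb(y %*% enc$phi_W, enc$phi_b)
    s <- relu(z)
    scale <- 1 / n_obs
    scale[n_obs == 0] <- 0
    list(h0 = s * scale + enc$u, z = z, scale = scale, y = y)
  }
  pc <- enc_pre(vals, n_obs_c, params$cell)
  pa <- enc_pre(t(vals), n_obs_a, params$assay)
  sc <- .sab_forward(pc$h0, params$cell$sab, config, keep_cache = TRUE)
  sa <- .sab_forward(pa$h0, params$assay$sab, config, keep_cache = TRUE)
  x <- cbind(sc$out[targets[, 1L], , drop = FALSE],
             sa$out[targets[, 2L], , drop = FALSE])
  dcache <- .decoder_forward(x, params$decoder, config,
                             training = training, keep_cache = TRUE)
  list(preds = as.numeric(dcache$out), pre_cell = pc, pre_assay = pa,
       sab_cell = sc, sab_assay = sa, dec = dcache, targets = targets)
}

.decoder_backward <- function(dout, cache, dec, config, training = FALSE) {
  n_layers <- length(dec$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  dy <- matrix(dout, ncol = 1L)
  gW[[n_layers]] <- crossprod(cache$acts[[n_layers]], dy)
  gb[[n_layers]] <- colSums(dy)
  dact <- tcrossprod(dy, dec$W[[n_layers]])
  p <- config$dropout_rate
  for (l in rev(seq_len(n_layers - 1L))) {
    if (training && p > 0) dact <- dact * cache$masks[[l]] / (1 - p)
    dz <- dact * (cache$zs[[l]] > 0)
    gW[[l]] <- crossprod(cache$acts[[l]], dz)
    gb[[l]] <- colSums(dz)
    dact <- tcrossprod(dz, dec$W[[l]])
  }
  list(gW = gW, gb = gb, dx = dact)
}

.sab_backward <- function(dh2, cache, sp, config) {
  d <- config$embed_dim
  nh <- config$n_heads
  dh_ <- d %/% nh
  # FFN residual: h2 = h1 + relu(h1 W1 + b1) W2 + b2
  dz2 <- dh2
  gW2 <- crossprod(cache$r1, dz2)
  gb2 <- colSums(dz2)
  dr1 <- tcrossprod(dz2, sp$W2)
  dz1 <- dr1 * (cache$z1 > 0)
  gW1 <- crossprod(cache$h1, dz1)
  gb1 <- colSums(dz1)
  dh1 <- dh2 + tcrossprod(dz1, sp$W1)
  # attention residual: h1 = h0 + (concat heads) Wo + bo
  dm <- dh1
  gWo <- crossprod(cache$o, dm)
  gbo <- colSums(dm)
  do_ <- tcrossprod(dm, sp$Wo)
  dq <- matrix(0, nrow(dh2), d)
  dk <- matrix(0, nrow(dh2), d)
  dv <- matrix(0, nrow(dh2), d)
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh_ + 1L):(h * dh_)
    a <- cache$attn[[h]]
    doh <- do_[, cols, drop = FALSE]
    da <- tcrossprod(doh, cache$v[, cols, drop = FALSE])
    dv[, cols] <- crossprod(a, doh)
    # softmax rows: ds = a * (da - rowSums(da * a)); n x n minus length-n
    # vector recycles down columns, i.e. row-wise subtraction
    ds <- a * (da - rowSums(da * a))
    dq[, cols] <- ds %*% cache$k[, cols, drop = FALSE] / sqrt(dh_)
    dk[, cols] <- crossprod(ds, cache$q[, cols, drop = FALSE]) / sqrt(dh_)
  }
  h0 <- cache$h0
  g <- list(
    Wq = crossprod(h0, dq), bq = colSums(dq),
    Wk = crossprod(h0, dk), bk = colSums(dk),
    Wv = crossprod(h0, dv), bv = colSums(dv),
    Wo = gWo, bo = gbo, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2
  )
  dh0 <- dh1 + tcrossprod(dq, sp$Wq) + tcrossprod(dk, sp$Wk) +
    tcrossprod(dv, sp$Wv)
  list(grads = g, dh0 = dh0)
}

.encoder_backward <- function(dh0, pre, enc) {
  du <- dh0
  ds <- dh0 * pre$scale
  dz <- ds * (pre$z > 0)
  list(
    phi_W = crossprod(pre$y, dz),
    phi_b = colSums(dz),
    u = du
  )
}

# gradient of per-slice masked MSE wrt all parameters; dpreds is
# d(loss)/d(pred) per target
.backward_slice <- function(fw, dpreds, params, config, training = FALSE) {
  d <- config$embed_dim
  db <- .decoder_backward(dpreds, fw$dec, params$decoder, config, training)
  tc <- fw$targets[, 1L]
  ta <- fw$targets[, 2L]
  dce <- matrix(0, params$n_cells, d)
  dae <- matrix(0, params$n_assays, d)
  dxc <- db$dx[, seq_len(d), drop = FALSE]
  dxa <- db$dx[, d + seq_len(d), drop = FALSE]
  for (t in seq_along(tc)) {
    dce[tc[t], ] <- dce[tc[t], ] + dxc[t, ]
    dae[ta[t], ] <- dae[ta[t], ] + dxa[t, ]
  }
  sbc <- .sab_backward(dce, fw$sab_cell, params$cell$sab, config)
  sba <- .sab_backward(dae, fw$sab_assay, params$assay$sab, config)
  ec <- .encoder_backward(sbc$dh0, fw$pre_cell, params$cell)
  ea <- .encoder_backward(sba$dh0, fw$pre_assay, params$assay)
  list(
    cell = c(ec, list(sab = sbc$grads)),
    assay = c(ea, list(sab = sba$grads)),
    decoder = list(W = db$gW, b = db$gb)
  )
}

# elementwise walk over parallel parameter trees (params, grads, states...)
.tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1L]]
  if (is.numeric(t1)) return(do.call(f, trees))
  out <- t1
  for (nm in seq_along(t1)) {
    out[[nm]] <- do.call(.tree_map, c(list(f), lapply(trees, `[[`, nm)))
  }
  out
}

.tree_add <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  for (k in seq_along(a)) a[[k]] <- .tree_add(a[[k]], b[[k]])
  a
}

.tree_scale <- function(a, s) {
  if (is.numeric(a)) return(a * s)
  for (k in seq_along(a)) a[[k]] <- .tree_scale(a[[k]], s)
  a
}
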