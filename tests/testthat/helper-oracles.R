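# Independent oracles and small fixtures shared across tests. These
# deliberately use different computational paths from the implementation.

# brute-force multi-head self-attention + FFN with residuals: explicit
# per-row softmax loops, no shared code with .sab_forward
oracle_sab <- function(h0, sp, n_heads) {
  n <- nrow(h0)
  d <- ncol(h0)
  dh <- d / n_heads
  q <- h0 %*% sp$Wq + matrix(sp$bq, n, d, byrow = TRUE)
  k <- h0 %*% sp$Wk + matrix(sp$bk, n, d, byrow = TRUE)
  v <- h0 %*% sp$Wv + matrix(sp$bv, n, d, byrow = TRUE)
  o <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(n)) {
      logits <- numeric(n)
      for (j in seq_len(n)) {
        logits[j] <- sum(q[i, cols] * k[j, cols]) / sqrt(dh)
      }
      a <- exp(logits) / sum(exp(logits))
      for (c_ in cols) o[i, c_] <- sum(a * v[, c_])
    }
  }
  m <- o %*% sp$Wo + matrix(sp$bo, n, d, byrow = TRUE)
  h1 <- h0 + m
  z1 <- h1 %*% sp$W1 + matrix(sp$b1, n, length(sp$b1), byrow = TRUE)
  r1 <- pmax(z1, 0)
  h1 + r1 %*% sp$W2 + matrix(sp$b2, n, d, byrow = TRUE)
}

# random self-attention parameters for a given width
random_sab_params <- function(d, hidden, scale = 0.5) {
  rm_ <- function(a, b) matrix(stats::rnorm(a * b, sd = scale), a, b)
  list(
    Wq = rm_(d, d), bq = stats::rnorm(d, sd = scale),
    Wk = rm_(d, d), bk = stats::rnorm(d, sd = scale),
    Wv = rm_(d, d), bv = stats::rnorm(d, sd = scale),
    Wo = rm_(d, d), bo = stats::rnorm(d, sd = scale),
    W1 = rm_(d, hidden), b1 = stats::rnorm(hidden, sd = scale),
    W2 = rm_(hidden, d), b2 = stats::rnorm(d, sd = scale)
  )
}

# average precision by explicit threshold enumeration: at each distinct
# score threshold compute precision/recall from scratch and accumulate the
# step-function area
oracle_auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  area <- 0
  prev_recall <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(called & labels)
    precision <- tp / sum(called)
    recall <- tp / P
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# 1-D optimal transport cost by explicit monotone coupling (two-pointer
# mass matching; optimal for the convex cost |i - j| and equivalent to the
# transport LP optimum in 1-D)
oracle_wasserstein <- function(a, b, bin_width) {
  a <- a / sum(a)
  b <- b / sum(b)
  i <- 1L
  j <- 1L
  cost <- 0
  while (i <= length(a) && j <= length(b)) {
    m <- min(a[i], b[j])
    cost <- cost + m * abs(i - j) * bin_width
    a[i] <- a[i] - m
    b[j] <- b[j] - m
    if (a[i] <= 1e-15) i <- i + 1L
    if (j <= length(b) && b[j] <= 1e-15) j <- j + 1L
  }
  cost
}

# tiny model fixture used throughout model/training unit tests
tiny_config <- function(dropout = 0) {
  model_config(
    embed_dim = 8L, n_heads = 2L, attn_hidden = 6L, attn_out = 8L,
    decoder_hidden = 10L, decoder_layers = 2L, dropout_rate = dropout
  )
}

tiny_slice <- function(nc = 4, na_ = 3, seed = 7, mask_frac = 0.3) {
  set.seed(seed)
  observed <- matrix(stats::runif(nc * na_) > 0.2, nc, na_)
  visible <- observed & matrix(stats::runif(nc * na_) > mask_frac, nc, na_)
  vals <- matrix(abs(stats::rnorm(nc * na_)), nc, na_)
  vals[!visible] <- 0
  signal_slice(vals, observed, visible)
}

# small fast synthetic world for pipeline-level unit tests
small_spec <- function(n_bins = 1500L, ...) {
  synthetic_spec(n_cells = 6L, n_assays = 5L, n_bins = n_bins,
                 core_assays = 3L, ...)
}
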