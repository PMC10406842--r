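# Adam optimizer over nested parameter trees. Only leaves present in the
# gradient tree are updated, so integer bookkeeping fields in the parameter
# list are untouched.

.adam_init <- function(grad_template) {
  list(
    m = .zero_like(grad_template),
    v = .zero_like(grad_template),
    t = 0L
  )
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map(
    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
    state$m, state$v
  )
  params <- .apply_update(params, upd)
  list(params = params, state = state)
}

# subtract update from params, following the update tree's structure
.apply_update <- function(params, upd) {
  if (is.numeric(upd)) return(params - upd)
  keys <- names(upd)
  if (is.null(keys)) keys <- seq_along(upd)
  for (nm in keys) {
    params[[nm]] <- .apply_update(params[[nm]], upd[[nm]])
  }
  params
}
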