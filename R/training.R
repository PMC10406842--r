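#' Training configuration
#'
#' The full-scale default regime: mask 120 tracks per bin,
#' 50 epochs of Adam at learning rate 3e-4; the transfer protocol pretrains
#' for 30 epochs and fine-tunes for 15 at 3e-5. Batch size and the number
#' of training bins are implementation choices (small random subsets of the
#' genome suffice for this model class).
#'
#' @param n_masked number of tracks masked per bin (`random_track` scheme).
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param pretrain_epochs,finetune_epochs,finetune_lr transfer-protocol
#'   stage lengths and fine-tuning rate.
#' @param batch_bins bins per optimizer step.
#' @param n_train_bins size of the fixed random subset of bins trained on.
#' @param mask_scheme `"random_track"` (uniform track subsets) or
#'   `"tissue_wise"` (all observed tracks of one random cell type per bin).
#' @param seed RNG seed controlling bin sampling, masking, dropout and
#'   initialisation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(n_masked = 120L, epochs = 50L, learning_rate = 3e-4,
                         pretrain_epochs = 30L, finetune_epochs = 15L,
                         finetune_lr = 3e-5, batch_bins = 256L,
                         n_train_bins = 10000L,
                         mask_scheme = c("random_track", "tissue_wise"),
                         seed = 1L) {
  mask_scheme <- match.arg(mask_scheme)
  stopifnot(learning_rate > 0, finetune_lr > 0, epochs >= 0, n_masked >= 1)
  structure(
    list(
      n_masked = as.integer(n_masked), epochs = as.integer(epochs),
      learning_rate = learning_rate,
      pretrain_epochs = as.integer(pretrain_epochs),
      finetune_epochs = as.integer(finetune_epochs),
      finetune_lr = finetune_lr, batch_bins = as.integer(batch_bins),
      n_train_bins = as.integer(n_train_bins), mask_scheme = mask_scheme,
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Sample the fixed set of training bins
#'
#' Uniform sample without replacement, fixed for the whole run and
#' reproducible under `seed`.
#'
#' @param binning a [genomic_binning()].
#' @param n_train_bins number of bins to draw (<= `binning$n_bins`).
#' @param seed integer seed.
#' @return sorted integer vector of 1-based bin indices.
#' @export
sample_training_bins <- function(binning, n_train_bins, seed = 1L) {
  stopifnot(inherits(binning, "genomic_binning"))
  n_train_bins <- as.integer(n_train_bins)
  if (n_train_bins > binning$n_bins) {
    stop("n_train_bins (", n_train_bins, ") exceeds n_bins (", binning$n_bins, ")")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sort(sample.int(binning$n_bins, n_train_bins))
}

#' Draw a mask over observed tracks
#'
#' `random_track`: `n_masked` distinct observed (cell, assay) pairs drawn
#' uniformly without replacement. `tissue_wise`: one cell type drawn
#' uniformly among cells with at least one observed track; all its observed
#' tracks are masked (mimicking an entirely unmeasured tissue).
#'
#' Uses the current RNG state (no internal seeding) so training draws a
#' fresh mask per bin per epoch reproducibly under the run seed.
#'
#' @param observed logical cell x assay matrix of maskable tracks.
#' @param scheme `"random_track"` or `"tissue_wise"`.
#' @param n_masked mask size for `random_track`.
#' @return a `mask_spec`: list with `entries` (t x 2 integer matrix of
#'   (cell, assay) indices) and `scheme`.
#' @export
sample_mask <- function(observed, scheme = c("random_track", "tissue_wise"),
                        n_masked = 120L) {
  scheme <- match.arg(scheme)
  obs_idx <- which(observed, arr.ind = TRUE)
  if (scheme == "random_track") {
    if (n_masked > nrow(obs_idx)) {
      stop("n_masked (", n_masked, ") exceeds number of observed tracks (",
           nrow(obs_idx), ")")
    }
    pick <- sample.int(nrow(obs_idx), n_masked)
    entries <- obs_idx[pick, , drop = FALSE]
  } else {
    eligible <- which(rowSums(observed) > 0)
    if (!length(eligible)) stop("no cell type has an observed track")
    cell <- eligible[sample.int(length(eligible), 1L)]
    assays <- which(observed[cell, ])
    entries <- cbind(rep.int(cell, length(assays)), assays)
  }
  dimnames(entries) <- list(NULL, c("cell", "assay"))
  structure(list(entries = entries, scheme = scheme), class = "mask_spec")
}

#' Masked mean squared error
#'
#' The per-bin reconstruction loss: mean squared error over the masked
#' entries only.
#'
#' @param predictions numeric vector, one prediction per mask entry.
#' @param truth_slice numeric cell x assay matrix of true values at the bin.
#' @param mask a `mask_spec` from [sample_mask()].
#' @return scalar loss.
#' @export
masked_mse_loss <- function(predictions, truth_slice, mask) {
  stopifnot(inherits(mask, "mask_spec"))
  m <- nrow(mask$entries)
  if (m == 0L) stop("empty mask")
  if (length(predictions) != m) {
    stop("need one prediction per mask entry (", m, ")")
  }
  truth <- truth_slice[mask$entries]
  mean((predictions - truth)^2)
}

# logical cell x assay matrix of tracks in the given split(s); all observed
# tracks when the tensor carries no track table
.split_matrix <- function(tensor, splits = "train") {
  obs <- tensor$observed
  tt <- tensor$tracks
  if (is.null(tt)) return(obs)
  m <- matrix(FALSE, nrow(obs), ncol(obs),
              dimnames = dimnames(obs))
  sel <- tt$split %in% splits
  ci <- match(tt$cell_type_id[sel], tensor$cell_ids)
  ai <- match(tt$assay_id[sel], tensor$assay_ids)
  m[cbind(ci, ai)] <- TRUE
  m & obs
}

#' Train the imputation model by masked reconstruction
#'
#' At each training bin, a fresh mask over observed training tracks is
#' drawn; masked entries are zeroed in the input slice and predicted from
#' the remainder, and the masked MSE is minimised with Adam. Deterministic
#' given `train$seed` and a fixed thread count.
#'
#' @param tensor a [signal_tensor()]; only training-split tracks (per its
#'   track table) are used as context or targets.
#' @param config a [model_config()].
#' @param train a [train_config()].
#' @param params optional warm-start `model_params` (default: fresh
#'   initialisation seeded from `train$seed`).
#' @param trainable logical cell x assay matrix restricting which observed
#'   tracks may be masked/used (used by [transfer_fit()]); default all
#'   training-split tracks.
#' @param epochs,learning_rate,mask_scheme optional overrides of the
#'   corresponding `train` fields (used by the transfer protocol).
#' @param log_path optional path for a tab-separated per-epoch loss log.
#' @return list with `params` (trained `model_params`) and `loss_history`
#'   (numeric, one mean masked-MSE per epoch).
#' @export
train_edice <- function(tensor, config = model_config(), train = train_config(),
                        params = NULL, trainable = NULL, epochs = NULL,
                        learning_rate = NULL, mask_scheme = NULL,
                        log_path = NULL) {
  stopifnot(inherits(tensor, "signal_tensor"), inherits(config, "model_config"),
            inherits(train, "train_config"))
  epochs <- epochs %||% train$epochs
  lr <- learning_rate %||% train$learning_rate
  scheme <- mask_scheme %||% train$mask_scheme
  obs <- .split_matrix(tensor, "train")
  if (!is.null(trainable)) obs <- obs & trainable
  n_obs_tracks <- sum(obs)
  if (scheme == "random_track" && train$n_masked >= n_obs_tracks) {
    stop("n_masked (", train$n_masked, ") must be < observed training tracks (",
         n_obs_tracks, ")")
  }
  d3 <- dim(tensor$values)
  bins <- sample_training_bins(tensor$binning,
                               min(train$n_train_bins, d3[3]),
                               seed = train$seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(train$seed + 1L)
  if (is.null(params)) {
    params <- init_model_params(d3[1], d3[2], config, seed = train$seed + 2L)
  }
  grad_template <- .zero_like(params[c("cell", "assay", "decoder")])
  state <- .adam_init(grad_template)
  loss_history <- numeric(0)
  if (epochs == 0L) {
    return(list(params = params, loss_history = loss_history))
  }
  for (epoch in seq_len(epochs)) {
    order_ <- sample(bins)
    batch_starts <- seq(1L, length(order_), by = train$batch_bins)
    epoch_losses <- numeric(0)
    for (bs in batch_starts) {
      batch <- order_[bs:min(bs + train$batch_bins - 1L, length(order_))]
      grads <- grad_template
      batch_loss <- 0
      for (b in batch) {
        truth <- tensor$values[, , b]
        mask <- sample_mask(obs, scheme, train$n_masked)
        visible <- obs
        visible[mask$entries] <- FALSE
        vals <- truth
        vals[!visible] <- 0
        fw <- .forward_slice_cached(vals, visible, mask$entries, params,
                                    config, training = TRUE)
        y <- truth[mask$entries]
        resid <- fw$preds - y
        batch_loss <- batch_loss + mean(resid^2)
        dpreds <- 2 * resid / (length(resid) * length(batch))
        g <- .backward_slice(fw, dpreds, params, config, training = TRUE)
        grads <- .tree_add(grads, g)
      }
      if (!is.finite(batch_loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      step <- .adam_step(params[c("cell", "assay", "decoder")], grads, state, lr)
      params[c("cell", "assay", "decoder")] <- step$params
      state <- step$state
      epoch_losses <- c(epoch_losses, batch_loss / length(batch))
    }
    loss_history <- c(loss_history, mean(epoch_losses))
    if (!is.null(log_path)) {
      utils::write.table(
        data.frame(epoch = seq_along(loss_history), loss = loss_history),
        log_path, sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
  }
  list(params = params, loss_history = loss_history)
}

#' Transfer a pretrained model to a new individual
#'
#' Two-stage protocol for individual-specific imputation: a model pretrained
#' on the fully mapped training individual is fine-tuned on the target
#' individual's observations excluding the held-out tissue, with
#' tissue-wise masking and a reduced learning rate. Held-out-tissue tracks
#' never enter any input slice or loss term.
#'
#' @param pretrained `model_params` from [train_edice()] on the training
#'   individual.
#' @param target_tensor the target individual's [signal_tensor()].
#' @param held_out_cell cell-type id (name or index) of the hidden tissue.
#' @param config a [model_config()].
#' @param train a [train_config()]; `finetune_epochs` and `finetune_lr`
#'   control this stage.
#' @return list with `params` and `loss_history` (fine-tuning epochs).
#' @export
transfer_fit <- function(pretrained, target_tensor, held_out_cell,
                         config = model_config(), train = train_config()) {
  stopifnot(inherits(target_tensor, "signal_tensor"))
  if (is.character(held_out_cell)) {
    held_out_cell <- match(held_out_cell, target_tensor$cell_ids)
  }
  if (is.na(held_out_cell) || held_out_cell < 1 ||
      held_out_cell > dim(target_tensor$values)[1]) {
    stop("held-out tissue not found in target tensor")
  }
  if (train$finetune_epochs == 0L) {
    return(list(params = pretrained, loss_history = numeric(0)))
  }
  trainable <- target_tensor$observed
  trainable[held_out_cell, ] <- FALSE
  train_edice(
    target_tensor, config, train,
    params = pretrained, trainable = trainable,
    epochs = train$finetune_epochs, learning_rate = train$finetune_lr,
    mask_scheme = "tissue_wise"
  )
}
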