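#' Specification of a synthetic epigenome tensor
#'
#' The generator emulates the structure the imputation model exploits: a
#' low-rank cross-track background (cell and assay latent factors), smooth
#' per-bin modulation, and peak-shaped enrichments planted per assay at
#' shared loci with cell-specific amplitudes, over a partially observed
#' mask in which a core set of assays is measured in every cell type and
#' the remainder only sparsely.
#'
#' Defaults describe the desk-scale world used throughout the test suite:
#' 12 cell types x 8 assays x 20,000 bins (500 kb at 25 bp), 5 core assays,
#' 50% coverage elsewhere, ~1 peak per 10 kb of mean width 300 bp, additive
#' truncated-Gaussian noise with sd 0.2 on the measurement scale (chosen so
#' that measurement noise caps the attainable genome-wide correlation near
#' 0.9, comparable to replicate concordance of real tracks).
#'
#' @param n_cells,n_assays,n_bins tensor dimensions.
#' @param latent_dim dimension of the cell/assay latent factors.
#' @param core_assays number of assays observed in every cell type.
#' @param coverage observation probability for non-core tracks.
#' @param peak_rate expected peaks per 10 kb per assay.
#' @param peak_width_bp mean peak width (4 sd of the Gaussian bump).
#' @param noise_sd measurement noise sd on the -log10 p scale.
#' @param individual_effect fraction of peaks made individual-specific in
#'   [generate_individual_pair()].
#' @param bin_size bin width in bp.
#' @param seed RNG seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 12L, n_assays = 8L, n_bins = 20000L,
                           latent_dim = 3L, core_assays = 5L, coverage = 0.5,
                           peak_rate = 1, peak_width_bp = 300,
                           noise_sd = 0.2, individual_effect = 0,
                           bin_size = 25L, seed = 1L) {
  stopifnot(
    n_cells >= 1, n_assays >= 1, n_bins >= 1, latent_dim >= 1,
    core_assays >= 1, core_assays <= n_assays,
    coverage > 0, coverage <= 1,
    peak_rate >= 0, peak_width_bp > 0, noise_sd >= 0,
    individual_effect >= 0, individual_effect <= 1
  )
  structure(
    list(
      n_cells = as.integer(n_cells), n_assays = as.integer(n_assays),
      n_bins = as.integer(n_bins), latent_dim = as.integer(latent_dim),
      core_assays = as.integer(core_assays), coverage = coverage,
      peak_rate = peak_rate, peak_width_bp = peak_width_bp,
      noise_sd = noise_sd, individual_effect = individual_effect,
      bin_size = as.integer(bin_size), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# smooth positive per-bin modulation with mean ~1
.smooth_process <- function(n_bins, window = 100L, sd_log = 0.25) {
  x <- stats::rnorm(n_bins + window)
  sm <- stats::filter(x, rep(1 / window, window), sides = 2L)
  sm <- sm[!is.na(sm)][seq_len(n_bins)]
  sm <- sm / stats::sd(sm) * sd_log
  exp(sm - sd_log^2 / 2)
}

# the generative "blueprint" shared by both individuals of a pair: latents,
# modulation, peak loci and amplitudes. `amplitude_mode` controls how peak
# strength varies over cells: "cell_specific" (default; amplitudes depend on
# the cell latent, the structure the imputer exploits), "shared" (identical
# across cells) or "cell_exclusive" (each peak in one random cell only, the
# hard case).
.synth_blueprint <- function(spec, latents = NULL,
                             amplitude_mode = "cell_specific") {
  L <- spec$latent_dim
  z <- latents$z %||% matrix(stats::rnorm(spec$n_cells * L), spec$n_cells, L)
  w <- latents$w %||% matrix(stats::rnorm(spec$n_assays * L), spec$n_assays, L)
  stopifnot(nrow(z) == spec$n_cells, nrow(w) == spec$n_assays)
  s <- .smooth_process(spec$n_bins)
  genome_bp <- spec$n_bins * spec$bin_size
  peaks <- vector("list", spec$n_assays)
  for (j in seq_len(spec$n_assays)) {
    n_pk <- stats::rpois(1L, spec$peak_rate * genome_bp / 1e4)
    if (n_pk == 0L) {
      peaks[[j]] <- data.frame(center = numeric(0), sd_bins = numeric(0))
      next
    }
    center <- stats::runif(n_pk, 1, spec$n_bins)
    sd_bins <- spec$peak_width_bp / 4 / spec$bin_size * stats::runif(n_pk, 0.75, 1.25)
    amp <- matrix(0, spec$n_cells, n_pk)
    for (p in seq_len(n_pk)) {
      v <- stats::rnorm(L)
      amp[, p] <- switch(amplitude_mode,
        cell_specific = 6 * softplus(z %*% v),
        shared = rep(6 * softplus(sum(v) / sqrt(L)), spec$n_cells),
        cell_exclusive = {
          a <- numeric(spec$n_cells)
          a[sample.int(spec$n_cells, 1L)] <- 6 * softplus(sum(v) / sqrt(L))
          a
        },
        stop("unknown amplitude_mode `", amplitude_mode, "`")
      )
    }
    peaks[[j]] <- list(center = center, sd_bins = sd_bins, amp = amp)
  }
  # observation mask: core assays everywhere, coverage elsewhere, with at
  # least two observed cells per non-core assay so averaging baselines and
  # splits are well-defined
  observed <- matrix(FALSE, spec$n_cells, spec$n_assays)
  observed[, seq_len(spec$core_assays)] <- TRUE
  if (spec$n_assays > spec$core_assays) {
    for (j in (spec$core_assays + 1L):spec$n_assays) {
      obs_j <- stats::runif(spec$n_cells) < spec$coverage
      while (sum(obs_j) < 2L) obs_j[sample.int(spec$n_cells, 1L)] <- TRUE
      observed[, j] <- obs_j
    }
  }
  list(z = z, w = w, s = s, peaks = peaks, observed = observed)
}

# render one individual's tensor from a blueprint; `keep` is a list per
# assay of logical vectors marking which peaks this individual carries
.render_tensor <- function(spec, bp, keep = NULL, amp_threshold = 1) {
  clean <- array(0, c(spec$n_cells, spec$n_assays, spec$n_bins))
  bg_level <- softplus(tcrossprod(bp$z, bp$w))  # n_cells x n_assays
  track_peaks <- vector("list", spec$n_cells * spec$n_assays)
  dim(track_peaks) <- c(spec$n_cells, spec$n_assays)
  kgrid <- seq_len(spec$n_bins)
  for (j in seq_len(spec$n_assays)) {
    for (i in seq_len(spec$n_cells)) {
      clean[i, j, ] <- bg_level[i, j] * bp$s
    }
    pk <- bp$peaks[[j]]
    if (!length(pk$center)) next
    sel <- if (is.null(keep)) rep(TRUE, length(pk$center)) else keep[[j]]
    for (p in which(sel)) {
      c_p <- pk$center[p]
      sd_p <- pk$sd_bins[p]
      win <- max(1L, floor(c_p - 4 * sd_p)):min(spec$n_bins, ceiling(c_p + 4 * sd_p))
      bump <- exp(-(win - c_p)^2 / (2 * sd_p^2))
      for (i in seq_len(spec$n_cells)) {
        clean[i, j, win] <- clean[i, j, win] + pk$amp[i, p] * bump
      }
    }
    # record planted per-track peak intervals (bp, 0-based half-open)
    for (i in seq_len(spec$n_cells)) {
      strong <- which(sel & pk$amp[i, ] > amp_threshold)
      if (length(strong)) {
        start <- pmax(0, floor((pk$center[strong] - 2 * pk$sd_bins[strong]) * spec$bin_size))
        end <- pmin(spec$n_bins * spec$bin_size,
                    ceiling((pk$center[strong] + 2 * pk$sd_bins[strong]) * spec$bin_size))
        track_peaks[[i, j]] <- .merge_intervals(start, end)
      } else {
        track_peaks[[i, j]] <- data.frame(start = numeric(0), end = numeric(0))
      }
    }
  }
  noisy <- clean
  if (spec$noise_sd > 0) {
    noisy <- pmax(clean + array(stats::rnorm(length(clean), sd = spec$noise_sd),
                                dim(clean)), 0)
  }
  list(clean = asinh(clean), noisy = asinh(noisy), track_peaks = track_peaks)
}

.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- c()
  out_e <- c()
  for (r in seq_along(start)[-1]) {
    if (start[r] <= me) {
      me <- max(me, end[r])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[r]; me <- end[r]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Generate a synthetic partially observed signal tensor
#'
#' @param spec a [synthetic_spec()].
#' @param split_fractions track-level train/val/test fractions for the
#'   embedded track table (default 0.7/0.1/0.2, mirroring typical
#'   consortium splits).
#' @param latents optional list with `z` (`n_cells x latent_dim`) and `w`
#'   (`n_assays x latent_dim`) overriding the drawn latent factors
#'   (degenerate constructions for testing).
#' @param amplitude_mode `"cell_specific"` (default), `"shared"`, or
#'   `"cell_exclusive"` peak amplitudes across cells.
#' @return list with `tensor` (a [signal_tensor()] of noisy arcsinh signal,
#'   unobserved tracks zeroed, with a track table), `clean` (noise-free
#'   arcsinh array, all tracks), `latents` (cell/assay factors and bin
#'   modulation), and `peaks` (cell x assay list-matrix of planted per-track
#'   peak intervals in bp).
#' @export
generate_tensor <- function(spec, split_fractions = c(0.7, 0.1, 0.2),
                            latents = NULL,
                            amplitude_mode = "cell_specific") {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  bp <- .synth_blueprint(spec, latents, amplitude_mode)
  r <- .render_tensor(spec, bp)
  .assemble_tensor(spec, bp, r, split_fractions)
}

.assemble_tensor <- function(spec, bp, r, split_fractions) {
  vals <- r$noisy
  for (i in seq_len(spec$n_cells)) {
    vals[i, !bp$observed[i, ], ] <- 0
  }
  binning <- genomic_binning("chrS", spec$n_bins * spec$bin_size, spec$bin_size)
  split <- split_tracks(bp$observed, split_fractions, seed = spec$seed + 7L)
  obs_idx <- which(bp$observed, arr.ind = TRUE)
  cell_ids <- paste0("C", seq_len(spec$n_cells))
  assay_ids <- paste0("A", seq_len(spec$n_assays))
  tt <- track_table(
    track_id = paste0(cell_ids[obs_idx[, 1]], "_", assay_ids[obs_idx[, 2]]),
    cell_type_id = cell_ids[obs_idx[, 1]],
    assay_id = assay_ids[obs_idx[, 2]],
    split = split[obs_idx]
  )
  tensor <- signal_tensor(vals, bp$observed, binning, tracks = tt,
                          cell_ids = cell_ids, assay_ids = assay_ids)
  list(tensor = tensor, clean = r$clean,
       latents = list(z = bp$z, w = bp$w, s = bp$s, peaks = bp$peaks),
       peaks = r$track_peaks)
}

#' Generate a two-individual synthetic scenario
#'
#' Individuals A ("training") and B ("target") share the same latent tissue
#' structure and peak blueprint; a fraction `individual_effect` of peaks is
#' toggled, half removed from B (A-only) and half removed from A (B-only).
#' B-only peak intervals per track are returned as ground-truth
#' individual-specific regions (every planted peak spans >= 150 bp, so none
#' is filtered by the minimum-length rule). Noise is drawn independently
#' per individual.
#'
#' @param spec a [synthetic_spec()]; with `individual_effect = 0` the two
#'   tensors differ only in their noise draws and no individual-specific
#'   region exists.
#' @return list with `tensor_a`, `tensor_b` (as in [generate_tensor()],
#'   full observation for A, same mask for B), `clean_a`, `clean_b`,
#'   `peaks_a`, `peaks_b` (planted per-track peaksets),
#'   `individual_specific` (cell x assay list-matrix of B-only intervals),
#'   and `keep_a`/`keep_b` (per-assay logical vectors of carried peaks).
#' @export
generate_individual_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  bp <- .synth_blueprint(spec)
  keep_a <- keep_b <- vector("list", spec$n_assays)
  for (j in seq_len(spec$n_assays)) {
    n_pk <- length(bp$peaks[[j]]$center)
    keep_a[[j]] <- rep(TRUE, n_pk)
    keep_b[[j]] <- rep(TRUE, n_pk)
    if (n_pk == 0L) next
    toggled <- stats::runif(n_pk) < spec$individual_effect
    to_a_only <- toggled & (stats::runif(n_pk) < 0.5)
    to_b_only <- toggled & !to_a_only
    keep_b[[j]][to_a_only] <- FALSE
    keep_a[[j]][to_b_only] <- FALSE
  }
  ra <- .render_tensor(spec, bp, keep_a)
  rb <- .render_tensor(spec, bp, keep_b)
  # B-only regions per track: planted peaks kept in B but not in A
  ind_spec <- vector("list", spec$n_cells * spec$n_assays)
  dim(ind_spec) <- c(spec$n_cells, spec$n_assays)
  for (j in seq_len(spec$n_assays)) {
    pk <- bp$peaks[[j]]
    b_only <- which(keep_b[[j]] & !keep_a[[j]])
    for (i in seq_len(spec$n_cells)) {
      strong <- b_only[pk$amp[i, b_only] > 1]
      if (length(strong)) {
        start <- pmax(0, floor((pk$center[strong] - 2 * pk$sd_bins[strong]) * spec$bin_size))
        end <- pmin(spec$n_bins * spec$bin_size,
                    ceiling((pk$center[strong] + 2 * pk$sd_bins[strong]) * spec$bin_size))
        ind_spec[[i, j]] <- .merge_intervals(start, end)
      } else {
        ind_spec[[i, j]] <- data.frame(start = numeric(0), end = numeric(0))
      }
    }
  }
  a <- .assemble_tensor(spec, bp, ra, c(1, 0, 0))
  b <- .assemble_tensor(spec, bp, rb, c(1, 0, 0))
  list(
    tensor_a = a$tensor, tensor_b = b$tensor,
    clean_a = ra$clean, clean_b = rb$clean,
    peaks_a = ra$track_peaks, peaks_b = rb$track_peaks,
    individual_specific = ind_spec,
    keep_a = keep_a, keep_b = keep_b
  )
}

#' Split tracks into train/val/test
#'
#' Random track-level split in which every cell type and every assay
#' retains at least one training track, so both encoders always have
#' context signal.
#'
#' @param observed logical cell x assay matrix.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed RNG seed.
#' @return character matrix of the same shape with entries `"train"`,
#'   `"val"`, `"test"` for observed tracks and `NA` elsewhere.
#' @export
split_tracks <- function(observed, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(is.matrix(observed), is.logical(observed))
  if (abs(sum(fractions) - 1) > 1e-8) stop("`fractions` must sum to 1")
  if (any(rowSums(observed) == 0L) || any(colSums(observed) == 0L)) {
    stop("every cell type and assay needs at least one observed track")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- matrix(NA_character_, nrow(observed), ncol(observed))
  idx <- which(observed, arr.ind = TRUE)
  n <- nrow(idx)
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  # seed the training set so each cell and assay keeps context
  forced <- integer(0)
  for (i in seq_len(nrow(observed))) {
    cand <- which(idx[, 1] == i)
    forced <- c(forced, cand[sample.int(length(cand), 1L)])
  }
  for (j in seq_len(ncol(observed))) {
    cand <- which(idx[, 2] == j)
    if (!any(cand %in% forced)) {
      forced <- c(forced, cand[sample.int(length(cand), 1L)])
    }
  }
  forced <- unique(forced)
  avail <- n - length(forced)
  if (n_val + n_test > avail) {
    # keep the context constraint; shrink held-out counts proportionally
    total <- avail
    n_val <- round(total * fractions[2] / max(fractions[2] + fractions[3], 1e-12))
    n_test <- total - n_val
  }
  rest <- setdiff(seq_len(n), forced)
  rest <- rest[sample.int(length(rest))]
  val <- rest[seq_len(n_val)]
  test <- rest[n_val + seq_len(n_test)]
  assign_split <- rep("train", n)
  assign_split[val] <- "val"
  assign_split[test] <- "test"
  out[idx] <- assign_split
  out
}
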