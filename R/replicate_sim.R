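#' Estimate per-region negative-binomial variability
#'
#' Method-of-moments estimator over replicated region counts: the mean is
#' the sample mean and the size (dispersion) parameter is
#' `r = mu^2 / (var - mu)` when the sample variance exceeds the mean, else
#' `r = Inf` (the Poisson limit). Variance of the NB is `mu + mu^2/r`.
#'
#' With few replicates the plug-in `mu^2` is noticeably biased upward
#' (`E[mu_hat^2] = mu^2 + var/n`), inflating `r`; by default the unbiased
#' moment `mu_hat^2 - var_hat/n` is substituted (`correct_bias = TRUE`),
#' falling back to the plain plug-in where the corrected numerator is not
#' positive.
#'
#' @param replicate_counts numeric matrix, regions x replicates (>= 2
#'   replicates), of nonnegative counts.
#' @param regions optional data.frame of region coordinates (`start`,
#'   `end`), carried through to the result.
#' @param correct_bias logical; apply the finite-replicate correction of
#'   the squared-mean moment (default TRUE).
#' @return an object of class `replicate_model`: data.frame with columns
#'   `mu` and `size` (one row per region) plus any region coordinates.
#' @export
estimate_nb <- function(replicate_counts, regions = NULL, correct_bias = TRUE) {
  m <- as.matrix(replicate_counts)
  if (ncol(m) < 2L) stop("need >= 2 replicates per region")
  if (any(m < 0)) stop("negative count at region ", which(rowSums(m < 0) > 0)[1L])
  mu <- rowMeans(m)
  v <- apply(m, 1L, stats::var)
  mu2 <- mu^2
  if (correct_bias) {
    corrected <- mu2 - v / ncol(m)
    mu2 <- ifelse(corrected > 0, corrected, mu2)
  }
  size <- ifelse(v > mu & mu > 0, mu2 / (v - mu), Inf)
  out <- data.frame(mu = mu, size = size)
  if (!is.null(regions)) out <- cbind(regions, out)
  class(out) <- c("replicate_model", "data.frame")
  out
}

#' Simulate pseudo-replicates from a mean track
#'
#' For each model region, draws `n_reps` independent negative-binomial
#' counts with mean equal to the region-aggregated inverse-arcsinh imputed
#' signal and the region's estimated size parameter (`size = Inf` draws
#' Poisson). Deterministic under `seed`.
#'
#' @param mean_track numeric per-bin imputed signal on the arcsinh scale.
#' @param model a [estimate_nb()] result whose rows carry `start`/`end`
#'   region coordinates in bp.
#' @param binning a [genomic_binning()].
#' @param n_reps number of replicates (>= 2).
#' @param seed RNG seed.
#' @return integer matrix, regions x `n_reps`, of simulated counts.
#' @export
simulate_replicates <- function(mean_track, model, binning, n_reps = 3L,
                                seed = 1L) {
  stopifnot(inherits(model, "replicate_model"))
  if (n_reps < 2L) stop("n_reps must be >= 2 (differential analysis needs replicates)")
  if (is.null(model$start) || is.null(model$end)) {
    stop("model must carry region `start`/`end` coordinates")
  }
  if (any(model$end > binning$chrom_length)) stop("region outside track bounds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- inverse_arcsinh(mean_track)
  bs <- binning$bin_size
  out <- matrix(0L, nrow(model), n_reps)
  for (r in seq_len(nrow(model))) {
    first <- floor(model$start[r] / bs) + 1L
    last <- min(binning$n_bins, ceiling(model$end[r] / bs))
    mu <- sum(x[first:last])
    if (mu <= 0) next
    out[r, ] <- if (is.finite(model$size[r])) {
      stats::rnbinom(n_reps, size = model$size[r], mu = mu)
    } else {
      stats::rpois(n_reps, mu)
    }
  }
  colnames(out) <- sprintf("rep%d", seq_len(n_reps))
  out
}

#' Wasserstein-1 distance between two signal shapes
#'
#' Both vectors are normalised to unit mass; the 1-D Wasserstein-1 distance
#' is then `bin_width * sum(|CDF_a - CDF_b|)`, the minimal cost of
#' transporting one normalized pile-up onto the other.
#'
#' @param signal_a,signal_b nonnegative vectors over the same region, each
#'   with at least one positive entry.
#' @param bin_width bin width in bp (distance unit).
#' @return scalar distance in bp.
#' @export
wasserstein_peak_distance <- function(signal_a, signal_b, bin_width = 25) {
  stopifnot(length(signal_a) == length(signal_b))
  if (any(signal_a < 0) || any(signal_b < 0)) stop("signals must be nonnegative")
  sa <- sum(signal_a)
  sb <- sum(signal_b)
  if (sa == 0 || sb == 0) stop("all-zero signal has no shape")
  bin_width * sum(abs(cumsum(signal_a / sa) - cumsum(signal_b / sb)))
}

#' Export a binding-affinity count matrix
#'
#' Sums each replicate's counts within each consensus region, producing the
#' regions x replicates matrix consumed by external differential-enrichment
#' tools. Written (optionally) as TSV with BED-style region columns.
#'
#' @param peakset consensus [peak_set()] (e.g. merged union of
#'   per-condition peak sets).
#' @param replicate_tracks list of numeric per-bin count tracks, all on the
#'   same binning; names become column names.
#' @param binning a [genomic_binning()].
#' @param path optional TSV output path.
#' @return numeric matrix, regions x replicates.
#' @export
export_affinity_matrix <- function(peakset, replicate_tracks, binning,
                                   path = NULL) {
  stopifnot(inherits(peakset, "peak_set"), is.list(replicate_tracks))
  if (any(peakset$end > binning$chrom_length)) {
    stop("region outside track bounds")
  }
  bs <- binning$bin_size
  n_reg <- nrow(peakset)
  out <- matrix(0, n_reg, length(replicate_tracks))
  for (t in seq_along(replicate_tracks)) {
    trk <- replicate_tracks[[t]]
    stopifnot(length(trk) == binning$n_bins)
    for (r in seq_len(n_reg)) {
      first <- floor(peakset$start[r] / bs) + 1L
      last <- min(binning$n_bins, ceiling(peakset$end[r] / bs))
      out[r, t] <- sum(trk[first:last])
    }
  }
  colnames(out) <- names(replicate_tracks) %||%
    sprintf("rep%d", seq_along(replicate_tracks))
  if (!is.null(path)) {
    df <- data.frame(
      chrom = attr(peakset, "chrom"),
      start = as.integer(peakset$start), end = as.integer(peakset$end),
      out, check.names = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Merge two peak sets into a consensus set
#'
#' Union of intervals with overlapping or bookended intervals merged.
#'
#' @param ... [peak_set()]s on the same chromosome.
#' @return a [peak_set()].
#' @export
consensus_peaks <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, nrow, 1L) > 0]
  if (!length(sets)) return(peak_set())
  chrom <- attr(sets[[1]], "chrom")
  start <- unlist(lapply(sets, `[[`, "start"))
  end <- unlist(lapply(sets, `[[`, "end"))
  m <- .merge_intervals(start, end)
  peak_set(m$start, m$end, numeric(nrow(m)), chrom)
}
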