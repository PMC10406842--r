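#' Genomic peak set
#'
#' Sorted, non-overlapping 0-based half-open intervals on one chromosome,
#' each scored with the maximum -log10 adjusted p-value of its bins.
#'
#' @param start,end numeric vectors (bp, 0-based half-open).
#' @param score numeric vector of per-peak scores.
#' @param chrom chromosome name.
#' @return a `data.frame` of class `peak_set`.
#' @export
peak_set <- function(start = numeric(0), end = numeric(0),
                     score = numeric(length(start)), chrom = "chr") {
  stopifnot(length(start) == length(end), length(score) == length(start))
  if (any(end <= start)) stop("peak intervals need end > start")
  o <- order(start)
  ps <- data.frame(start = start[o], end = end[o], score = score[o])
  if (nrow(ps) > 1 && any(ps$start[-1] < ps$end[-nrow(ps)])) {
    stop("peak intervals must be non-overlapping")
  }
  attr(ps, "chrom") <- chrom
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' Enriched-bin indicator of a peak set
#'
#' @param peaks a [peak_set()].
#' @param binning a [genomic_binning()].
#' @return logical vector over bins; TRUE where the bin overlaps a peak by
#'   at least 1 bp.
#' @export
peak_bins <- function(peaks, binning) {
  out <- logical(binning$n_bins)
  if (!nrow(peaks)) return(out)
  bs <- binning$bin_size
  first <- pmax(1L, floor(peaks$start / bs) + 1L)
  last <- pmin(binning$n_bins, ceiling(peaks$end / bs))
  for (r in seq_len(nrow(peaks))) out[first[r]:last[r]] <- TRUE
  out
}

#' Simplified Poisson/BH peak caller
#'
#' A deterministic simplification of MACS2-style enrichment detection: each
#' bin's (inverse-arcsinh, rounded) signal is treated as a count and tested
#' against a background rate with a one-sided upper-tail Poisson test;
#' p-values are Benjamini-Hochberg adjusted across all bins of the track,
#' and bins with adjusted p <= `alpha` are merged into peaks when
#' contiguous (no gap tolerance). The background rate is the track mean
#' (`lambda_mode = "global"`), or MACS2-style the maximum of the global
#' mean and local 1 kb/5 kb/10 kb window means (`"local"`).
#'
#' @param track numeric per-bin signal vector.
#' @param binning a [genomic_binning()].
#' @param alpha adjusted-p cutoff (default 0.01).
#' @param lambda_mode `"global"` or `"local"`.
#' @param scale scale of `track`: `"arcsinh"` (inverted before testing) or
#'   `"measurement"`.
#' @return a [peak_set()]; empty for an all-zero track.
#' @export
poisson_peak_call <- function(track, binning, alpha = 0.01,
                              lambda_mode = c("global", "local"),
                              scale = c("arcsinh", "measurement")) {
  lambda_mode <- match.arg(lambda_mode)
  scale <- match.arg(scale)
  stopifnot(length(track) == binning$n_bins)
  if (any(track < 0)) stop("track must be nonnegative")
  x <- if (scale == "arcsinh") inverse_arcsinh(track) else track
  counts <- round(x)
  lambda_global <- mean(x)
  if (lambda_global == 0) return(peak_set(chrom = binning$chrom))
  if (lambda_mode == "global") {
    lambda <- rep(lambda_global, binning$n_bins)
  } else {
    win_mean <- function(w_bp) {
      w <- max(1L, round(w_bp / binning$bin_size))
      as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L, circular = TRUE))
    }
    lambda <- pmax(lambda_global, win_mean(1000), win_mean(5000), win_mean(10000))
  }
  pval <- stats::ppois(counts - 1, lambda, lower.tail = FALSE)
  padj <- stats::p.adjust(pval, method = "BH")
  sig <- padj <= alpha
  if (!any(sig)) return(peak_set(chrom = binning$chrom))
  r <- rle(sig)
  stop_bin <- cumsum(r$lengths)
  start_bin <- stop_bin - r$lengths + 1L
  keep <- r$values
  starts <- start_bin[keep]
  stops <- stop_bin[keep]
  score <- vapply(seq_along(starts), function(k) {
    max(-log10(pmax(padj[starts[k]:stops[k]], 1e-300)))
  }, numeric(1))
  bs <- binning$bin_size
  peak_set(
    start = (starts - 1L) * bs,
    end = pmin(stops * bs, binning$chrom_length),
    score = score, chrom = binning$chrom
  )
}

#' MSE and Pearson correlation, stratified by enrichment
#'
#' Computes mean squared error and Pearson correlation between an imputed
#' and an observed track on the arcsinh scale, genome-wide and restricted
#' to foreground (enriched) and background bins. Pearson on a stratum with
#' fewer than 2 bins or zero variance is reported as `NA`.
#'
#' @param imputed,observed numeric vectors of equal length.
#' @param foreground logical vector marking enriched bins (derived from the
#'   observed track's peak set).
#' @return list with `mse` and `pearson`, each a named numeric vector over
#'   `global`, `fg`, `bg`.
#' @export
stratified_mse_pearson <- function(imputed, observed, foreground) {
  stopifnot(length(imputed) == length(observed),
            length(foreground) == length(observed))
  one <- function(sel) {
    a <- imputed[sel]
    b <- observed[sel]
    mse <- if (length(a)) mean((a - b)^2) else NA_real_
    pe <- if (length(a) >= 2 && stats::sd(a) > 0 && stats::sd(b) > 0) {
      stats::cor(a, b)
    } else {
      NA_real_
    }
    c(mse = mse, pearson = pe)
  }
  g <- one(rep(TRUE, length(imputed)))
  f <- one(foreground)
  b <- one(!foreground)
  list(
    mse = c(global = g[["mse"]], fg = f[["mse"]], bg = b[["mse"]]),
    pearson = c(global = g[["pearson"]], fg = f[["pearson"]], bg = b[["pearson"]])
  )
}

#' Area under the precision-recall curve
#'
#' Step-function area over all score thresholds (average precision); equal
#' scores are grouped into a single threshold.
#'
#' @param scores numeric vector (higher = more peak-like).
#' @param labels logical or 0/1 vector of enriched-bin indicators.
#' @return scalar in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0L || P == length(labels)) {
    stop("labels must contain at least one positive and one negative")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  grp_last <- which(diff(s) != 0)
  grp_last <- c(grp_last, length(s))
  tp_cum <- cumsum(l)[grp_last]
  n_cum <- grp_last
  tp_gain <- diff(c(0, tp_cum))
  sum(tp_gain / P * (tp_cum / n_cum))
}

#' Precision and recall between two peak sets
#'
#' Evaluated at bin resolution over enriched-bin sets. Precision is `NA`
#' when the predicted set is empty (recall is then 0).
#'
#' @param predicted,reference [peak_set()]s on the same chromosome.
#' @param binning a [genomic_binning()].
#' @return named numeric vector `c(precision, recall)`.
#' @export
peakset_precision_recall <- function(predicted, reference, binning) {
  pb <- peak_bins(predicted, binning)
  rb <- peak_bins(reference, binning)
  inter <- sum(pb & rb)
  precision <- if (sum(pb)) inter / sum(pb) else NA_real_
  recall <- if (sum(rb)) inter / sum(rb) else 0
  c(precision = precision, recall = recall)
}

#' Individual-specific evaluation regions
#'
#' Builds the evaluation mask and labels for individual-specific peak
#' scoring: target-individual peaks that overlap (share >= 1 bp with) any
#' training-individual peak are conserved and their bins are excluded from
#' evaluation; target-only peaks shorter than `min_len` are excluded as
#' spurious; the remaining target-only peaks' bins are positives and all
#' other included bins are negatives.
#'
#' @param target_peaks,training_peaks [peak_set()]s for the two individuals.
#' @param binning a [genomic_binning()].
#' @param min_len minimum individual-specific peak length in bp
#'   (default 150, roughly one nucleosome of wrapped DNA).
#' @return list with `eval_mask` (logical; TRUE = bin enters evaluation)
#'   and `labels` (logical; positive bins).
#' @export
individual_specific_regions <- function(target_peaks, training_peaks, binning,
                                        min_len = 150) {
  n <- binning$n_bins
  eval_mask <- rep(TRUE, n)
  labels <- rep(FALSE, n)
  if (!nrow(target_peaks)) return(list(eval_mask = eval_mask, labels = labels))
  overlaps_training <- function(s, e) {
    if (!nrow(training_peaks)) return(FALSE)
    any(training_peaks$start < e & training_peaks$end > s)
  }
  for (r in seq_len(nrow(target_peaks))) {
    s <- target_peaks$start[r]
    e <- target_peaks$end[r]
    one <- peak_set(s, e, 0, attr(target_peaks, "chrom"))
    bins <- peak_bins(one, binning)
    if (overlaps_training(s, e)) {
      eval_mask[bins] <- FALSE        # conserved across individuals
    } else if ((e - s) < min_len) {
      eval_mask[bins] <- FALSE        # spurious short peak
    } else {
      labels[bins] <- TRUE            # individual-specific positive
    }
  }
  list(eval_mask = eval_mask, labels = labels)
}

#' AUPRC for individual-specific enrichment
#'
#' [auprc()] restricted to the evaluation mask from
#' [individual_specific_regions()], reported together with the positive
#' fraction (the random-scorer baseline). `auprc` is `NA` when the masked
#' region has no positives or no negatives.
#'
#' @param imputed numeric imputed track.
#' @param regions result of [individual_specific_regions()].
#' @return named numeric vector `c(auprc, pos_fraction, n_positive)`.
#' @export
individual_specific_auprc <- function(imputed, regions) {
  sel <- regions$eval_mask
  stopifnot(length(imputed) == length(sel))
  lab <- regions$labels[sel]
  sc <- imputed[sel]
  pos_fraction <- mean(lab)
  a <- if (any(lab) && !all(lab)) auprc(sc, lab) else NA_real_
  c(auprc = a, pos_fraction = pos_fraction, n_positive = sum(lab))
}

#' Write / read peak sets as BED
#'
#' BED6 output with scores scaled to the 0-1000 BED convention; BED and
#' narrowPeak files are accepted on read (score column rescaled back).
#'
#' @param peaks a [peak_set()].
#' @param path file path.
#' @export
write_peaks <- function(peaks, path) {
  chrom <- attr(peaks, "chrom") %||% "chr"
  score1000 <- if (nrow(peaks) && max(peaks$score) > 0) {
    as.integer(pmin(1000, round(peaks$score / max(peaks$score) * 1000)))
  } else {
    integer(nrow(peaks))
  }
  df <- data.frame(
    chrom = chrom, start = as.integer(peaks$start), end = as.integer(peaks$end),
    name = sprintf("peak_%d", seq_len(max(nrow(peaks), 0))),
    score = score1000, strand = "."
  )
  utils::write.table(df[seq_len(nrow(peaks)), ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @param chrom restrict to one chromosome (default: first seen).
#' @return `read_peaks()` returns a [peak_set()].
#' @export
read_peaks <- function(path, chrom = NULL) {
  if (file.size(path) == 0) return(peak_set(chrom = chrom %||% "chr"))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(chrom)) chrom <- df[[1]][1]
  df <- df[df[[1]] == chrom, , drop = FALSE]
  score <- if (ncol(df) >= 5) as.numeric(df[[5]]) else numeric(nrow(df))
  peak_set(start = df[[2]], end = df[[3]], score = score, chrom = chrom)
}
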