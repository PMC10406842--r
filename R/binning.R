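#' Fixed-width genomic binning
#'
#' Describes the partition of one chromosome into non-overlapping fixed-width
#' bins. Bin `k` (1-based in R; 0-based in coordinates) covers
#' `[(k-1)*bin_size, k*bin_size)` in 0-based half-open bp coordinates; a
#' final partial bin covers the remaining bases.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin width in bp (default 25).
#' @return an object of class `genomic_binning` with fields `chrom`,
#'   `chrom_length`, `bin_size`, `n_bins`.
#' @export
genomic_binning <- function(chrom, chrom_length, bin_size = 25L) {
  chrom_length <- as.integer(chrom_length)
  bin_size <- as.integer(bin_size)
  if (is.na(chrom_length) || chrom_length < 1L) stop("`chrom_length` must be >= 1")
  if (is.na(bin_size) || bin_size < 1L) stop("`bin_size` must be >= 1")
  structure(
    list(
      chrom = as.character(chrom),
      chrom_length = chrom_length,
      bin_size = bin_size,
      n_bins = as.integer(ceiling(chrom_length / bin_size))
    ),
    class = "genomic_binning"
  )
}

#' @export
print.genomic_binning <- function(x, ...) {
  cat(sprintf(
    "<genomic_binning> %s: %d bp, %d bins of %d bp\n",
    x$chrom, x$chrom_length, x$n_bins, x$bin_size
  ))
  invisible(x)
}

#' Bin a per-base signal vector to per-bin means
#'
#' Averages a per-base signal within each non-overlapping bin. A terminal
#' partial bin is averaged over its actual width, so constant signal stays
#' constant at chromosome ends.
#'
#' @param per_base numeric vector of length `binning$chrom_length`,
#'   nonnegative and finite.
#' @param binning a [genomic_binning()].
#' @return numeric vector of length `binning$n_bins` of per-bin means.
#' @export
bin_signal <- function(per_base, binning) {
  stopifnot(inherits(binning, "genomic_binning"))
  if (length(per_base) != binning$chrom_length) {
    stop(
      "`per_base` has length ", length(per_base),
      " but binning expects ", binning$chrom_length
    )
  }
  bad <- !is.finite(per_base) | per_base < 0
  if (any(bad)) {
    stop("negative or non-finite signal at position ", which(bad)[1L])
  }
  idx <- rep(seq_len(binning$n_bins),
    each = binning$bin_size,
    length.out = binning$chrom_length
  )
  sums <- as.numeric(rowsum(per_base, idx))  # groups sorted numerically
  widths <- tabulate(idx, nbins = binning$n_bins)
  sums / widths
}
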