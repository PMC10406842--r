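#' Read a signal track and bin it
#'
#' Reads a bedGraph or bigWig file of -log10 p-value signal, expands it to
#' per-base resolution over the chromosome described by `binning`, averages
#' within bins and applies the arcsinh transform. Bases not covered by any
#' record are treated as signal 0 (sparse-bedGraph semantics).
#'
#' @param source_path path to a bedGraph (4-column, 0-based half-open) or
#'   bigWig file.
#' @param binning a [genomic_binning()].
#' @return numeric vector of length `binning$n_bins` on the arcsinh scale.
#' @export
read_track <- function(source_path, binning) {
  stopifnot(inherits(binning, "genomic_binning"))
  if (file.exists(source_path) && file.size(source_path) == 0) {
    return(rep(0, binning$n_bins))
  }
  gr <- rtracklayer::import(source_path)
  gr <- gr[GenomicRanges::seqnames(gr) == binning$chrom]
  per_base <- rep(0, binning$chrom_length)
  if (length(gr) > 0) {
    # 0-based half-open on disk; rtracklayer yields 1-based closed
    starts <- GenomicRanges::start(gr)
    ends <- GenomicRanges::end(gr)
    ord <- order(starts)
    starts <- starts[ord]
    ends <- ends[ord]
    scores <- S4Vectors::mcols(gr)$score[ord]
    if (any(starts[-1] <= ends[-length(ends)])) {
      stop("overlapping intervals in ", source_path)
    }
    if (any(ends > binning$chrom_length)) {
      stop("interval beyond chromosome end in ", source_path)
    }
    for (r in seq_along(starts)) {
      per_base[starts[r]:ends[r]] <- scores[r]
    }
  }
  arcsinh_transform(bin_signal(per_base, binning))
}

#' Write a binned track as bedGraph
#'
#' Inverse-arcsinh is applied when `scale = "arcsinh"` so files hold the
#' measurement-scale signal. Runs of equal values are merged into single
#' records; zero runs are omitted (sparse convention).
#'
#' @param track numeric vector of per-bin values.
#' @param binning a [genomic_binning()].
#' @param path output file path.
#' @param scale scale of `track`: `"arcsinh"` (default; inverted on write)
#'   or `"measurement"`.
#' @export
write_bedgraph <- function(track, binning, path, scale = c("arcsinh", "measurement")) {
  scale <- match.arg(scale)
  stopifnot(length(track) == binning$n_bins)
  x <- if (scale == "arcsinh") inverse_arcsinh(track) else track
  n <- binning$n_bins
  bs <- binning$bin_size
  starts0 <- (seq_len(n) - 1L) * bs
  ends0 <- pmin(starts0 + bs, binning$chrom_length)
  run <- rle(x)
  stop_idx <- cumsum(run$lengths)
  start_idx <- stop_idx - run$lengths + 1L
  keep <- run$values != 0
  df <- data.frame(
    chrom = rep(binning$chrom, sum(keep)),
    start = starts0[start_idx[keep]],
    end = ends0[stop_idx[keep]],
    value = run$values[keep]
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
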