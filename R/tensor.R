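#' Track metadata table
#'
#' Builds and validates the table mapping each track to its coordinates in
#' the tensor: `(cell_type_id, assay_id, individual_id)` triples must be
#' unique, and `split` assigns each track to train/val/test.
#'
#' @param track_id character vector of track identifiers.
#' @param cell_type_id,assay_id character vectors, recycled to length.
#' @param individual_id optional character vector (NA when single-individual).
#' @param split factor/character in `train`, `val`, `test`.
#' @param source_path optional character vector of source files.
#' @return a `data.frame` with class `track_table`.
#' @export
track_table <- function(track_id, cell_type_id, assay_id,
                        individual_id = NA_character_,
                        split = "train", source_path = NA_character_) {
  tt <- data.frame(
    track_id = as.character(track_id),
    cell_type_id = as.character(cell_type_id),
    assay_id = as.character(assay_id),
    individual_id = as.character(individual_id),
    split = as.character(split),
    source_path = as.character(source_path),
    stringsAsFactors = FALSE
  )
  validate_track_table(tt)
  class(tt) <- c("track_table", "data.frame")
  tt
}

validate_track_table <- function(tt) {
  stopifnot(is.data.frame(tt))
  need <- c("track_id", "cell_type_id", "assay_id", "individual_id", "split")
  missing_cols <- setdiff(need, names(tt))
  if (length(missing_cols)) {
    stop("track table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tt$track_id)) stop("duplicate track_id values")
  key <- paste(tt$cell_type_id, tt$assay_id, tt$individual_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (cell_type_id, assay_id, individual_id) triple")
  }
  bad_split <- setdiff(unique(tt$split), c("train", "val", "test"))
  if (length(bad_split)) {
    stop("invalid split value(s): ", paste(bad_split, collapse = ", "))
  }
  invisible(tt)
}

#' Partially observed signal tensor
#'
#' The central container: a cell type x assay x bin array of
#' arcsinh-transformed signal plus a track-level observation mask. Values of
#' unobserved tracks are stored as zero by contract (missing tracks are
#' indistinguishable from masked ones downstream).
#'
#' @param values numeric 3-D array `[n_cells x n_assays x n_bins]`.
#' @param observed logical matrix `[n_cells x n_assays]`; TRUE where a track
#'   exists.
#' @param binning a [genomic_binning()] describing the bin axis.
#' @param tracks optional [track_table()] with one row per observed track.
#' @param cell_ids,assay_ids optional dimension names; default from dimnames
#'   or generated.
#' @return an object of class `signal_tensor`.
#' @export
signal_tensor <- function(values, observed, binning, tracks = NULL,
                          cell_ids = NULL, assay_ids = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  stopifnot(is.matrix(observed), is.logical(observed))
  stopifnot(inherits(binning, "genomic_binning"))
  d <- dim(values)
  if (!all(dim(observed) == d[1:2])) {
    stop("observation mask is ", paste(dim(observed), collapse = "x"),
         " but values are ", paste(d[1:2], collapse = "x"))
  }
  if (d[3] != binning$n_bins) {
    stop("values have ", d[3], " bins but binning has ", binning$n_bins)
  }
  if (any(!is.finite(values))) stop("tensor values must be finite")
  if (any(values < 0)) stop("tensor values must be >= 0 (arcsinh of nonnegative signal)")
  # missing tracks must be stored as zero
  for (i in seq_len(d[1])) {
    miss <- !observed[i, ]
    if (any(miss) && any(values[i, miss, , drop = FALSE] != 0)) {
      stop("values of unobserved tracks must be 0 (cell ", i, ")")
    }
  }
  if (is.null(cell_ids)) cell_ids <- dimnames(values)[[1]] %||% paste0("C", seq_len(d[1]))
  if (is.null(assay_ids)) assay_ids <- dimnames(values)[[2]] %||% paste0("A", seq_len(d[2]))
  dimnames(values) <- list(cell_ids, assay_ids, NULL)
  dimnames(observed) <- list(cell_ids, assay_ids)
  structure(
    list(
      values = values, observed = observed, binning = binning,
      tracks = tracks, cell_ids = cell_ids, assay_ids = assay_ids
    ),
    class = "signal_tensor"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.signal_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<signal_tensor> %d cell types x %d assays x %d bins (%s, %d bp bins); %d/%d tracks observed\n",
    d[1], d[2], d[3], x$binning$chrom, x$binning$bin_size,
    sum(x$observed), length(x$observed)
  ))
  invisible(x)
}

#' @export
dim.signal_tensor <- function(x) dim(x$values)

#' Restrict a tensor to a bin range
#'
#' @param tensor a [signal_tensor()].
#' @param bins integer vector of bin indices (1-based, contiguous).
#' @return a new `signal_tensor` over the selected bins.
#' @export
subset_bins <- function(tensor, bins) {
  stopifnot(inherits(tensor, "signal_tensor"))
  bins <- as.integer(bins)
  if (any(bins < 1L | bins > dim(tensor$values)[3])) stop("bin index out of range")
  b <- tensor$binning
  nb <- genomic_binning(b$chrom, length(bins) * b$bin_size, b$bin_size)
  signal_tensor(
    tensor$values[, , bins, drop = FALSE], tensor$observed, nb,
    tracks = tensor$tracks, cell_ids = tensor$cell_ids,
    assay_ids = tensor$assay_ids
  )
}

#' Persist a signal tensor
#'
#' Writes the value array, observation mask, binning metadata and track
#' table to a single-file store. The save/load round trip is bit-exact for
#' values and mask. The store is a versioned R serialisation (no HDF5 R
#' bindings are assumed on the host); the layout keys mirror an HDF5 group
#' (`values`, `observed`, `binning`, `tracks`).
#'
#' @param tensor a [signal_tensor()].
#' @param store_path file path to write.
#' @export
save_tensor <- function(tensor, store_path) {
  stopifnot(inherits(tensor, "signal_tensor"))
  obj <- list(
    format = "edice_tensor", version = 1L,
    values = tensor$values, observed = tensor$observed,
    binning = unclass(tensor$binning), tracks = tensor$tracks,
    cell_ids = tensor$cell_ids, assay_ids = tensor$assay_ids
  )
  saveRDS(obj, store_path)
  invisible(store_path)
}

#' Load a signal tensor, optionally restricted to a region
#'
#' @param store_path path written by [save_tensor()].
#' @param region optional integer vector `c(first_bin, last_bin)` (1-based,
#'   inclusive) restricting the bin axis.
#' @return a [signal_tensor()].
#' @export
load_tensor <- function(store_path, region = NULL) {
  obj <- readRDS(store_path)
  if (!identical(obj$format, "edice_tensor")) stop("not an edice tensor store")
  for (field in c("values", "observed", "binning")) {
    if (is.null(obj[[field]])) stop("store is missing field `", field, "`")
  }
  b <- obj$binning
  binning <- genomic_binning(b$chrom, b$chrom_length, b$bin_size)
  tensor <- signal_tensor(obj$values, obj$observed, binning,
    tracks = obj$tracks, cell_ids = obj$cell_ids, assay_ids = obj$assay_ids
  )
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1] <= region[2])
    tensor <- subset_bins(tensor, seq.int(region[1], region[2]))
  }
  tensor
}
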