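#' Arcsinh transform of a nonnegative signal
#'
#' Variance-stabilising transform applied to binned -log10 p-value signal
#' before modelling: `y = ln(x + sqrt(x^2 + 1))`. It compresses the heavy
#' right tail of enrichment tracks while staying linear near zero, and maps
#' 0 to 0 so absent signal stays absent.
#'
#' @param x numeric array of finite values (signal is expected to be >= 0).
#' @return array of the same shape with `asinh` applied elementwise.
#' @seealso [inverse_arcsinh()]
#' @export
arcsinh_transform <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (any(!is.finite(x))) {
    stop("non-finite value at position ", which(!is.finite(x))[1L])
  }
  asinh(x)
}

#' Invert the arcsinh transform
#'
#' @param y numeric array on the arcsinh scale.
#' @return array on the original (measurement) scale, `sinh(y)`.
#' @export
inverse_arcsinh <- function(y) {
  if (!is.numeric(y)) stop("`y` must be numeric")
  if (any(!is.finite(y))) {
    stop("non-finite value at position ", which(!is.finite(y))[1L])
  }
  sinh(y)
}
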