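#' @keywords internal
#' @importFrom EBImage erode dilate distmap
#' @importFrom igraph make_empty_graph add_edges components
#' @importFrom png readPNG writePNG
#' @importFrom tiff readTIFF
#' @importFrom jsonlite toJSON
#' @importFrom yaml read_yaml as.yaml
#' @importFrom utils modifyList
#' @importFrom stats rnorm runif
"_PACKAGE"

#' Validate a grayscale image matrix
#'
#' A grayscale image in symseg is a plain numeric matrix of intensities,
#' indexed `[row, col]` with 0-based geometry implied by the math (R's
#' 1-based indices are an implementation detail). Pipelines expect
#' intensities in `[0, 1]` after [normalize_gray()].
#'
#' @param image numeric matrix, at least 8x8, all finite.
#' @param arg name used in error messages.
#' @return the validated matrix, invisibly unchanged.
#' @export
as_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(image) < 8L || ncol(image) < 8L)
    stop(sprintf("`%s` must be at least 8x8 (got %dx%d)",
                 arg, nrow(image), ncol(image)), call. = FALSE)
  if (!all(is.finite(image)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  image
}

#' Validate a binary mask
#'
#' @param mask logical matrix.
#' @param shape optional `c(rows, cols)` the mask must match.
#' @param arg name used in error messages.
#' @return the validated logical matrix.
#' @export
as_binary_mask <- function(mask, shape = NULL, arg = "mask") {
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg), call. = FALSE)
  if (anyNA(mask))
    stop(sprintf("`%s` contains NA", arg), call. = FALSE)
  if (!is.null(shape) && !identical(dim(mask), as.integer(shape)))
    stop(sprintf("`%s` shape (%dx%d) does not match image shape (%dx%d)",
                 arg, nrow(mask), ncol(mask), shape[1], shape[2]),
         call. = FALSE)
  mask
}

#' Rescale intensities to the unit interval
#'
#' Min-max scaling to `[0, 1]`. A constant (zero-range) image maps to the
#' all-0.5 image rather than erroring, so blank slices flow through the
#' pipelines and trivially yield no detection. Idempotent.
#'
#' @param image numeric matrix.
#' @return numeric matrix with `min >= 0`, `max <= 1`.
#' @export
normalize_gray <- function(image) {
  as_gray_image(image)
  rng <- range(image)
  if (rng[2] - rng[1] <= 0) {
    image[] <- 0.5
    return(image)
  }
  (image - rng[1]) / (rng[2] - rng[1])
}

# Column-reversal-invariant sum: folding colSums with its own reverse makes
# the floating-point total identical for M and M[, ncol:1], which is what
# lets the pipelines be bit-exactly equivariant under left-right mirroring.
sum_sym <- function(m) {
  cs <- .colSums(m, nrow(m), ncol(m))
  sum((cs + rev(cs)) / 2)
}
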