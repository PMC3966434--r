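#' Disk structuring element
#'
#' Binary disk of the given pixel radius: offsets `(dr, dc)` with
#' `dr^2 + dc^2 <= radius^2`.
#'
#' @param radius positive integer.
#' @return 0/1 matrix of size `(2*radius+1)^2`.
#' @export
disk_kernel <- function(radius) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  d <- seq(-radius, radius)
  k <- outer(d^2, d^2, "+") <= radius^2
  storage.mode(k) <- "double"
  k
}

#' Morphological cleanup of a grayscale slice
#'
#' Grayscale morphology with a disk structuring element, used (optionally)
#' before the symmetry stage to suppress bright speckle that would otherwise
#' survive into the difference image. `"open"` is erosion followed by
#' dilation — the order used when this step precedes reflection — `"close"`
#' the reverse, and `"open-close"` applies both in that order.
#'
#' @param image numeric matrix.
#' @param radius disk radius in pixels; must satisfy
#'   `1 <= radius < min(dim(image)) / 2`.
#' @param mode one of `"open"`, `"close"`, `"open-close"`.
#' @return filtered matrix, same shape; values stay within the input range
#'   (opening is anti-extensive, closing extensive).
#' @export
morphological_clean <- function(image, radius = 2L,
                                mode = c("open", "close", "open-close")) {
  as_gray_image(image)
  mode <- match.arg(mode)
  radius <- as.integer(radius)
  if (radius < 1L || radius >= min(dim(image)) / 2)
    stop("radius must be in [1, min(rows, cols)/2)", call. = FALSE)
  k <- disk_kernel(radius)
  open_  <- function(x) EBImage::dilate(EBImage::erode(x, k), k)
  close_ <- function(x) EBImage::erode(EBImage::dilate(x, k), k)
  out <- switch(mode,
    "open"       = open_(image),
    "close"      = close_(image),
    "open-close" = close_(open_(image))
  )
  out <- as.matrix(out)
  dimnames(out) <- NULL
  out
}
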