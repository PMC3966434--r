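#' Mirror a slice about its vertical midline
#'
#' Returns the reflection `R[r, c] = O[r, cols - 1 - c]` (0-based): a
#' left-right flip about the inter-hemispheric axis, which for a centered
#' axial slice approximates swapping the hemispheres. An involution:
#' `reflect(reflect(x)) == x`. For odd widths the center column maps onto
#' itself.
#'
#' @param image numeric (or logical) matrix.
#' @return matrix of the same type and shape, columns reversed.
#' @export
reflect <- function(image) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  image[, ncol(image):1, drop = FALSE]
}

#' Signed and rectified hemispheric difference image
#'
#' Computes `D = O - R` in real arithmetic, where `R` is normally
#' [reflect]`(O)`. An asymmetric hyperintensity shows up as a positive
#' residual at its true location and (by mirror antisymmetry) a negative
#' residual at its mirror site; downstream stages consume the rectified
#' positive part so that each lesion's evidence stays at its own location,
#' which is what makes bilateral and multiple lesions separable.
#'
#' @param original numeric matrix `O`.
#' @param reflection numeric matrix `R`, same shape; defaults to
#'   `reflect(original)`.
#' @return object of class `difference_image`: list with `signed` (may be
#'   negative) and `rectified` (`pmax(signed, 0)`) matrices.
#' @export
difference_image <- function(original, reflection = reflect(original)) {
  as_gray_image(original, "original")
  as_gray_image(reflection, "reflection")
  if (!identical(dim(original), dim(reflection)))
    stop("`original` and `reflection` shapes differ", call. = FALSE)
  signed <- original - reflection
  structure(list(signed = signed, rectified = pmax(signed, 0)),
            class = "difference_image")
}

#' @export
print.difference_image <- function(x, ...) {
  cat(sprintf("<difference_image %dx%d, max rectified %.4f>\n",
              nrow(x$signed), ncol(x$signed), max(x$rectified)))
  invisible(x)
}

#' Estimate a small lateral midline offset
#'
#' Searches integer column shifts within `+/- max_frac * cols` for the one
#' maximizing the correlation between the image and its reflection —
#' an optional pre-registration aid for slices that are not centered.
#' The pipelines assume a centered midline and leave this off by default.
#'
#' @param image numeric matrix.
#' @param max_frac maximum shift as a fraction of the width (default 0.1).
#' @return integer column shift (0 for a centered head).
#' @export
estimate_midline_shift <- function(image, max_frac = 0.1) {
  as_gray_image(image)
  nc <- ncol(image)
  kmax <- max(1L, as.integer(floor(max_frac * nc)))
  best_k <- 0L
  best_score <- -Inf
  for (k in seq(-kmax, kmax)) {
    shifted <- .shift_cols(image, k)
    score <- -sum((shifted - reflect(shifted))^2)
    if (score > best_score) { best_score <- score; best_k <- k }
  }
  best_k
}

.shift_cols <- function(image, k) {
  if (k == 0L) return(image)
  nc <- ncol(image)
  out <- matrix(0, nrow(image), nc)
  if (k > 0L) out[, (k + 1L):nc] <- image[, 1L:(nc - k)]
  else out[, 1L:(nc + k)] <- image[, (1L - k):nc]
  out
}
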