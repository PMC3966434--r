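#' Pipeline configuration
#'
#' Nested list of every tunable the pipelines consume, with the package
#' defaults. Override any subset via `...` (named nested lists are merged
#' recursively), e.g. `seg_config(seed = list(frac = 0.4))`.
#'
#' Groups:
#' * `preprocess`: `enabled` (default TRUE), `radius` (disk radius, 2 px),
#'   `mode` (`"open"`).
#' * `symmetry`: `shift_search` (FALSE; when TRUE, pre-registers a small
#'   lateral midline offset before reflecting).
#' * `seed`: `frac` (0.5; threshold on the rectified difference as a
#'   fraction of its max), `min_area` (10 px; smaller components are
#'   discarded), `noise_floor` (0.05; below this rectified max the slice is
#'   declared symmetric and nothing is seeded).
#' * `ehasa`: `fraction` (0.25 of the maximum original intensity — the
#'   binarization threshold), `use_mean_threshold` (FALSE; when TRUE the
#'   threshold is instead the mean of the rectified difference, a fidelity
#'   switch for the ambiguous description of the binarization step).
#' * `chanvese`: all [chanvese_params()] fields.
#' * `min_region_area`: final-mask components smaller than this (10 px) are
#'   dropped before reporting.
#' * `drop_border_regions`: FALSE; when TRUE, final components touching the
#'   image border are removed.
#'
#' @param ... named overrides.
#' @return nested configuration list of class `seg_config`.
#' @export
seg_config <- function(...) {
  base <- list(
    preprocess = list(enabled = TRUE, radius = 2L, mode = "open"),
    symmetry = list(shift_search = FALSE),
    seed = list(frac = 0.5, min_area = 10L, noise_floor = 0.05),
    ehasa = list(fraction = 0.25, use_mean_threshold = FALSE),
    chanvese = unclass(chanvese_params()),
    min_region_area = 10L,
    drop_border_regions = FALSE
  )
  structure(utils::modifyList(base, list(...)), class = "seg_config")
}

.cv_params <- function(config) do.call(chanvese_params, config$chanvese)

#' Locate aggregated asymmetric hyperintensities
#'
#' Finds where the rectified hemispheric difference concentrates: threshold
#' at `frac * max(rectified)`, label 8-connected components, drop those
#' smaller than `min_area`, and return the survivors sorted by integrated
#' rectified intensity (mass), largest first. When the rectified maximum is
#' below `noise_floor` the slice is treated as symmetric and an empty list
#' (the no-tumor signal) is returned.
#'
#' @param diff a [difference_image()].
#' @param frac threshold fraction in `(0, 1)`.
#' @param min_area minimum component area in pixels.
#' @param noise_floor absolute rectified-intensity floor.
#' @return list of seed regions, each with `centroid` (0-based `c(row, col)`),
#'   `bbox` (`c(r0, c0, r1, c1)`, half-open), `mass`, and `area_px`.
#' @export
localize_high_intensity <- function(diff, frac = 0.5, min_area = 10L,
                                    noise_floor = 0.05) {
  stopifnot(inherits(diff, "difference_image"), frac > 0, frac < 1)
  rect <- diff$rectified
  mx <- max(rect)
  if (mx < noise_floor) return(list())
  lab <- label_components(rect > frac * mx)
  st <- component_stats(lab, weights = rect)
  st <- st[st$area_px >= min_area, , drop = FALSE]
  if (nrow(st) == 0L) return(list())
  st <- st[order(-st$mass), , drop = FALSE]
  lapply(seq_len(nrow(st)), function(i) list(
    centroid = c(st$centroid_r[i], st$centroid_c[i]),
    bbox = c(st$r0[i], st$c0[i], st$r1[i], st$c1[i]),
    mass = st$mass[i],
    area_px = st$area_px[i]
  ))
}

#' Binarization threshold for the enhanced pipeline
#'
#' A quarter (by default) of the maximum intensity of the original slice:
#' `T = fraction * max(image)`. On a normalized slice with max 1 this is
#' exactly 0.25.
#'
#' @param image the original (optionally preprocessed) slice.
#' @param fraction fraction of the maximum, default 0.25.
#' @return scalar threshold.
#' @export
ehasa_threshold <- function(image, fraction = 0.25) {
  as_gray_image(image)
  fraction * max(image)
}

#' Binarize the rectified difference image
#'
#' `mask[r, c] = rectified[r, c] > T`. The rectified (positive-part)
#' difference is used so that each lesion is detected at its own location.
#'
#' @param diff a [difference_image()].
#' @param T non-negative threshold, typically from [ehasa_threshold()].
#' @return logical matrix.
#' @export
ehasa_mask <- function(diff, T) {
  stopifnot(inherits(diff, "difference_image"), T >= 0)
  diff$rectified > T
}

#' Map a binary mask onto an image
#'
#' Elementwise product: pixels outside the mask become exactly 0, pixels
#' inside keep their original intensity.
#'
#' @param mask logical matrix.
#' @param image numeric matrix, same shape.
#' @return numeric matrix.
#' @export
map_mask <- function(mask, image) {
  mask <- as_binary_mask(mask, dim(image))
  image * mask
}

# Shared front half of both pipelines: optional morphology, optional midline
# shift, reflection, difference.
.symmetry_front <- function(image, config) {
  pre <- image
  if (isTRUE(config$preprocess$enabled))
    pre <- morphological_clean(pre, config$preprocess$radius,
                               config$preprocess$mode)
  if (isTRUE(config$symmetry$shift_search)) {
    k <- estimate_midline_shift(pre)
    if (k != 0L) pre <- .shift_cols(pre, k)
  }
  refl <- reflect(pre)
  list(pre = pre, refl = refl, diff = difference_image(pre, refl))
}

# Assemble a segmentation_result from a final level set (or mask).
.finalize_result <- function(mask, image, method, config, intermediates) {
  lab <- label_components(mask)
  st <- component_stats(lab, weights = image)
  keep <- st$area_px >= config$min_region_area
  if (isTRUE(config$drop_border_regions) && nrow(st) > 0L) {
    keep <- keep & !(st$r0 == 0L | st$c0 == 0L |
                       st$r1 == nrow(mask) | st$c1 == ncol(mask))
  }
  drop_ids <- st$id[!keep]
  if (length(drop_ids)) mask[lab %in% drop_ids] <- FALSE
  st <- st[keep, , drop = FALSE]
  if (nrow(st) > 0L) {
    st$mean_intensity <- st$mass / st$area_px
    st <- st[order(-st$area_px), , drop = FALSE]
    rownames(st) <- NULL
  } else {
    st$mean_intensity <- numeric(0)
  }
  structure(list(
    mask = mask,
    regions = st,
    n_regions = nrow(st),
    method = method,
    params_used = config,
    intermediates = intermediates
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<%s segmentation: %d region(s), %d mask px>\n",
              x$method, x$n_regions, sum(x$mask)))
  if (x$n_regions > 0L)
    print(x$regions[, c("area_px", "centroid_r", "centroid_c",
                        "mean_intensity")])
  invisible(x)
}

#' HASA: symmetry-seeded active contour on the difference image
#'
#' Pipeline: optional morphological opening, reflection about the vertical
#' midline, signed difference, rectification, localization of aggregated
#' hyperintense residuals, then a Chan-Vese contour initialized at those
#' seeds and evolved on the rectified difference image itself. An empty seed
#' list (symmetric slice) short-circuits to an empty mask — that is the
#' no-tumor answer, not an error.
#'
#' @param image numeric matrix in `[0, 1]` (see [read_image()]).
#' @param config a [seg_config()].
#' @param verbose when TRUE, every stage output is kept in
#'   `$intermediates` (preprocessed, reflection, signed/rectified
#'   difference, initial phi, final phi).
#' @return a `segmentation_result`: `mask`, per-region table `regions`,
#'   `n_regions`, `method`, `params_used`, `intermediates`.
#' @export
run_hasa <- function(image, config = seg_config(), verbose = FALSE) {
  as_gray_image(image)
  fr <- .symmetry_front(image, config)
  seeds <- localize_high_intensity(fr$diff, config$seed$frac,
                                   config$seed$min_area,
                                   config$seed$noise_floor)
  inter <- if (verbose) list(preprocessed = fr$pre, reflection = fr$refl,
                             signed = fr$diff$signed,
                             rectified = fr$diff$rectified) else NULL
  if (length(seeds) == 0L) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
    return(.finalize_result(mask, fr$diff$rectified, "hasa", config, inter))
  }
  phi0 <- init_level_set(dim(image), seeds)
  phi <- chanvese_evolve(fr$diff$rectified, phi0, .cv_params(config))
  if (verbose) inter <- c(inter, list(phi0 = phi0, phi = phi))
  .finalize_result(phi > 0, fr$diff$rectified, "hasa", config, inter)
}

#' EHASA: threshold, mask-map, then contour the masked original
#'
#' Pipeline: optional morphological opening, reflection, signed difference;
#' threshold the rectified difference at [ehasa_threshold()] (a quarter of
#' the original slice's maximum intensity), map the resulting binary mask
#' back onto the original image, seed from the mask's components, and evolve
#' the Chan-Vese contour on the masked original. Because the final contour
#' sees original intensities, dim asymmetric residuals that survive the
#' threshold are still rejected — the refinement over [run_hasa()].
#'
#' @inheritParams run_hasa
#' @return a `segmentation_result`.
#' @export
run_ehasa <- function(image, config = seg_config(), verbose = FALSE) {
  as_gray_image(image)
  fr <- .symmetry_front(image, config)
  Tval <- if (isTRUE(config$ehasa$use_mean_threshold))
    mean(fr$diff$rectified) else
    ehasa_threshold(fr$pre, config$ehasa$fraction)
  bmask <- ehasa_mask(fr$diff, Tval)
  mapped <- map_mask(bmask, fr$pre)
  lab <- label_components(bmask)
  st <- component_stats(lab, weights = fr$diff$rectified)
  st <- st[st$area_px >= config$seed$min_area, , drop = FALSE]
  inter <- if (verbose) list(preprocessed = fr$pre, reflection = fr$refl,
                             signed = fr$diff$signed,
                             rectified = fr$diff$rectified,
                             binary = bmask, mapped = mapped) else NULL
  if (nrow(st) == 0L) {
    mask <- matrix(FALSE, nrow(image), ncol(image))
    return(.finalize_result(mask, mapped, "ehasa", config, inter))
  }
  st <- st[order(-st$mass), , drop = FALSE]
  seeds <- lapply(seq_len(nrow(st)), function(i) list(
    centroid = c(st$centroid_r[i], st$centroid_c[i]),
    area_px = st$area_px[i]
  ))
  phi0 <- init_level_set(dim(image), seeds)
  phi <- chanvese_evolve(mapped, phi0, .cv_params(config))
  if (verbose) inter <- c(inter, list(phi0 = phi0, phi = phi))
  .finalize_result(phi > 0, mapped, "ehasa", config, inter)
}

#' Plain Chan-Vese baseline on the raw slice
#'
#' The unaided comparison arm: a checkerboard-initialized two-phase
#' Chan-Vese contour on the original image, with no symmetry information.
#' On a head slice it segments every bright structure — scalp, brain
#' parenchyma, lesion alike — so its region count exceeds the symmetry
#' pipelines', which is exactly the behavior the hybrid methods remove.
#'
#' @inheritParams run_hasa
#' @return a `segmentation_result`.
#' @export
run_chanvese_baseline <- function(image, config = seg_config(),
                                  verbose = FALSE) {
  as_gray_image(image)
  if (diff(range(image)) <= .Machine$double.eps) {
    # zero-range slice: no structure, degenerate by convention
    mask <- matrix(FALSE, nrow(image), ncol(image))
    return(.finalize_result(mask, image, "chanvese-baseline", config, NULL))
  }
  phi0 <- init_level_set(dim(image), NULL)
  phi <- chanvese_evolve(image, phi0, .cv_params(config))
  # the two phases are label-symmetric under checkerboard init; report the
  # brighter phase as the segmentation (bright-on-dark convention)
  cs <- region_means(image, phi, config$chanvese$eps)
  mask <- if (cs[["c1"]] >= cs[["c2"]]) phi > 0 else phi <= 0
  inter <- if (verbose) list(phi0 = phi0, phi = phi) else NULL
  .finalize_result(mask, image, "chanvese-baseline", config, inter)
}
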