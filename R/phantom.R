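#' Declarative synthetic head-slice specification
#'
#' Describes everything [make_phantom()] renders: a bright elliptical brain
#' on a dark background, an optional bright scalp/skull annulus separated
#' from the brain by a dark CSF gap, optional mirrored dark ventricles, any
#' number of hyperintense lesions (the ground truth), optional bright
#' non-tumor artifacts (excluded from ground truth), mild hemispheric
#' asymmetry, and additive Gaussian noise. All coordinates are 0-based
#' `(row, col)`; ellipse centers may be fractional — centering a lesion at
#' column `(cols - 1) / 2` puts it exactly on the symmetry axis.
#'
#' @param shape `c(rows, cols)`, default `c(128, 128)`.
#' @param head list with `center` (`c(row, col)`), `semi_axes`
#'   (`c(row_semiaxis, col_semiaxis)`), `intensity` in `(0, 1)`.
#' @param skull `NULL`, or list with `gap` and `thickness` (fractions of the
#'   head semi-axes forming the annulus) and `intensity`.
#' @param ventricles `NULL`, or list with `center` (`c(row, col_offset)`:
#'   the pair is mirrored at `+/- col_offset` from the head center column),
#'   `semi_axes`, `intensity`.
#' @param lesions list of lesions, each a list with `center`, `semi_axes`,
#'   `angle` (radians, default 0), `delta` (intensity added over local
#'   tissue, `> 0`). Lesion ellipses must lie inside the head ellipse and
#'   `head$intensity + delta` must stay `<= 1`.
#' @param artifacts like `lesions` but unconstrained in position and not part
#'   of the ground truth (models non-tumor asymmetric hyperintensities).
#' @param asymmetry_jitter max fractional per-pixel multiplicative
#'   perturbation applied to the right hemisphere (`>= 0`).
#' @param noise_sigma additive Gaussian noise SD, `0 <= noise_sigma < 0.2`.
#' @param rng_seed integer; the render is a pure function of the spec.
#' @param mirror when TRUE the fully rendered image and truth are flipped
#'   left-right, giving the exact pixel mirror of the unflipped spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         head = list(center = NULL, semi_axes = NULL,
                                     intensity = 0.55),
                         skull = list(gap = 0.10, thickness = 0.10,
                                      intensity = 0.8),
                         ventricles = list(center = c(-8, 10),
                                           semi_axes = c(9, 4),
                                           intensity = 0.25),
                         lesions = list(),
                         artifacts = list(),
                         asymmetry_jitter = 0,
                         noise_sigma = 0.02,
                         rng_seed = 1L,
                         mirror = FALSE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 16L))
  ctr <- c((shape[1] - 1) / 2, (shape[2] - 1) / 2)
  if (is.null(head$center)) head$center <- ctr
  if (is.null(head$semi_axes))
    head$semi_axes <- c(0.40 * shape[1], 0.33 * shape[2])
  stopifnot(head$intensity > 0, head$intensity < 1)
  if (asymmetry_jitter < 0) stop("asymmetry_jitter must be >= 0", call. = FALSE)
  if (noise_sigma < 0 || noise_sigma >= 0.2)
    stop("noise_sigma must be in [0, 0.2)", call. = FALSE)
  for (L in lesions) {
    if (is.null(L$delta) || L$delta <= 0)
      stop("lesion delta must be > 0", call. = FALSE)
    if (head$intensity + L$delta > 1 + 1e-12)
      stop("lesion delta pushes intensity above 1", call. = FALSE)
    rel <- (L$center - head$center) / head$semi_axes
    ext <- max(L$semi_axes) / min(head$semi_axes)
    if (sqrt(sum(rel^2)) + ext > 1)
      stop("lesion does not lie inside the head ellipse", call. = FALSE)
  }
  structure(list(shape = shape, head = head, skull = skull,
                 ventricles = ventricles, lesions = lesions,
                 artifacts = artifacts,
                 asymmetry_jitter = asymmetry_jitter,
                 noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed),
                 mirror = isTRUE(mirror)),
            class = "phantom_spec")
}

# Anti-aliased coverage of a rotated ellipse: ~1 px linear edge ramp on the
# normalized radial coordinate.
.ellipse_alpha <- function(shape, center, semi_axes, angle = 0) {
  nr <- shape[1]; nc <- shape[2]
  r <- matrix(seq_len(nr) - 1, nr, nc) - center[1]
  c_ <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) - center[2]
  if (angle != 0) {
    u <- cos(angle) * r + sin(angle) * c_
    v <- -sin(angle) * r + cos(angle) * c_
  } else { u <- r; v <- c_ }
  q <- sqrt((u / semi_axes[1])^2 + (v / semi_axes[2])^2)
  pmin(pmax(0.5 + (1 - q) * min(semi_axes), 0), 1)
}

.blend <- function(img, alpha, intensity) img * (1 - alpha) + alpha * intensity

#' Render a synthetic head slice with ground truth
#'
#' Deterministic render of a [phantom_spec()]: background 0.05, head
#' ellipse, skull annulus, mirrored ventricles, anti-aliased lesions at
#' local tissue intensity plus `delta`, artifacts likewise; then the
#' right-hemisphere multiplicative jitter, then additive Gaussian noise
#' clipped to `[0, 1]`. The ground-truth mask is the union of the lesion
#' ellipses (coverage >= 0.5), rendered before jitter and noise so it never
#' depends on the noise realization. The caller's RNG state is preserved.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (numeric matrix in `[0, 1]`) and `truth`
#'   (logical lesion mask).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$rng_seed)

  sh <- spec$shape
  img <- matrix(0.05, sh[1], sh[2])
  head_a <- .ellipse_alpha(sh, spec$head$center, spec$head$semi_axes)
  if (!is.null(spec$skull)) {
    outer_ax <- spec$head$semi_axes * (1 + spec$skull$gap + spec$skull$thickness)
    inner_ax <- spec$head$semi_axes * (1 + spec$skull$gap)
    ring <- pmax(.ellipse_alpha(sh, spec$head$center, outer_ax) -
                   .ellipse_alpha(sh, spec$head$center, inner_ax), 0)
    img <- .blend(img, ring, spec$skull$intensity)
  }
  img <- .blend(img, head_a, spec$head$intensity)
  if (!is.null(spec$ventricles)) {
    v <- spec$ventricles
    for (s in c(-1, 1)) {
      ctr <- c(spec$head$center[1] + v$center[1],
               spec$head$center[2] + s * v$center[2])
      img <- .blend(img, .ellipse_alpha(sh, ctr, v$semi_axes), v$intensity)
    }
  }
  truth <- matrix(FALSE, sh[1], sh[2])
  for (L in spec$lesions) {
    ang <- if (is.null(L$angle)) 0 else L$angle
    a <- .ellipse_alpha(sh, L$center, L$semi_axes, ang)
    img <- img + a * L$delta
    truth <- truth | (a >= 0.5)
  }
  for (A in spec$artifacts) {
    ang <- if (is.null(A$angle)) 0 else A$angle
    a <- .ellipse_alpha(sh, A$center, A$semi_axes, ang)
    img <- img + a * A$delta
  }
  if (spec$asymmetry_jitter > 0) {
    right <- seq.int(floor(sh[2] / 2) + 1L, sh[2])
    jit <- matrix(stats::runif(sh[1] * length(right),
                               1 - spec$asymmetry_jitter,
                               1 + spec$asymmetry_jitter),
                  sh[1], length(right))
    img[, right] <- img[, right] * jit
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                        sh[1], sh[2])
  img <- pmin(pmax(img, 0), 1)
  if (spec$mirror) {
    img <- reflect(img)
    truth <- reflect(truth)
  }
  list(image = img, truth = truth)
}

#' Named fixture suite covering the pipelines' claims
#'
#' Six 128x128 phantoms with fixed seeds:
#' \describe{
#'   \item{symmetric}{no lesion, no jitter — the null case.}
#'   \item{left-lesion}{one 9x7 px-semi-axis lesion (+0.4 contrast) in the
#'     left hemisphere, mild jitter.}
#'   \item{right-lesion}{the exact pixel mirror of `left-lesion` (same spec,
#'     `mirror = TRUE`) — the laterality-equivariance fixture.}
#'   \item{bilateral-two-lesions}{one lesion per hemisphere at
#'     non-mirroring positions.}
#'   \item{midline-lesion}{a lesion centered exactly on the symmetry axis —
#'     the documented failure mode.}
#'   \item{lesion-plus-artifact}{`left-lesion` plus a dim bright streak
#'     outside the head on the right: asymmetric (so it survives the
#'     difference image) but faint in the original (so the enhanced
#'     pipeline's final contour rejects it).}
#' }
#'
#' @return named list of [phantom_spec()] objects.
#' @export
standard_suite <- function() {
  lesion_left <- list(center = c(56, 38), semi_axes = c(9, 7),
                      angle = 0, delta = 0.4)
  streak <- list(center = c(12, 104), semi_axes = c(5, 9),
                 angle = 0.2, delta = 0.22)
  list(
    "symmetric" = phantom_spec(asymmetry_jitter = 0, rng_seed = 101L),
    "left-lesion" = phantom_spec(lesions = list(lesion_left),
                                 asymmetry_jitter = 0.02, rng_seed = 102L),
    "right-lesion" = phantom_spec(lesions = list(lesion_left),
                                  asymmetry_jitter = 0.02, rng_seed = 102L,
                                  mirror = TRUE),
    "bilateral-two-lesions" = phantom_spec(
      lesions = list(
        list(center = c(52, 36), semi_axes = c(8, 6), angle = 0, delta = 0.4),
        list(center = c(78, 88), semi_axes = c(7, 6), angle = 0.3, delta = 0.4)
      ),
      asymmetry_jitter = 0.02, rng_seed = 104L),
    "midline-lesion" = phantom_spec(
      lesions = list(list(center = c(58, 63.5), semi_axes = c(8, 6),
                          angle = 0, delta = 0.4)),
      asymmetry_jitter = 0.02, rng_seed = 105L),
    "lesion-plus-artifact" = phantom_spec(
      lesions = list(lesion_left), artifacts = list(streak),
      asymmetry_jitter = 0.02, rng_seed = 106L)
  )
}

#' Export a phantom to disk
#'
#' Writes the rendered slice as PNG or minimal synthetic DICOM (8-bit
#' MONOCHROME2) plus the ground-truth mask as PNG, exercising the full read
#' path end-to-end.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"dicom"`.
#' @param name base filename, default `"phantom"`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_phantom <- function(spec, dir, format = c("png", "dicom"),
                          name = "phantom") {
  format <- match.arg(format)
  ph <- make_phantom(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, if (format == "png") ".png"
                                    else ".dcm"))
  if (format == "png") write_image(ph$image, img_path)
  else write_dicom(ph$image, img_path, bits_stored = 8L,
                   window_center = 127.5, window_width = 255)
  truth_path <- file.path(dir, paste0(name, "_truth.png"))
  write_mask(ph$truth, truth_path)
  invisible(c(image = img_path, truth = truth_path))
}
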