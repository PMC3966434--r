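#' Chan-Vese parameter set
#'
#' All tunables of the two-phase piecewise-constant active contour in one
#' record. The energy minimized is
#' \deqn{E(\phi) = \mu\,\mathrm{length}(\{\phi = 0\})
#'   + \lambda_1 \int_{\phi>0} (I - c_1)^2
#'   + \lambda_2 \int_{\phi<0} (I - c_2)^2,}
#' with `c1`/`c2` the inside/outside region means, evolved by gradient
#' descent on a level set `phi` whose positive region is the segmentation.
#'
#' Defaults are the standard published values of the model for unit-interval
#' intensities: `mu = 0.2` (contour-length weight; larger smooths more and
#' suppresses small regions), `lambda1 = lambda2 = 1` (inside/outside
#' fidelity), `dt = 0.5` (descent time step), `eps = 1` (width in pixels of
#' the smoothed Heaviside/Dirac; the arctan form has nonzero support
#' everywhere, so far-away contours still feel the data term), `tol = 1e-3`
#' (stop when the mean absolute level-set update falls below this),
#' `max_iter = 500`. `reinit_every = 0` disables signed-distance
#' reinitialization; a positive value rebuilds `phi` as an SDF every that
#' many iterations.
#'
#' @param mu contour length weight, `>= 0`.
#' @param lambda1,lambda2 fidelity weights, `> 0`.
#' @param dt time step, `> 0`.
#' @param eps Heaviside smoothing width, `> 0`.
#' @param max_iter positive integer iteration cap.
#' @param tol convergence threshold on mean `|delta phi|`, `> 0`.
#' @param reinit_every non-negative integer.
#' @return object of class `chanvese_params`.
#' @export
chanvese_params <- function(mu = 0.2, lambda1 = 1, lambda2 = 1, dt = 0.5,
                            eps = 1, max_iter = 500L, tol = 1e-3,
                            reinit_every = 0L) {
  stopifnot(mu >= 0, lambda1 > 0, lambda2 > 0, dt > 0, eps > 0,
            max_iter >= 1, tol > 0, reinit_every >= 0)
  structure(list(mu = mu, lambda1 = lambda1, lambda2 = lambda2, dt = dt,
                 eps = eps, max_iter = as.integer(max_iter), tol = tol,
                 reinit_every = as.integer(reinit_every)),
            class = "chanvese_params")
}

# Smoothed Heaviside and Dirac (arctan regularization).
heaviside_eps <- function(phi, eps) 0.5 * (1 + (2 / pi) * atan(phi / eps))
dirac_eps <- function(phi, eps) (eps / pi) / (eps^2 + phi^2)

#' Inside/outside region means of the Chan-Vese model
#'
#' Weighted means of the image under the smoothed Heaviside
#' `H(phi) = (1/2)(1 + (2/pi) atan(phi/eps))`:
#' `c1 = sum(H * I) / sum(H)` and `c2 = sum((1-H) * I) / sum(1-H)`.
#' If a region carries (numerically) zero weight its mean falls back to the
#' global image mean, so an emptied phase never produces NaN.
#'
#' @param image numeric matrix.
#' @param phi level set, same shape; inside is `phi > 0`.
#' @param eps Heaviside smoothing width.
#' @return named numeric vector `c(c1 = ..., c2 = ...)`.
#' @export
region_means <- function(image, phi, eps = 1) {
  if (!identical(dim(image), dim(phi)))
    stop("`image` and `phi` shapes differ", call. = FALSE)
  h <- heaviside_eps(phi, eps)
  w1 <- sum_sym(h)
  w2 <- sum_sym(1 - h)
  gmean <- sum_sym(image) / length(image)
  c1 <- if (w1 > 1e-12) sum_sym(h * image) / w1 else gmean
  c2 <- if (w2 > 1e-12) sum_sym((1 - h) * image) / w2 else gmean
  c(c1 = c1, c2 = c2)
}

# Replicate-padded neighbor shifts (Neumann boundary).
.shift_up    <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
.shift_down  <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
.shift_left  <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
.shift_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

# Curvature div(grad phi / |grad phi|) by central differences with a 1e-8
# regularizer in the gradient-norm denominator.
.curvature <- function(phi) {
  px <- (.shift_right(phi) - .shift_left(phi)) / 2
  py <- (.shift_down(phi) - .shift_up(phi)) / 2
  nrm <- sqrt(px^2 + py^2 + 1e-8)
  nx <- px / nrm
  ny <- py / nrm
  (.shift_right(nx) - .shift_left(nx)) / 2 +
    (.shift_down(ny) - .shift_up(ny)) / 2
}

#' Total Chan-Vese energy
#'
#' Diagnostic evaluation of the functional minimized by [chanvese_evolve()]:
#' length term approximated as `sum(dirac_eps(phi) * |grad phi|)` (central
#' differences), data terms as Heaviside-weighted sums of squared deviations
#' from the current region means.
#'
#' @param image numeric matrix.
#' @param phi level set, same shape.
#' @param params [chanvese_params()].
#' @return scalar energy.
#' @export
chanvese_energy <- function(image, phi, params = chanvese_params()) {
  if (!identical(dim(image), dim(phi)))
    stop("`image` and `phi` shapes differ", call. = FALSE)
  cs <- region_means(image, phi, params$eps)
  h <- heaviside_eps(phi, params$eps)
  px <- (.shift_right(phi) - .shift_left(phi)) / 2
  py <- (.shift_down(phi) - .shift_up(phi)) / 2
  len <- sum_sym(dirac_eps(phi, params$eps) * sqrt(px^2 + py^2))
  params$mu * len +
    params$lambda1 * sum_sym(h * (image - cs["c1"])^2) +
    params$lambda2 * sum_sym((1 - h) * (image - cs["c2"])^2)
}

#' Evolve a Chan-Vese level set
#'
#' Gradient descent on the two-phase piecewise-constant energy:
#' `phi <- phi + dt * dirac_eps(phi) * (mu * curvature - lambda1 * (I - c1)^2
#' + lambda2 * (I - c2)^2)`, with `c1`, `c2` refreshed each iteration as the
#' plain means of the image over `phi > 0` and `phi <= 0` (the sharp limit
#' of [region_means()], which is what reference implementations of the
#' model iterate; an emptied phase falls back to the global mean).
#' Stops when the mean absolute update over the contour's active band
#' (pixels with `|phi| < 2 * eps`, where the smoothed Dirac is
#' non-negligible and the contour actually moves) drops below `tol`, or
#' after `max_iter` iterations; an empty active band means the contour has
#' vanished and also stops the evolution. Averaging over the band rather
#' than the full frame keeps the stopping rule independent of how much
#' inert far-field the image carries. Fully deterministic.
#'
#' @param image numeric matrix with intensities in `[0, 1]`.
#' @param phi0 initial level set from [init_level_set()].
#' @param params [chanvese_params()].
#' @return final level set matrix; segmentation is `phi > 0`.
#' @export
chanvese_evolve <- function(image, phi0, params = chanvese_params()) {
  as_gray_image(image)
  if (!identical(dim(image), dim(phi0)))
    stop("`image` and `phi0` shapes differ", call. = FALSE)
  phi <- phi0
  gmean <- sum_sym(image) / length(image)
  for (it in seq_len(params$max_iter)) {
    # region averages over the sign of phi (the eps -> 0 limit form used by
    # reference implementations): keeps the averages crisp when phi has
    # large amplitude and lets a checkerboard init break symmetry at once
    ins <- phi > 0
    w1 <- sum(ins)
    c1 <- if (w1 > 0L) sum_sym(image * ins) / w1 else gmean
    c2 <- if (w1 < length(ins)) sum_sym(image * !ins) / (length(ins) - w1)
          else gmean
    force <- params$mu * .curvature(phi) -
      params$lambda1 * (image - c1)^2 +
      params$lambda2 * (image - c2)^2
    dphi <- params$dt * dirac_eps(phi, params$eps) * force
    phi <- phi + dphi
    if (!all(is.finite(phi)))
      stop("Chan-Vese evolution produced non-finite values at iteration ",
           it, call. = FALSE)
    if (params$reinit_every > 0L && it %% params$reinit_every == 0L)
      phi <- .reinit_sdf(phi)
    band <- abs(phi) < 2 * params$eps
    nb <- sum(band)  # exact integer count: mirror-invariant
    if (nb == 0 || sum_sym(abs(dphi) * band) / nb < params$tol) break
  }
  phi
}

# Rebuild phi as a signed Euclidean distance to the current zero level.
.reinit_sdf <- function(phi) {
  mask <- phi > 0
  if (all(mask) || !any(mask)) return(phi)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  dpos <- as.matrix(EBImage::distmap(m))
  dneg <- as.matrix(EBImage::distmap(1 - m))
  out <- dpos - dneg
  dimnames(out) <- NULL
  out
}

#' Initialize a level set
#'
#' With seeds: `phi` is the signed distance to the union of seed disks
#' (positive inside), computed as the pointwise maximum of the per-disk
#' signed distances `r_i - ||x - x_i||` — exact for disjoint disks. Without
#' seeds (the baseline's unattended mode): a checkerboard
#' `sin(pi r / 10) * sin(pi c / 10)`, which puts both phases everywhere so
#' the contour can lock onto structure anywhere in the slice.
#'
#' @param shape `c(rows, cols)`.
#' @param seeds `NULL`, or a list of seeds, each a list with `centroid`
#'   (`c(row, col)`, 0-based) and either `radius` or `area_px` (radius then
#'   `sqrt(area/pi)`, floored at 2 px). [localize_high_intensity()] output
#'   is accepted directly.
#' @return level-set matrix of the given shape.
#' @export
init_level_set <- function(shape, seeds = NULL) {
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (is.null(seeds) || length(seeds) == 0L) {
    r <- matrix(seq_len(nr) - 1L, nr, nc)
    c_ <- matrix(rep(seq_len(nc) - 1L, each = nr), nr, nc)
    return(sin(pi * r / 10) * sin(pi * c_ / 10))
  }
  rgrid <- matrix(seq_len(nr) - 1, nr, nc)
  cgrid <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  phi <- matrix(-Inf, nr, nc)
  for (s in seeds) {
    ctr <- s$centroid
    if (ctr[1] < 0 || ctr[1] > nr - 1 || ctr[2] < 0 || ctr[2] > nc - 1)
      stop("seed centroid outside image bounds", call. = FALSE)
    rad <- if (!is.null(s$radius)) s$radius else max(2, sqrt(s$area_px / pi))
    d <- sqrt((rgrid - ctr[1])^2 + (cgrid - ctr[2])^2)
    phi <- pmax(phi, rad - d)
  }
  phi
}
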