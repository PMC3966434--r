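test_that("region means match a direct weighted-mean oracle", {
  withr::local_seed(51)
  for (k in 1:5) {
    img <- matrix(runif(64), 8, 8)
    phi <- matrix(rnorm(64), 8, 8)
    cs <- region_means(img, phi, eps = 1)
    h <- 0.5 * (1 + (2 / pi) * atan(phi / 1))
    expect_lt(abs(cs[["c1"]] - sum(h * img) / sum(h)), 1e-10)
    expect_lt(abs(cs[["c2"]] - sum((1 - h) * img) / sum(1 - h)), 1e-10)
  }

  # sharp separation in the eps -> 0 limit
  img <- matrix(0.2, 8, 8); img[, 1:4] <- 0.8
  phi <- matrix(-1, 8, 8); phi[, 1:4] <- 1
  cs <- region_means(img, phi, eps = 1e-8)
  expect_equal(unname(cs), c(0.8, 0.2), tolerance = 1e-6)

  # constant image: both means equal the constant
  cs <- region_means(matrix(0.3, 8, 8), phi, eps = 1)
  expect_equal(unname(cs), c(0.3, 0.3))

  # one-sided phi: emptied phase falls back to the global mean
  cs <- region_means(img, matrix(1e9, 8, 8), eps = 1e-3)
  expect_equal(cs[["c2"]], mean(img))
})

test_that("energy matches direct summation and is linear in the data weights", {
  withr::local_seed(52)
  img <- matrix(runif(64), 8, 8)
  phi <- matrix(rnorm(64), 8, 8)
  p <- chanvese_params()
  # independent elementwise oracle
  h <- 0.5 * (1 + (2 / pi) * atan(phi / p$eps))
  dlt <- (p$eps / pi) / (p$eps^2 + phi^2)
  pad <- function(m, dr, dc) {
    r <- pmin(pmax(row(m) + dr, 1), nrow(m))
    c <- pmin(pmax(col(m) + dc, 1), ncol(m))
    matrix(m[cbind(as.vector(r), as.vector(c))], nrow(m))
  }
  gx <- (pad(phi, 0, 1) - pad(phi, 0, -1)) / 2
  gy <- (pad(phi, 1, 0) - pad(phi, -1, 0)) / 2
  c1 <- sum(h * img) / sum(h); c2 <- sum((1 - h) * img) / sum(1 - h)
  Eref <- p$mu * sum(dlt * sqrt(gx^2 + gy^2)) +
    p$lambda1 * sum(h * (img - c1)^2) + p$lambda2 * sum((1 - h) * (img - c2)^2)
  expect_lt(abs(chanvese_energy(img, phi, p) - Eref), 1e-10)

  # doubling both fidelity weights doubles the data part of the energy
  p2 <- chanvese_params(lambda1 = 2, lambda2 = 2)
  len_only <- chanvese_params(lambda1 = 1e-12, lambda2 = 1e-12)
  Elen <- chanvese_energy(img, phi, len_only)
  E1 <- chanvese_energy(img, phi, p)
  E2 <- chanvese_energy(img, phi, p2)
  expect_equal(E2 - Elen, 2 * (E1 - Elen), tolerance = 1e-8)

  # far-from-zero flat phi on a constant image carries ~no energy
  expect_lt(chanvese_energy(matrix(0.5, 8, 8), matrix(50, 8, 8), p), 1e-3)
})

test_that("level-set initialization gives signed distances and checkerboards", {
  phi <- init_level_set(c(32, 32), list(list(centroid = c(16, 16), radius = 5)))
  expect_equal(phi[17, 17], 5)        # value at the center is the radius
  expect_equal(phi[17, 22], 0)        # zero on the circle
  expect_equal(phi[17, 27], -5)       # SDF outside

  phi2 <- init_level_set(c(32, 32),
                         list(list(centroid = c(8, 8), radius = 4),
                              list(centroid = c(24, 24), radius = 4)))
  lab <- symseg:::label_components(phi2 > 0)
  expect_equal(max(lab), 2L)

  cb <- init_level_set(c(16, 16), NULL)
  expect_true(any(cb > 0) && any(cb < 0))

  expect_error(init_level_set(c(16, 16),
                              list(list(centroid = c(40, 8), radius = 2))),
               "bounds")
})

test_that("the contour locks onto a two-phase disk", {
  fx <- make_disk_image()
  phi0 <- init_level_set(dim(fx$image),
                         list(list(centroid = fx$center, radius = 8)))
  phi <- chanvese_evolve(fx$image, phi0)
  expect_gte(dice(phi > 0, fx$disk), 0.98)
  # boundary within one pixel of the analytic circle
  rr <- matrix(seq_len(64) - 1, 64, 64); cc <- t(rr)
  rad_err <- abs(sqrt((rr - fx$center[1])^2 + (cc - fx$center[2])^2) -
                   fx$radius)
  expect_true(all(rad_err[xor(phi > 0, fx$disk)] <= 1.5))
})

test_that("evolution is deterministic and affine-covariant", {
  fx <- make_disk_image(48, 9)
  phi0 <- init_level_set(dim(fx$image),
                         list(list(centroid = fx$center, radius = 6)))
  m1 <- chanvese_evolve(fx$image, phi0) > 0
  m2 <- chanvese_evolve(fx$image, phi0) > 0
  expect_identical(m1, m2)
  # affine rescale of the image with compensating fidelity weights
  a <- 0.6
  m3 <- chanvese_evolve(a * fx$image + 0.2, phi0,
                        chanvese_params(lambda1 = 1 / a^2,
                                        lambda2 = 1 / a^2)) > 0
  expect_identical(m1, m3)
})

test_that("invalid parameters are rejected", {
  expect_error(chanvese_params(mu = -1))
  expect_error(chanvese_params(dt = 0))
  expect_error(chanvese_params(lambda1 = 0))
})
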