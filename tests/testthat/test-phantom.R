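test_that("a clean symmetric spec renders an exactly mirror-symmetric head", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, asymmetry_jitter = 0,
                                  rng_seed = 71L))
  expect_identical(ph$image, reflect(ph$image))
  d <- difference_image(ph$image)
  expect_true(all(d$signed == 0))
  expect_false(any(ph$truth))
})

test_that("lesion ground-truth area matches the ellipse area", {
  sp <- phantom_spec(lesions = list(list(center = c(56, 40),
                                         semi_axes = c(8, 6),
                                         angle = 0, delta = 0.4)),
                     noise_sigma = 0, asymmetry_jitter = 0, rng_seed = 72L)
  ph <- make_phantom(sp)
  expect_lt(abs(sum(ph$truth) - pi * 8 * 6) / (pi * 8 * 6), 0.05)
})

test_that("rendering is deterministic and truth is noise-independent", {
  sp <- standard_suite()[["left-lesion"]]
  p1 <- make_phantom(sp)
  p2 <- make_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$truth, p2$truth)

  sp_noisier <- sp
  sp_noisier$noise_sigma <- 0.1
  expect_identical(make_phantom(sp_noisier)$truth, p1$truth)

  # the generator must not disturb the caller's RNG stream
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(make_phantom(sp)); b <- runif(3)
  expect_identical(a, b)
})

test_that("the standard suite covers the documented six scenarios", {
  suite <- standard_suite()
  expect_length(suite, 6)
  expect_setequal(names(suite),
                  c("symmetric", "left-lesion", "right-lesion",
                    "bilateral-two-lesions", "midline-lesion",
                    "lesion-plus-artifact"))
  left <- make_phantom(suite[["left-lesion"]])
  right <- make_phantom(suite[["right-lesion"]])
  expect_identical(right$image, reflect(left$image))
  expect_identical(right$truth, reflect(left$truth))

  mid <- make_phantom(suite[["midline-lesion"]])
  st <- symseg:::component_stats(symseg:::label_components(mid$truth))
  expect_lt(abs(st$centroid_c - ncol(mid$image) / 2), 1)
})

test_that("the symmetric residual stays within the quantified noise band", {
  # max |O - R| for iid Gaussian noise: difference sd is sigma*sqrt(2) and
  # the max over ~16k pixels sits near 4.3 of those sd's; 5.5 gives margin
  for (seed in c(73L, 74L)) {
    sp <- phantom_spec(asymmetry_jitter = 0.02, rng_seed = seed)
    d <- difference_image(make_phantom(sp)$image)
    bound <- 5.5 * sqrt(2) * sp$noise_sigma + 2 * sp$asymmetry_jitter
    expect_lt(max(abs(d$signed)), bound)
  }
})

test_that("invalid specifications are rejected", {
  expect_error(phantom_spec(lesions = list(list(center = c(64, 5),
                                                semi_axes = c(8, 6),
                                                delta = 0.4))),
               "inside the head")
  expect_error(phantom_spec(lesions = list(list(center = c(60, 60),
                                                semi_axes = c(5, 5),
                                                delta = 0.8))),
               "above 1")
  expect_error(phantom_spec(noise_sigma = 0.3), "noise_sigma")
})

test_that("phantoms round-trip through PNG and synthetic DICOM export", {
  d <- withr::local_tempdir()
  sp <- standard_suite()[["left-lesion"]]
  paths <- write_phantom(sp, d, format = "png", name = "t")
  img <- read_image(paths[["image"]])
  truth <- read_mask(paths[["truth"]])
  expect_identical(dim(img), dim(truth))
  res <- run_ehasa(img)
  expect_gte(region_report(res, truth)$dice, 0.85)

  paths2 <- write_phantom(sp, d, format = "dicom", name = "t2")
  img2 <- read_image(paths2[["image"]])
  ph <- make_phantom(sp)
  expect_lt(max(abs(img2 - ph$image)), 1 / 255 + 1e-9)
})
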