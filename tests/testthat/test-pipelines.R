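zero_img <- function(n = 32) matrix(0, n, n)

test_that("seed localization finds aggregated residuals and filters noise", {
  # no asymmetry at all -> empty
  d0 <- difference_image(zero_img(), zero_img())
  expect_length(localize_high_intensity(d0), 0)

  # two blobs of equal intensity, areas ~50 and ~20: both found, big first
  o <- zero_img()
  o[5:9, 5:14] <- 0.6        # 50 px
  o[20:23, 20:24] <- 0.6     # 20 px
  d <- difference_image(o, zero_img())
  seeds <- localize_high_intensity(d, frac = 0.5, min_area = 10)
  expect_length(seeds, 2)
  expect_gt(seeds[[1]]$mass, seeds[[2]]$mass)
  expect_equal(seeds[[1]]$area_px, 50L)
  expect_equal(seeds[[2]]$area_px, 20L)
  # oracle agreement on the component partition
  want <- partition_signature(oracle_label(o > 0.3))
  got <- partition_signature(symseg:::label_components(d$rectified > 0.3))
  expect_identical(got, want)

  # a 3-px blob dies under min_area = 10
  o2 <- zero_img(); o2[4, 4:6] <- 0.9
  d2 <- difference_image(o2, zero_img())
  expect_length(localize_high_intensity(d2, min_area = 10), 0)

  # sub-noise-floor fields are declared symmetric
  o3 <- zero_img(); o3[10:15, 10:15] <- 0.04
  d3 <- difference_image(o3, zero_img())
  expect_length(localize_high_intensity(d3, noise_floor = 0.05), 0)
})

test_that("the binarization threshold is a quarter of the max intensity", {
  img <- matrix(runif(256), 16, 16)
  img <- img / max(img)               # max exactly 1
  expect_identical(ehasa_threshold(img), 0.25)
  expect_identical(ehasa_threshold(zero_img(16)), 0)
  img2 <- matrix(0.1, 16, 16); img2[3, 3] <- 0.8
  expect_equal(ehasa_threshold(img2, 0.25), 0.2)
})

test_that("the difference mask matches a brute-force count and is monotone", {
  withr::local_seed(61)
  for (k in 1:5) {
    o <- matrix(runif(256), 16, 16)
    d <- difference_image(o)
    Tv <- runif(1, 0, 0.5)
    m <- ehasa_mask(d, Tv)
    expect_equal(sum(m), sum(d$rectified > Tv))   # direct count oracle
    # raising the threshold never adds pixels
    m_hi <- ehasa_mask(d, Tv + 0.1)
    expect_true(all(m | !m_hi))
    expect_true(all(m_hi[m == FALSE] == FALSE))
  }
  d <- difference_image(matrix(0.5, 8, 8), matrix(0.2, 8, 8))
  expect_true(all(ehasa_mask(d, 0)))   # T = 0 on strictly positive field
  expect_false(any(ehasa_mask(difference_image(zero_img(8), zero_img(8)),
                              0.1)))
})

test_that("mask mapping is the elementwise product", {
  withr::local_seed(62)
  img <- matrix(runif(64), 8, 8)
  m <- random_mask(8, 8)
  expect_identical(map_mask(matrix(TRUE, 8, 8), img), img)
  expect_true(all(map_mask(matrix(FALSE, 8, 8), img) == 0))
  expect_equal(map_mask(m, img), img * ifelse(m, 1, 0))
  expect_error(map_mask(matrix(TRUE, 8, 4), img), "shape")
})

test_that("zero-asymmetry inputs give empty segmentations in both pipelines", {
  sym <- make_phantom(phantom_spec(noise_sigma = 0, asymmetry_jitter = 0,
                                   rng_seed = 63L))$image
  for (run in list(run_hasa, run_ehasa)) {
    res <- run(sym)
    expect_equal(res$n_regions, 0L)
    expect_false(any(res$mask))
  }
})

test_that("pipelines are pure functions: identical reruns, mirror equivariance", {
  ph <- make_phantom(standard_suite()[["left-lesion"]])
  r1 <- run_hasa(ph$image)
  r2 <- run_hasa(ph$image)
  expect_identical(r1$mask, r2$mask)
  # the method cannot prefer a hemisphere
  rm <- run_hasa(reflect(ph$image))
  expect_identical(rm$mask, reflect(r1$mask))
  em <- run_ehasa(reflect(ph$image))
  expect_identical(em$mask, reflect(run_ehasa(ph$image)$mask))
})

test_that("segmentation results carry consistent region metadata", {
  ph <- make_phantom(standard_suite()[["bilateral-two-lesions"]])
  res <- run_ehasa(ph$image)
  expect_s3_class(res, "segmentation_result")
  expect_equal(res$n_regions,
               max(symseg:::label_components(res$mask)))
  expect_equal(nrow(res$regions), res$n_regions)
  if (res$n_regions > 1)
    expect_true(all(diff(res$regions$area_px) <= 0))  # sorted descending
  expect_equal(res$method, "ehasa")
})

test_that("verbose mode retains the full intermediate panel sequence", {
  ph <- make_phantom(standard_suite()[["left-lesion"]])
  rh <- run_hasa(ph$image, verbose = TRUE)
  expect_named(rh$intermediates,
               c("preprocessed", "reflection", "signed", "rectified",
                 "phi0", "phi"))
  re <- run_ehasa(ph$image, verbose = TRUE)
  expect_true(all(c("binary", "mapped") %in% names(re$intermediates)))
  expect_identical(re$intermediates$mapped,
                   map_mask(re$intermediates$binary,
                            re$intermediates$preprocessed))
})

test_that("the unaided baseline recovers a two-phase disk but over-segments heads", {
  fx <- make_disk_image()
  rb <- run_chanvese_baseline(fx$image)
  expect_gte(dice(rb$mask, fx$disk), 0.98)

  expect_equal(run_chanvese_baseline(matrix(0.7, 32, 32))$n_regions, 0L)

  ph <- make_phantom(standard_suite()[["left-lesion"]])
  rb2 <- run_chanvese_baseline(ph$image)
  rh <- run_hasa(ph$image)
  expect_gt(rb2$n_regions, 1L)
  expect_gt(rb2$n_regions, rh$n_regions)
})
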