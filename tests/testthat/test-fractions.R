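test_that("scale_dvf is exact scalar multiplication and composes linearly", {
  vec <- array(0, c(8, 8, 8, 3))
  vec[1, 1, 1, ] <- c(2, 4, 6)
  d <- displacement_field(vec)
  expect_identical(scale_dvf(d, 0)$vectors, vec * 0)
  expect_identical(scale_dvf(d, 1)$vectors, vec)
  expect_equal(scale_dvf(d, -0.5)$vectors[1, 1, 1, ], c(-1, -2, -3))
  r <- make_smooth_dvf(c(8, 8, 8), 2, 2, seed = 1)
  # composition is bit-exact for the interpolation scales in use
  # (signs and powers of two); general scalars agree to rounding
  expect_identical(scale_dvf(scale_dvf(r, 0.5), -1)$vectors,
                   scale_dvf(r, -0.5)$vectors)
  expect_equal(scale_dvf(scale_dvf(r, 0.3), -1.7)$vectors,
               scale_dvf(r, 0.3 * -1.7)$vectors, tolerance = 1e-12)
})

test_that("the default scale set yields 5 fractions with an exact middle", {
  ph <- make_phantom(phantom_config(shape = c(16, 16, 16), n_structures = 2,
                                    seed = 2))
  dvf <- make_smooth_dvf(c(16, 16, 16), 2, 3, seed = 3)
  series <- simulate_fractions(ph$image, ph$contours, dvf)
  expect_length(series$fractions, 5L)
  mid <- series$fractions[[3]]  # scale 0
  expect_identical(mid$image$data, ph$image$data)
  expect_identical(mid$contours$masks, ph$contours$masks)
  expect_error(simulate_fractions(ph$image, ph$contours, dvf,
                                  scales = numeric(0)), "scale")
})

test_that("a unit-scale integer shift reproduces the shift oracle", {
  dm <- c(12, 12, 12)
  mask <- array(0, dm); mask[5:8, 5:8, 5:8] <- 1
  img <- image_volume(array(runif(prod(dm)), dm))
  dvf <- displacement_field(array(rep(c(0, 2, 0), each = prod(dm)),
                                  c(dm, 3)))
  series <- simulate_fractions(img, structure_set(list(organ = mask)), dvf,
                               scales = 1.0)
  expect_equal(series$fractions[[1]]$contours$masks$organ,
               oracle_shift(mask, c(0, 2, 0)))
})

test_that("linear images interpolate exactly at the midpoint scale", {
  dm <- c(12, 12, 12)
  ramp <- array(0, dm)
  for (d in 1:12) ramp[d, , ] <- ramp[d, , ] + 1.5 * d
  for (w in 1:12) ramp[, , w] <- ramp[, , w] - 0.5 * w
  img <- image_volume(ramp)
  mask <- array(0, dm); mask[5:8, 5:8, 5:8] <- 1
  dvf <- displacement_field(array(rep(c(1.2, -0.6, 0.8), each = prod(dm)),
                                  c(dm, 3)))
  series <- simulate_fractions(img, structure_set(list(m = mask)), dvf,
                               scales = c(0, 0.5, 1))
  inner <- 4:9
  f0 <- series$fractions[[1]]$image$data
  f05 <- series$fractions[[2]]$image$data
  f1 <- series$fractions[[3]]$image$data
  expect_equal(f05[inner, inner, inner],
               ((f0 + f1) / 2)[inner, inner, inner], tolerance = 1e-6)
})

test_that("contour propagation preserves binarity and structure count", {
  series <- make_test_series(shape = c(16, 16, 16), n_structures = 2,
                             amplitude = 3)
  for (f in series$fractions) {
    expect_length(f$contours$masks, 2L)
    for (m in f$contours$masks) expect_true(all(m %in% c(0, 1)))
  }
})

test_that("pretrain cohorts are reproducible and grid-consistent", {
  cfg <- phantom_config(shape = c(16, 16, 16), n_structures = 2,
                        dvf_amplitude = 3)
  a <- build_pretrain_cohort(4, cfg, seed = 11)
  b <- build_pretrain_cohort(4, cfg, seed = 11)
  expect_length(a, 4L)
  for (p in seq_along(a)) {
    expect_length(a[[p]]$fractions, 5L)
    expect_identical(a[[p]]$planning_image$data, b[[p]]$planning_image$data)
    for (f in a[[p]]$fractions)
      expect_identical(dim(f$image$data), c(16L, 16L, 16L))
  }
  # patients are independent draws
  expect_false(identical(a[[1]]$planning_image$data,
                         a[[2]]$planning_image$data))
})
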