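test_that("phantom generation is deterministic and organs are well separated", {
  cfg <- phantom_config(shape = c(32, 32, 32), n_structures = 2, seed = 7)
  a <- make_phantom(cfg)
  b <- make_phantom(cfg)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$contours$masks, b$contours$masks)

  cfg3 <- phantom_config(shape = c(32, 32, 32), n_structures = 3, seed = 3)
  ph <- make_phantom(cfg3)
  union <- pmin(Reduce(`+`, ph$contours$masks), 1)
  expect_equal(oracle_components(union), 3)
  # pairwise disjoint
  expect_equal(max(Reduce(`+`, ph$contours$masks)), 1)
})

test_that("noise-free phantoms have exactly constant organ intensities", {
  cfg <- phantom_config(shape = c(24, 24, 24), n_structures = 2,
                        noise_sd = 0, seed = 5)
  ph <- make_phantom(cfg)
  for (m in ph$contours$masks)
    expect_length(unique(ph$image$data[m == 1]), 1L)
  # background is the documented constant
  bg <- ph$image$data[Reduce(`+`, ph$contours$masks) == 0]
  expect_true(all(bg == 0.1))
})

test_that("impossible placements raise an explicit error", {
  expect_error(make_phantom(phantom_config(shape = c(8, 8, 8),
                                           n_structures = 6, seed = 1)),
               "place")
})

test_that("smooth DVFs honour the amplitude bound and zero/seed contracts", {
  z <- make_smooth_dvf(c(16, 16, 16), 0, 3, seed = 1)
  expect_true(all(z$vectors == 0))
  a <- make_smooth_dvf(c(16, 16, 16), 3, 3, seed = 2)
  b <- make_smooth_dvf(c(16, 16, 16), 3, 3, seed = 2)
  expect_identical(a$vectors, b$vectors)
  nrm <- sqrt(a$vectors[, , , 1]^2 + a$vectors[, , , 2]^2 +
                a$vectors[, , , 3]^2)
  expect_lte(max(nrm), 3 + 1e-6)
})

test_that("zero displacement is the identity warp for images and masks", {
  ph <- make_phantom(phantom_config(shape = c(16, 16, 16), n_structures = 2,
                                    seed = 9))
  z <- displacement_field(array(0, c(16, 16, 16, 3)))
  expect_identical(warp_image(ph$image, z)$data, ph$image$data)
  expect_identical(warp_mask(ph$contours$masks[[1]], z),
                   ph$contours$masks[[1]])
})

test_that("constant integer shifts match the index-shift oracle", {
  dm <- c(12, 10, 9)
  ramp <- array(seq_len(prod(dm)), dm)
  dvf <- displacement_field(array(rep(c(1, 0, 0), each = prod(dm)),
                                  c(dm, 3)))
  out <- warp_image(image_volume(ramp, c(1, 1, 1)), dvf)$data
  expect_equal(out, oracle_shift(ramp, c(1, 0, 0)))

  set.seed(4)
  mask <- array(0, dm); mask[4:8, 3:6, 3:6] <- 1
  wm <- warp_mask(mask, dvf)
  expect_equal(wm, oracle_shift(mask, c(1, 0, 0)))
  expect_equal(sum(wm), sum(mask))  # interior shift conserves voxel count
})

test_that("warping forward then backward recovers a linear ramp", {
  dm <- c(12, 12, 12)
  ramp <- array(0, dm)
  for (d in 1:12) ramp[d, , ] <- ramp[d, , ] + 0.5 * d
  for (h in 1:12) ramp[, h, ] <- ramp[, h, ] + 0.25 * h
  img <- image_volume(ramp, c(1, 1, 1))
  t <- c(0.5, -0.25, 0.75)
  const_dvf <- function(t) displacement_field(
    array(rep(t, each = prod(dm)), c(dm, 3)))
  fwd <- warp_image(img, const_dvf(t))
  back <- warp_image(fwd, const_dvf(-t))
  inner <- 3:10
  expect_equal(back$data[inner, inner, inner], ramp[inner, inner, inner],
               tolerance = 1e-6)
})

test_that("masks stay binary under smooth warps and centroids stay local", {
  ph <- make_phantom(phantom_config(shape = c(20, 20, 20), n_structures = 2,
                                    seed = 21))
  amp <- 3
  for (s in 1:4) {
    dvf <- make_smooth_dvf(c(20, 20, 20), amp, 3, seed = s)
    for (m in ph$contours$masks) {
      wm <- warp_mask(m, dvf)
      expect_true(all(wm %in% c(0, 1)))
      if (sum(wm) > 0) {
        cen <- function(x) colMeans(which(x == 1, arr.ind = TRUE))
        expect_lte(sqrt(sum((cen(wm) - cen(m))^2)), amp + 1)
      }
    }
  }
})

test_that("shape mismatches are rejected", {
  img <- image_volume(array(0, c(16, 16, 16)))
  dvf <- make_smooth_dvf(c(12, 12, 12), 1, 2, seed = 1)
  expect_error(warp_image(img, dvf), "shape")
  expect_error(warp_mask(array(0, c(16, 16, 16)), dvf), "shape")
})
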