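test_that("rigid registration recovers identity and known shifts", {
  ph <- make_phantom(phantom_config(shape = c(24, 24, 24), n_structures = 2,
                                    seed = 13))
  reg0 <- rigid_register(ph$image, ph$image)
  expect_lt(sqrt(sum(reg0$transform$translation^2)), 0.1)
  expect_identical(reg0$transform$rotation, diag(3))

  shift <- c(2, 0, 0)
  dvf <- displacement_field(array(rep(shift, each = 24^3), c(24, 24, 24, 3)))
  fixed <- warp_image(ph$image, dvf)
  reg <- rigid_register(ph$image, fixed)
  expect_lt(sqrt(sum((reg$transform$translation - shift)^2)), 0.5)
  expect_lt(mean((reg$resampled$data - fixed$data)^2), 1e-4)
})

test_that("assemble_input builds the documented 3-channel stack", {
  ph <- make_phantom(phantom_config(shape = c(16, 16, 16), n_structures = 2,
                                    seed = 5))
  inp <- assemble_input(ph$image, ph$contours, ph$image)
  expect_identical(dim(inp), c(16L, 16L, 16L, 3L))
  expect_identical(inp[, , , 1], ph$image$data)
  expect_identical(inp[, , , 3], ph$image$data)
  # empty structure set encodes to zeros
  empty <- structure_set(setNames(list(), character(0)))
  inp0 <- assemble_input(ph$image, empty, ph$image)
  expect_true(all(inp0[, , , 2] == 0))
})

test_that("the label channel enumerates k/K for K = 8 structures", {
  dm <- c(16, 16, 16)
  masks <- list()
  for (k in 1:8) {
    m <- array(0, dm)
    m[2 * k - 1, 1:3, 1:3] <- 1
    masks[[paste0("s", k)]] <- m
  }
  ss <- structure_set(masks)
  img <- image_volume(array(0.2, dm))
  inp <- assemble_input(img, ss, img)
  vals <- sort(unique(as.numeric(inp[, , , 2])))
  expect_true(all(vals %in% c(0, (1:8) / 8)))
  expect_identical(vals, c(0, (1:8) / 8))
})

test_that("registration-derived priors duplicate the current image channel", {
  ph <- make_phantom(phantom_config(shape = c(16, 16, 16), n_structures = 2,
                                    seed = 6))
  inp <- assemble_dir_input(ph$image, ph$contours)
  expect_identical(dim(inp)[4], 3L)
  expect_identical(inp[, , , 1], inp[, , , 3])
})

test_that("the contour-prior baseline follows the rigid transform", {
  ph <- make_phantom(phantom_config(shape = c(16, 16, 16), n_structures = 2,
                                    seed = 8))
  # identity: untouched
  out <- contour_prior_baseline(ph$contours, rigid_transform())
  expect_identical(out$masks, ph$contours$masks)
  # known integer shift with identity transform: overlap Dice equals the
  # shift-overlap oracle
  shift <- c(0, 2, 0)
  shifted <- lapply(ph$contours$masks, oracle_shift, t = shift)
  for (nm in names(shifted)) {
    d_pkg <- dice_coefficient(ph$contours$masks[[nm]], shifted[[nm]])
    inter <- sum(ph$contours$masks[[nm]] * shifted[[nm]])
    d_oracle <- 2 * inter /
      (sum(ph$contours$masks[[nm]]) + sum(shifted[[nm]]))
    expect_equal(d_pkg, d_oracle)
  }
})

test_that("a static course gives the baseline a perfect score", {
  ph <- make_phantom(phantom_config(shape = c(16, 16, 16), n_structures = 2,
                                    seed = 9))
  zero <- displacement_field(array(0, c(16, 16, 16, 3)))
  series <- simulate_fractions(ph$image, ph$contours, zero,
                               scales = c(0, 0, 0))
  cp <- contour_prior_course(series)
  atoms <- evaluate_course(cp, series)
  expect_true(all(atoms$dsc == 1))
})

test_that("run_course produces chronological records from zero memory", {
  series <- make_test_series(shape = c(16, 16, 16),
                             scales = seq(-1, 1, length.out = 7))
  m <- seg_model(model_config("lstm_unet", out_channels = 2, features = 2,
                              levels = 2), seed = 2)
  cp <- run_course(m, series, store_memory = TRUE, register = FALSE)
  expect_length(cp$fractions, 7L)
  for (s in cp$fractions[[1]]$memory) {
    expect_true(all(s$h == 0))
    expect_true(all(s$c == 0))
  }
  expect_identical(vapply(cp$fractions, function(f) f$index, integer(1)),
                   1:7)
})

test_that("revised and autonomous priors agree on the first fraction", {
  series <- make_test_series(shape = c(16, 16, 16), scales = c(-1, 0, 1))
  m <- seg_model(model_config("lstm_unet", out_channels = 2, features = 2,
                              levels = 2), seed = 2)
  a <- run_course(m, series, prior_mode = "revised", register = FALSE)
  b <- run_course(m, series, prior_mode = "auto", register = FALSE)
  expect_identical(a$fractions[[1]]$probs, b$fractions[[1]]$probs)
})

test_that("dir mode consumes deformed contours on the current grid", {
  series <- make_test_series(shape = c(16, 16, 16), scales = c(-1, 0, 1))
  m <- seg_model(model_config("lstm_unet", out_channels = 2, features = 2,
                              levels = 2), seed = 2)
  cp <- run_course(m, series, prior_mode = "dir", register = FALSE)
  expect_identical(cp$fractions[[2]]$prior_source, "dir_deformed")
  expect_length(cp$fractions, 3L)
})

test_that("predictions depend only on past fractions and are patient-isolated", {
  series <- make_test_series(shape = c(16, 16, 16),
                             scales = c(-1, -0.5, 0, 0.5, 1))
  m <- seg_model(model_config("lstm_unet", out_channels = 2, features = 2,
                              levels = 2), seed = 2)
  full <- run_course(m, series, register = FALSE)
  # truncation: first 3 fractions rerun reproduce the prefix bit-exactly
  trunc <- patient_series(series$patient_id, series$planning_image,
                          series$planning_contours, series$fractions[1:3])
  part <- run_course(m, trunc, register = FALSE)
  for (k in 1:3)
    expect_identical(part$fractions[[k]]$probs, full$fractions[[k]]$probs)
  # interleaving an unrelated patient does not perturb a later course
  other <- make_test_series(shape = c(16, 16, 16), seed = 77,
                            scales = c(-1, 1))
  run_course(m, other, register = FALSE)
  again <- run_course(m, series, register = FALSE)
  for (k in 1:5)
    expect_identical(again$fractions[[k]]$probs, full$fractions[[k]]$probs)
})

test_that("course prediction rejects a mismatched model", {
  series <- make_test_series(shape = c(16, 16, 16), scales = c(0, 1))
  m_bad <- seg_model(model_config("lstm_unet", out_channels = 5,
                                  features = 2, levels = 2), seed = 1)
  expect_error(run_course(m_bad, series), "structure count")
})
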