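random_lstm_params <- function(cf, seed = 1) {
  set.seed(seed)
  list(w_x = array(rnorm(27 * cf * 4 * cf, 0, 0.3), c(3, 3, 3, cf, 4 * cf)),
       w_h = array(rnorm(27 * cf * 4 * cf, 0, 0.3), c(3, 3, 3, cf, 4 * cf)),
       b = rnorm(4 * cf, 0, 0.2))
}

test_that("the convolutional LSTM cell matches the elementwise gate oracle", {
  for (cf in c(1L, 2L)) {
    p <- random_lstm_params(cf, seed = cf)
    set.seed(10 + cf)
    x <- array(rnorm(64 * cf), c(4, 4, 4, cf))
    h0 <- array(rnorm(64 * cf, 0, 0.5), c(4, 4, 4, cf))
    c0 <- array(rnorm(64 * cf, 0, 0.5), c(4, 4, 4, cf))
    got <- conv_lstm_cell(x, h0, c0, p)
    want <- oracle_conv_lstm(x, h0, c0, p)
    expect_equal(got$h, want$h, tolerance = 1e-6)
    expect_equal(got$c, want$c, tolerance = 1e-6)
  }
})

test_that("zero input, state and bias is an exact fixed point of the cell", {
  cf <- 2L
  p <- random_lstm_params(cf)
  p$b[] <- 0
  zero <- array(0, c(4, 4, 4, cf))
  out <- conv_lstm_cell(zero, zero, zero, p)
  expect_true(all(out$c == 0))
  expect_true(all(out$h == 0))
})

test_that("with closed gates the cell state halves: c_new = 0.5 * c_prev", {
  cf <- 1L
  p <- random_lstm_params(cf)
  p$b[] <- 0
  zero <- array(0, c(4, 4, 4, cf))
  cp <- array(rnorm(64), c(4, 4, 4, cf))
  out <- conv_lstm_cell(zero, zero, cp, p)
  expect_equal(out$c, 0.5 * cp, tolerance = 1e-12)
})

test_that("memory initializes to zero with one (h,c) pair per level", {
  cfg <- model_config("lstm_unet", out_channels = 8)
  mem <- init_memory(cfg, c(32, 32, 32))
  expect_length(mem, 5L)
  for (l in 1:5) {
    expect_true(all(mem[[l]]$h == 0))
    expect_true(all(mem[[l]]$c == 0))
    # channel doubling from 32 first-level features
    expect_identical(dim(mem[[l]]$h)[4], as.integer(32 * 2^(l - 1)))
    expect_identical(dim(mem[[l]]$h)[1:3], as.integer(rep(32 / 2^(l - 1), 3)))
  }
  expect_error(init_memory(cfg, c(30, 32, 32)), "divisible")
})

test_that("forward emits probabilities, is deterministic, and updates memory", {
  cfg <- model_config("lstm_unet", out_channels = 2, features = 2,
                      levels = 2)
  m <- seg_model(cfg, seed = 3)
  set.seed(8)
  input <- array(runif(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  out1 <- model_forward(m, input)
  out2 <- model_forward(m, input)
  expect_true(all(out1$probs >= 0 & out1$probs <= 1))
  expect_identical(out1$probs, out2$probs)
  # state moves away from the zero initialization
  expect_gt(max(abs(out1$memory[[1]]$c)), 0)
  # and a second sequential call moves it again
  out3 <- model_forward(m, input, out1$memory)
  expect_false(identical(out3$memory[[1]]$c, out1$memory[[1]]$c))
  expect_error(model_forward(m, input, out1$memory[1]), "level")
  expect_error(model_forward(m, array(0, c(8, 8, 8, 2))), "input")
  expect_error(model_forward(m, array(0, c(9, 9, 9, 3))), "divisible")
})

test_that("baseline variants are stateless and channel-checked", {
  cfg_ds <- model_config("unet_ds", out_channels = 2, features = 2,
                         levels = 2)
  m_ds <- seg_model(cfg_ds, seed = 1)
  set.seed(2)
  x1 <- array(runif(8 * 8 * 8 * 1), c(8, 8, 8, 1))
  expect_identical(forward_baseline(m_ds, x1), forward_baseline(m_ds, x1))
  expect_error(forward_baseline(m_ds, array(0, c(8, 8, 8, 3))), "input")
  expect_error(model_config("unet_ds", out_channels = 2, in_channels = 3),
               "1 input channel")
  cfg_pr <- model_config("unet_prior", out_channels = 2, features = 2,
                         levels = 2)
  m_pr <- seg_model(cfg_pr, seed = 1)
  expect_error(forward_baseline(seg_model(model_config("lstm_unet",
    out_channels = 2, features = 2, levels = 2)), x1), "memory-free")
  expect_gt(count_parameters(m_pr), count_parameters(m_ds))
})

test_that("parameter counts scale as expected", {
  c1 <- count_parameters(model_config("lstm_unet", out_channels = 2,
                                      features = 4, levels = 3))
  c2 <- count_parameters(model_config("lstm_unet", out_channels = 2,
                                      features = 8, levels = 3))
  expect_gt(c2 / c1, 3.5)   # convolution weights dominate: ~4x
  expect_lt(c2 / c1, 4.5)
  cds <- count_parameters(model_config("unet_ds", out_channels = 2,
                                       features = 4, levels = 3))
  expect_gt(c1, cds)  # LSTM variant is a strict superset of layers
})

test_that("every parameter receives gradient from the composite loss", {
  cfg <- model_config("lstm_unet", out_channels = 2, features = 2,
                      levels = 2)
  m <- seg_model(cfg, seed = 4)
  set.seed(5)
  input <- array(runif(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  target <- array(rbinom(8 * 8 * 8 * 2, 1, 0.3), c(8, 8, 8, 2))
  # nonzero carried memory, as from a previous fraction: the hidden-to-gate
  # kernels only see gradient once h(t-1) is nonzero
  mem <- lapply(init_memory(cfg, c(8, 8, 8)), function(s)
    list(h = array(rnorm(length(s$h), 0, 0.1), dim(s$h)),
         c = array(rnorm(length(s$c), 0, 0.1), dim(s$c))))
  ft <- progseg:::forward_tape(m, input, mem)
  loss <- progseg:::tg_scalar_mix(progseg:::tg_bce(ft$probs, target),
                                  progseg:::tg_soft_dice(ft$probs, target),
                                  0.5, 0.5)
  progseg:::tg_backward(loss)
  grads <- progseg:::collect_grads(ft$params)
  for (nm in names(m$params)) {
    for (f in names(m$params[[nm]])) {
      expect_false(is.null(grads[[nm]][[f]]),
                   label = paste0(nm, "$", f, " gradient present"))
      # conv biases directly before instance norm are analytically
      # mean-free; every other parameter must see nonzero gradient
      if (!(f == "b" && !grepl("lstm|up|head", nm)))
        expect_gt(max(abs(grads[[nm]][[f]])), 0,
                  label = paste0(nm, "$", f, " gradient nonzero"))
    }
  }
})

test_that("autograd gradients match central finite differences", {
  cfg <- model_config("lstm_unet", out_channels = 2, features = 2,
                      levels = 2)
  m <- seg_model(cfg, seed = 4)
  set.seed(6)
  input <- array(runif(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  target <- array(rbinom(8 * 8 * 8 * 2, 1, 0.3), c(8, 8, 8, 2))
  mem <- lapply(init_memory(cfg, c(8, 8, 8)), function(s)
    list(h = array(rnorm(length(s$h), 0, 0.1), dim(s$h)),
         c = array(rnorm(length(s$c), 0, 0.1), dim(s$c))))
  loss_value <- function() {
    ft <- progseg:::forward_tape(m, input, mem)
    0.5 * bce_loss(ft$probs$value, target) +
      0.5 * soft_dice_loss(ft$probs$value, target)
  }
  ft <- progseg:::forward_tape(m, input, mem)
  loss <- progseg:::tg_scalar_mix(progseg:::tg_bce(ft$probs, target),
                                  progseg:::tg_soft_dice(ft$probs, target),
                                  0.5, 0.5)
  progseg:::tg_backward(loss)
  grads <- progseg:::collect_grads(ft$params)
  h <- 1e-5
  set.seed(7)
  for (nm in c("enc1_c1", "lstm1", "lstm2", "up1", "dec1_c2", "head")) {
    f <- sample(names(m$params[[nm]]), 1)
    idx <- sample(length(m$params[[nm]][[f]]), 1)
    orig <- m$params[[nm]][[f]][idx]
    m$params[[nm]][[f]][idx] <- orig + h
    lp <- loss_value()
    m$params[[nm]][[f]][idx] <- orig - h
    lm <- loss_value()
    m$params[[nm]][[f]][idx] <- orig
    num <- (lp - lm) / (2 * h)
    ana <- grads[[nm]][[f]][idx]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste0("gradient of ", nm, "$", f))
  }
})
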