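# The LSTM-UNet and its two neural baselines.
#
# Architecture: a 3D U-Net with `levels` resolutions. Each encoder level
# applies two (3x3x3 conv -> instance norm -> ReLU) blocks, doubling the
# channel count per level, with 2x max-pool between levels. In the
# `lstm_unet` variant a convolutional LSTM unit sits at every resolution:
# the encoder feature is the cell input x(t), the per-patient (h, c) state
# is carried across fractions, and the cell output c(t) is what the decoder
# consumes through the skip connection (the bottom level's c(t) feeds the
# decoder trunk). The decoder mirrors the encoder with kernel-2 stride-2
# transposed-convolution upsampling, concatenation with the skip feature,
# and two conv blocks; a final 1x1x1 convolution with a per-structure
# sigmoid produces multi-label probabilities.
#
# The baselines share the identical U-Net topology with plain skip
# connections and no state: `unet_prior` takes the same 3-channel input,
# `unet_ds` only the current image (1 channel).

#' Model architecture settings
#'
#' @param variant `"lstm_unet"` (memory in every skip connection),
#'   `"unet_prior"` (same 3-channel input, no memory), or `"unet_ds"`
#'   (current image only, no prior, no memory).
#' @param out_channels number of structures segmented (one sigmoid
#'   probability channel each).
#' @param in_channels input channels; defaults to 3 for the prior-guided
#'   variants (prior image, encoded prior contours, current image) and 1
#'   for `unet_ds`.
#' @param features first-level feature channels (doubled per level;
#'   default 32).
#' @param levels number of resolutions, i.e. LSTM units in the
#'   `lstm_unet` variant (default 5). Input spatial dims must be divisible
#'   by `2^(levels - 1)`.
#' @param decoder_skip whether the decoder consumes the LSTM cell state
#'   `"c"` (default) or the hidden state `"h"`.
#' @return A `model_config` list.
#' @export
model_config <- function(variant = c("lstm_unet", "unet_prior", "unet_ds"),
                         out_channels, in_channels = NULL, features = 32L,
                         levels = 5L, decoder_skip = c("c", "h")) {
  variant <- match.arg(variant)
  decoder_skip <- match.arg(decoder_skip)
  if (is.null(in_channels))
    in_channels <- if (variant == "unet_ds") 1L else 3L
  if (variant == "unet_ds" && in_channels != 1L)
    stop("unet_ds takes exactly 1 input channel", call. = FALSE)
  if (variant != "unet_ds" && in_channels != 3L)
    stop(variant, " takes exactly 3 input channels", call. = FALSE)
  stopifnot(levels >= 2L, features >= 1L, out_channels >= 1L)
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 features = as.integer(features), levels = as.integer(levels),
                 kernel = 3L, decoder_skip = decoder_skip),
            class = "model_config")
}

# Channel count of level l.
level_channels <- function(config, l) config$features * 2L^(l - 1L)

conv_init <- function(K, cin, cout, gain = 2) {
  fan_in <- K^3 * cin
  array(rnorm(K^3 * cin * cout, 0, sqrt(gain / fan_in)),
        c(K, K, K, cin, cout))
}

# Parameter set for one (conv -> instance norm) block.
block_params <- function(K, cin, cout) {
  list(w = conv_init(K, cin, cout), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

#' Instantiate a segmentation model
#'
#' Builds the parameter set for the configured variant with He-style
#' random initialization (forget-gate biases start at 1 so early memory is
#' retained; the output head's bias starts at -2 so initial foreground
#' probabilities reflect the small volume fraction of real structures). The returned object is an environment so that training
#' updates parameters in place.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `progseg_model` with fields `config` and
#'   `params` (named list of numeric arrays).
#' @export
seg_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  L <- config$levels
  with_seed(seed, {
    params <- list()
    for (l in seq_len(L)) {
      cin <- if (l == 1L) config$in_channels else level_channels(config, l - 1L)
      cf <- level_channels(config, l)
      params[[sprintf("enc%d_c1", l)]] <- block_params(3L, cin, cf)
      params[[sprintf("enc%d_c2", l)]] <- block_params(3L, cf, cf)
      if (config$variant == "lstm_unet") {
        b <- numeric(4L * cf)
        b[cf + seq_len(cf)] <- 1  # forget gate
        params[[sprintf("lstm%d", l)]] <- list(
          w_x = conv_init(3L, cf, 4L * cf, gain = 1),
          w_h = conv_init(3L, cf, 4L * cf, gain = 1),
          b = b)
      }
    }
    for (l in seq_len(L - 1L)) {
      cf <- level_channels(config, l)
      cup <- level_channels(config, l + 1L)
      params[[sprintf("up%d", l)]] <- list(
        w = conv_init(2L, cup, cf), b = numeric(cf))
      params[[sprintf("dec%d_c1", l)]] <- block_params(3L, 2L * cf, cf)
      params[[sprintf("dec%d_c2", l)]] <- block_params(3L, cf, cf)
    }
    # head bias starts negative so initial foreground probability is low
    # (~0.12), reflecting that structures occupy a small volume fraction;
    # this markedly speeds up early Dice convergence
    params[["head"]] <- list(w = conv_init(1L, config$features,
                                           config$out_channels),
                             b = rep(-2, config$out_channels))
    model <- new.env(parent = emptyenv())
    model$config <- config
    model$params <- params
    class(model) <- "progseg_model"
    model
  })
}

#' @export
print.progseg_model <- function(x, ...) {
  cat("<progseg_model> variant ", x$config$variant, ", ",
      x$config$in_channels, "-channel input, ", x$config$out_channels,
      " structure(s), features ", x$config$features, ", levels ",
      x$config$levels, ", ", format(count_parameters(x), big.mark = ","),
      " parameters\n", sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model a `progseg_model` (or a [model_config()], which is
#'   instantiated temporarily).
#' @return Integer scalar: total number of trainable values.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "model_config")) model <- seg_model(model, seed = 1L)
  sum(vapply(model$params,
             function(p) sum(vapply(p, length, numeric(1))), numeric(1)))
}

#' Zeroed per-patient memory
#'
#' One (h, c) pair per resolution, every entry exactly 0; this is the state
#' the model starts from before a patient's first fraction.
#'
#' @param config a [model_config()].
#' @param input_shape spatial grid size, integer length-3; each dimension
#'   must be divisible by `2^(levels - 1)`.
#' @return A list of `levels` elements, each `list(h = , c = )` of zero
#'   arrays at that level's resolution and channel count.
#' @export
init_memory <- function(config, input_shape) {
  stopifnot(inherits(config, "model_config"))
  input_shape <- as.integer(input_shape)
  div <- 2L^(config$levels - 1L)
  if (any(input_shape %% div != 0L))
    stop("input dims must be divisible by 2^(levels-1) = ", div,
         call. = FALSE)
  lapply(seq_len(config$levels), function(l) {
    shp <- input_shape %/% (2L^(l - 1L))
    cf <- level_channels(config, l)
    list(h = array(0, c(shp, cf)), c = array(0, c(shp, cf)))
  })
}

# --- convolutional LSTM cell -------------------------------------------------

# Differentiable cell used inside the forward tape. Gate channel order in
# the stacked kernels is (input i, forget f, output o, candidate g):
#   i = sigma(Wxi*x + Whi*h + bi)      f = sigma(Wxf*x + Whf*h + bf)
#   o = sigma(Wxo*x + Who*h + bo)      g = tanh(Wxg*x + Whg*h + bg)
#   c_t = f . c_{t-1} + i . g          h_t = o . tanh(c_t)
# with * a resolution-preserving 3x3x3 convolution and . the Hadamard
# product.
tg_conv_lstm <- function(x, h_prev, c_prev, w_x, w_h, b) {
  cf <- dim(tg_wrap(x)$value)[4L]
  zx <- tg_conv3d(x, w_x, b)
  zh <- tg_conv3d(h_prev, w_h, tg_node(numeric(4L * cf)))
  z <- tg_add(zx, zh)
  i <- tg_sigmoid(tg_channels(z, seq_len(cf)))
  f <- tg_sigmoid(tg_channels(z, cf + seq_len(cf)))
  o <- tg_sigmoid(tg_channels(z, 2L * cf + seq_len(cf)))
  g <- tg_tanh(tg_channels(z, 3L * cf + seq_len(cf)))
  c_new <- tg_add(tg_mul(f, c_prev), tg_mul(i, g))
  h_new <- tg_mul(o, tg_tanh(c_new))
  list(h = h_new, c = c_new)
}

#' Apply one convolutional LSTM cell
#'
#' The state-update primitive of the memory mechanism, exposed on plain
#' arrays. `params` holds the stacked input-to-gate kernel `w_x`
#' (dim `c(3,3,3,C,4C)`), hidden-to-gate kernel `w_h` (same shape) and bias
#' `b` (length `4C`), with gate channel order input, forget, output,
#' candidate.
#'
#' @param x input feature grid, dim `c(D,H,W,C)`.
#' @param h_prev,c_prev previous hidden and cell state, same shape as `x`.
#' @param params list with `w_x`, `w_h`, `b`.
#' @return `list(h = , c = )`, the updated states.
#' @export
conv_lstm_cell <- function(x, h_prev, c_prev, params) {
  stopifnot(identical(dim(x), dim(h_prev)),
            identical(dim(x), dim(c_prev)))
  out <- tg_conv_lstm(tg_node(x), tg_node(h_prev), tg_node(c_prev),
                      tg_node(params$w_x), tg_node(params$w_h),
                      tg_node(params$b))
  list(h = out$h$value, c = out$c$value)
}

# --- full forward pass -------------------------------------------------------

tg_conv_block <- function(x, p) {
  tg_relu(tg_instance_norm(tg_conv3d(x, p$w, p$b),
                           p$gamma, p$beta))
}

# Wrap every parameter array of the model into leaf nodes for one tape.
wrap_params <- function(model) {
  lapply(model$params, function(p) lapply(p, tg_node))
}

# Forward pass building the autodiff tape. `memory` entries may be raw
# arrays (detached, truncated backpropagation) or tg_nodes (full
# backpropagation through time). Returns the probability node, the new
# memory (nodes), and the wrapped parameter leaves.
forward_tape <- function(model, input, memory = NULL, pn = NULL) {
  config <- model$config
  L <- config$levels
  if (is.null(pn)) pn <- wrap_params(model)
  dmx <- dim(input)
  if (length(dmx) != 4L || dmx[4L] != config$in_channels)
    stop("input must be (D,H,W,", config$in_channels, ")", call. = FALSE)
  div <- 2L^(L - 1L)
  if (any(dmx[1:3] %% div != 0L))
    stop("input dims must be divisible by 2^(levels-1) = ", div,
         call. = FALSE)
  is_lstm <- config$variant == "lstm_unet"
  if (is_lstm) {
    if (is.null(memory)) memory <- init_memory(config, dmx[1:3])
    if (length(memory) != L)
      stop("memory does not match the model's level count", call. = FALSE)
  }
  x <- tg_node(input)
  skips <- vector("list", L)
  new_mem <- vector("list", L)
  for (l in seq_len(L)) {
    if (l > 1L) x <- tg_maxpool(x)
    x <- tg_conv_block(x, pn[[sprintf("enc%d_c1", l)]])
    x <- tg_conv_block(x, pn[[sprintf("enc%d_c2", l)]])
    if (is_lstm) {
      mp <- pn[[sprintf("lstm%d", l)]]
      hc <- memory[[l]]
      if (!identical(dim(tg_wrap(hc$h)$value), dim(x$value)))
        stop("memory shape does not match encoder level ", l, call. = FALSE)
      st <- tg_conv_lstm(x, hc$h, hc$c, mp$w_x, mp$w_h, mp$b)
      new_mem[[l]] <- st
      skips[[l]] <- if (config$decoder_skip == "c") st$c else st$h
    } else {
      skips[[l]] <- x
    }
  }
  trunk <- skips[[L]]
  for (l in seq(L - 1L, 1L)) {
    up <- pn[[sprintf("up%d", l)]]
    trunk <- tg_convT3d(trunk, up$w, up$b)
    trunk <- tg_concat(trunk, skips[[l]])
    trunk <- tg_conv_block(trunk, pn[[sprintf("dec%d_c1", l)]])
    trunk <- tg_conv_block(trunk, pn[[sprintf("dec%d_c2", l)]])
  }
  head <- pn[["head"]]
  probs <- tg_sigmoid(tg_conv3d(trunk, head$w, head$b, K = 1L, pad = 0L))
  list(probs = probs, memory = if (is_lstm) new_mem, params = pn)
}

#' Run the model on one fraction's input
#'
#' @param model a `progseg_model`.
#' @param input numeric array `c(D,H,W,in_channels)`, e.g. from
#'   [assemble_input()].
#' @param memory per-patient memory from [init_memory()] or a previous
#'   call; ignored by the stateless baselines.
#' @return `list(probs = , memory = )`: per-structure probability volumes
#'   (`c(D,H,W,out_channels)`, values in \[0,1\]) and the updated memory
#'   (`NULL` for baselines).
#' @export
model_forward <- function(model, input, memory = NULL) {
  stopifnot(inherits(model, "progseg_model"))
  ft <- forward_tape(model, input, memory)
  list(probs = ft$probs$value,
       memory = if (!is.null(ft$memory))
         lapply(ft$memory, function(s) list(h = s$h$value, c = s$c$value)))
}

#' @rdname model_forward
#' @details `forward_baseline()` is the stateless entry point for the
#'   `unet_prior` and `unet_ds` variants; it rejects models with memory.
#' @export
forward_baseline <- function(model, input) {
  stopifnot(inherits(model, "progseg_model"))
  if (model$config$variant == "lstm_unet")
    stop("forward_baseline is for the memory-free variants", call. = FALSE)
  model_forward(model, input)$probs
}

# --- checkpointing -----------------------------------------------------------

#' Save and load model checkpoints
#'
#' A checkpoint bundles the architecture config and all parameter arrays
#' (plus, optionally, optimizer and scheduler state for resumption).
#'
#' @param model a `progseg_model`.
#' @param path file path (`.rds`).
#' @param extra optional named list stored alongside (e.g. optimizer state).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns `list(model = , extra = )`.
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  saveRDS(list(config = model$config, params = model$params, extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- new.env(parent = emptyenv())
  model$config <- ck$config
  model$params <- ck$params
  class(model) <- "progseg_model"
  list(model = model, extra = ck$extra)
}

#' Save and load per-patient memory between sessions
#'
#' Serializes the per-level (h, c) arrays so an adaptive course can resume
#' across sessions.
#'
#' @param memory memory list as returned by [model_forward()].
#' @param path file path (`.rds`).
#' @return `save_memory()` returns `path` invisibly; `load_memory()` the
#'   memory list.
#' @export
save_memory <- function(memory, path) {
  saveRDS(memory, path)
  invisible(path)
}

#' @rdname save_memory
#' @export
load_memory <- function(path) readRDS(path)
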