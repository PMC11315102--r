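# Differentiable operations used by the segmentation networks. Each op
# takes tg_node (or raw array) arguments and returns a tg_node whose vjp
# closure produces the parents' gradients.

tg_conv3d <- function(x, w, b, K = 3L, pad = (K - 1L) %/% 2L) {
  x <- tg_wrap(x); w <- tg_wrap(w); b <- tg_wrap(b)
  dmx <- dim(x$value)
  dmw <- dim(w$value)
  stopifnot(length(dmx) == 4L, dmw[4L] == dmx[4L])
  D <- dmx[1]; H <- dmx[2]; W <- dmx[3]; Cin <- dmx[4]; Cout <- dmw[5L]
  y <- cpp_conv3d(x$value, w$value, b$value, D, H, W, Cin, Cout, K, pad)
  need_gx <- !is.null(x$vjp) || length(x$parents) > 0L || isTRUE(x$requires)
  tg_node(y, parents = list(x, w, b), vjp = function(g) {
    bw <- cpp_conv3d_bwd(x$value, w$value, g, D, H, W, Cin, Cout, K, pad,
                         need_gx)
    list(if (need_gx) bw$gx else NULL, bw$gw, bw$gb)
  })
}

tg_convT3d <- function(x, w, b) {
  x <- tg_wrap(x); w <- tg_wrap(w); b <- tg_wrap(b)
  dmx <- dim(x$value)
  D <- dmx[1]; H <- dmx[2]; W <- dmx[3]; Cin <- dmx[4]
  Cout <- dim(w$value)[5L]
  y <- cpp_convT3d(x$value, w$value, b$value, D, H, W, Cin, Cout)
  tg_node(y, parents = list(x, w, b), vjp = function(g) {
    bw <- cpp_convT3d_bwd(x$value, w$value, g, D, H, W, Cin, Cout)
    list(bw$gx, bw$gw, bw$gb)
  })
}

tg_maxpool <- function(x) {
  x <- tg_wrap(x)
  dm <- dim(x$value)
  res <- cpp_maxpool3d(x$value, dm[1], dm[2], dm[3], dm[4])
  tg_node(res$y, parents = list(x), vjp = function(g) {
    gx <- cpp_maxpool3d_bwd(g, res$idx, length(x$value))
    dim(gx) <- dm
    list(gx)
  })
}

tg_relu <- function(x) {
  x <- tg_wrap(x)
  y <- pmax(x$value, 0)
  dim(y) <- dim(x$value)
  tg_node(y, parents = list(x), vjp = function(g) list(g * (x$value > 0)))
}

tg_sigmoid <- function(x) {
  x <- tg_wrap(x)
  y <- 1 / (1 + exp(-x$value))
  tg_node(y, parents = list(x), vjp = function(g) list(g * y * (1 - y)))
}

tg_tanh <- function(x) {
  x <- tg_wrap(x)
  y <- tanh(x$value)
  tg_node(y, parents = list(x), vjp = function(g) list(g * (1 - y * y)))
}

tg_add <- function(a, b) {
  a <- tg_wrap(a); b <- tg_wrap(b)
  tg_node(a$value + b$value, parents = list(a, b),
          vjp = function(g) list(g, g))
}

tg_mul <- function(a, b) {
  a <- tg_wrap(a); b <- tg_wrap(b)
  tg_node(a$value * b$value, parents = list(a, b),
          vjp = function(g) list(g * b$value, g * a$value))
}

# Concatenate two feature maps along the channel axis.
tg_concat <- function(a, b) {
  a <- tg_wrap(a); b <- tg_wrap(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(identical(da[1:3], db[1:3]))
  y <- array(0, c(da[1:3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a$value
  y[, , , da[4] + seq_len(db[4])] <- b$value
  tg_node(y, parents = list(a, b), vjp = function(g) {
    list(g[, , , seq_len(da[4]), drop = FALSE],
         g[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

# Select a contiguous channel range.
tg_channels <- function(x, idx) {
  x <- tg_wrap(x)
  dm <- dim(x$value)
  y <- x$value[, , , idx, drop = FALSE]
  tg_node(y, parents = list(x), vjp = function(g) {
    gx <- array(0, dm)
    gx[, , , idx] <- g
    list(gx)
  })
}

# Instance normalization: per-channel standardization over the spatial
# volume, with learnable gain and bias. Chosen because the sequential
# fraction-by-fraction regime fixes the batch size at 1.
tg_instance_norm <- function(x, gamma, beta, eps = 1e-5) {
  x <- tg_wrap(x); gamma <- tg_wrap(gamma); beta <- tg_wrap(beta)
  dm <- dim(x$value)
  S <- prod(dm[1:3]); C <- dm[4]
  xm <- matrix(x$value, S, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma$value, `*`), 2L, beta$value, `+`)
  dim(y) <- dm
  tg_node(y, parents = list(x, gamma, beta), vjp = function(g) {
    gm <- matrix(g, S, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gh <- sweep(gm, 2L, gamma$value, `*`)
    t1 <- sweep(gh, 2L, colMeans(gh))
    t2 <- sweep(xhat, 2L, colMeans(gh * xhat), `*`)
    gx <- sweep(t1 - t2, 2L, inv_sd, `*`)
    dim(gx) <- dm
    list(gx, dgamma, dbeta)
  })
}

# Composite segmentation loss on probabilities: equally weighted binary
# cross-entropy and soft Dice, as single graph nodes with closed-form
# gradients.
tg_bce <- function(pred, target, clamp = 1e-7) {
  pred <- tg_wrap(pred)
  p <- pmin(pmax(pred$value, clamp), 1 - clamp)
  n <- length(p)
  val <- -mean(target * log(p) + (1 - target) * log(1 - p))
  tg_node(val, parents = list(pred), vjp = function(g) {
    gx <- as.numeric(g) * (-(target / p) + (1 - target) / (1 - p)) / n
    dim(gx) <- dim(pred$value)
    list(gx)
  })
}

tg_soft_dice <- function(pred, target, eps = 1e-6) {
  pred <- tg_wrap(pred)
  dm <- dim(pred$value)
  C <- dm[4]
  S <- prod(dm[1:3])
  pm <- matrix(pred$value, S, C)
  tm <- matrix(target, S, C)
  inter <- colSums(pm * tm)
  sums <- colSums(pm) + colSums(tm)
  dice_c <- (2 * inter + eps) / (sums + eps)
  val <- mean(1 - dice_c)
  tg_node(val, parents = list(pred), vjp = function(g) {
    # d(1 - dice_c)/dp = -(2 t (sums+eps) - (2 inter+eps)) / (sums+eps)^2
    gm <- matrix(0, S, C)
    for (c in seq_len(C)) {
      gm[, c] <- -(2 * tm[, c] * (sums[c] + eps) - (2 * inter[c] + eps)) /
        (sums[c] + eps)^2
    }
    gx <- as.numeric(g) * gm / C
    dim(gx) <- dm
    list(gx)
  })
}

tg_scalar_mix <- function(a, b, wa, wb) {
  a <- tg_wrap(a); b <- tg_wrap(b)
  tg_node(wa * a$value + wb * b$value, parents = list(a, b),
          vjp = function(g) list(g * wa, g * wb))
}
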