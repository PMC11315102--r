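# Independent brute-force oracles. These deliberately share no code with
# the package internals: direct nested-loop convolution, elementwise gate
# equations, index-shift warps, flood fill, all-pairs surface distances and
# textbook t statistics.

# Direct zero-padded 3D convolution of a (D,H,W,Cin) array with a
# (K,K,K,Cin,Cout) kernel, resolution preserving.
oracle_conv3d <- function(x, w, b) {
  dm <- dim(x); K <- dim(w)[1]; pad <- (K - 1) %/% 2
  cout <- dim(w)[5]
  y <- array(0, c(dm[1:3], cout))
  for (co in seq_len(cout)) {
    acc <- array(b[co], dm[1:3])
    for (ci in seq_len(dm[4])) for (kd in 1:K) for (kh in 1:K) for (kw in 1:K) {
      wgt <- w[kd, kh, kw, ci, co]
      if (wgt == 0) next
      for (d in seq_len(dm[1])) {
        sd <- d + kd - 1 - pad
        if (sd < 1 || sd > dm[1]) next
        for (h in seq_len(dm[2])) {
          sh <- h + kh - 1 - pad
          if (sh < 1 || sh > dm[2]) next
          for (wv in seq_len(dm[3])) {
            sw <- wv + kw - 1 - pad
            if (sw < 1 || sw > dm[3]) next
            acc[d, h, wv] <- acc[d, h, wv] + wgt * x[sd, sh, sw, ci]
          }
        }
      }
    }
    y[, , , co] <- acc
  }
  y
}

# Elementwise convolutional-LSTM gate equations, computed directly from the
# same stacked kernels (gate order i, f, o, g).
oracle_conv_lstm <- function(x, h_prev, c_prev, params) {
  cf <- dim(x)[4]
  zx <- oracle_conv3d(x, params$w_x, params$b)
  zh <- oracle_conv3d(h_prev, params$w_h, numeric(4 * cf))
  z <- zx + zh
  sig <- function(v) 1 / (1 + exp(-v))
  i <- sig(z[, , , seq_len(cf), drop = FALSE])
  f <- sig(z[, , , cf + seq_len(cf), drop = FALSE])
  o <- sig(z[, , , 2 * cf + seq_len(cf), drop = FALSE])
  g <- tanh(z[, , , 3 * cf + seq_len(cf), drop = FALSE])
  cc <- f * c_prev + i * g
  hh <- o * tanh(cc)
  list(h = hh, c = cc)
}

# Integer-shift oracle with edge clamping, pull convention:
# out(v) = in(v + t).
oracle_shift <- function(arr, t) {
  dm <- dim(arr)
  out <- array(0, dm)
  for (d in seq_len(dm[1])) for (h in seq_len(dm[2])) for (w in seq_len(dm[3])) {
    sd <- min(max(d + t[1], 1), dm[1])
    sh <- min(max(h + t[2], 1), dm[2])
    sw <- min(max(w + t[3], 1), dm[3])
    out[d, h, w] <- arr[sd, sh, sw]
  }
  out
}

# 6-connected components by BFS flood fill.
oracle_components <- function(mask) {
  dm <- dim(mask)
  seen <- array(FALSE, dm)
  count <- 0
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (i in which(mask == 1 & !seen)) {
    if (seen[i]) next
    count <- count + 1
    queue <- list(arrayInd(i, dm)[1, ])
    seen[i] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (k in 1:6) {
        n <- v + offs[k, ]
        if (any(n < 1) || any(n > dm)) next
        if (mask[n[1], n[2], n[3]] == 1 && !seen[n[1], n[2], n[3]]) {
          seen[n[1], n[2], n[3]] <- TRUE
          queue[[length(queue) + 1]] <- n
        }
      }
    }
  }
  count
}

# Boundary voxels (foreground with a 6-neighbour background or on the
# volume edge), as an n x 3 index matrix.
oracle_boundary <- function(mask) {
  dm <- dim(mask)
  out <- NULL
  for (d in seq_len(dm[1])) for (h in seq_len(dm[2])) for (w in seq_len(dm[3])) {
    if (mask[d, h, w] == 0) next
    edge <- d == 1 || d == dm[1] || h == 1 || h == dm[2] ||
      w == 1 || w == dm[3]
    if (!edge) {
      nb <- c(mask[d - 1, h, w], mask[d + 1, h, w], mask[d, h - 1, w],
              mask[d, h + 1, w], mask[d, h, w - 1], mask[d, h, w + 1])
      edge <- any(nb == 0)
    }
    if (edge) out <- rbind(out, c(d, h, w))
  }
  out
}

# All-pairs directed surface distances in mm.
oracle_surface_dists <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- oracle_boundary(a); pb <- oracle_boundary(b)
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
                Vectorize(function(i, j)
                  sqrt(sum(((pa[i, ] - pb[j, ]) * spacing)^2))))
  list(ab = apply(dmat, 1, min), ba = apply(dmat, 2, min))
}

# Textbook paired t statistic and two-sided p.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}

# Small helper: one deterministic phantom series for runtime tests.
make_test_series <- function(shape = c(16, 16, 16), n_structures = 2,
                             seed = 7, amplitude = 2, smoothness = 3,
                             scales = c(-1, -0.5, 0, 0.5, 1)) {
  ph <- make_phantom(phantom_config(shape = shape,
                                    n_structures = n_structures,
                                    seed = seed))
  dvf <- make_smooth_dvf(shape, amplitude, smoothness, seed = seed + 1)
  simulate_fractions(ph$image, ph$contours, dvf, scales = scales)
}
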