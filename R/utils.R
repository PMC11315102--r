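# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Separable 3D Gaussian smoothing with edge renormalisation.
gauss_smooth3 <- function(arr, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  smooth_axis <- function(n) {
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmax(1L, pmin(n, i + seq(-r, r)))
      for (t in seq_along(j)) S[i, j[t]] <- S[i, j[t]] + k[t]
    }
    S / rowSums(S)
  }
  dm <- dim(arr)
  S1 <- smooth_axis(dm[1]); S2 <- smooth_axis(dm[2]); S3 <- smooth_axis(dm[3])
  x <- matrix(arr, dm[1], dm[2] * dm[3])
  x <- S1 %*% x
  x <- array(x, dm)
  x <- aperm(x, c(2, 1, 3))
  x <- array(S2 %*% matrix(x, dm[2], dm[1] * dm[3]), c(dm[2], dm[1], dm[3]))
  x <- aperm(x, c(2, 1, 3))
  x <- aperm(x, c(3, 1, 2))
  x <- array(S3 %*% matrix(x, dm[3], dm[1] * dm[2]), c(dm[3], dm[1], dm[2]))
  aperm(x, c(2, 3, 1))
}

# Stack 3D arrays into a (D,H,W,C) feature array.
stack_channels <- function(...) {
  chans <- list(...)
  dm <- dim(chans[[1L]])
  arr <- array(0, c(dm, length(chans)))
  for (i in seq_along(chans)) arr[, , , i] <- chans[[i]]
  arr
}
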