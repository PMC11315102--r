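# Minimal reverse-mode automatic differentiation over dense arrays.
#
# A node is an environment holding a value, its parents, and a vector-
# Jacobian product closure mapping the node's output gradient to one
# gradient per parent. Backpropagation walks the graph in reverse
# topological order. This is deliberately small: just enough machinery for
# a convolutional encoder/decoder with LSTM state, with the heavy kernels
# (im2col GEMM convolutions, pooling) delegated to compiled code.

.tg_counter <- local({
  i <- 0L
  function() { i <<- i + 1L; i }
})

# Create a graph node. Leaves (parameters, inputs) have no vjp.
tg_node <- function(value, parents = list(), vjp = NULL) {
  e <- new.env(parent = emptyenv())
  e$id <- .tg_counter()
  e$value <- value
  e$parents <- parents
  e$vjp <- vjp
  e$grad <- NULL
  class(e) <- "tg_node"
  e
}

tg_is_node <- function(x) inherits(x, "tg_node")

# Accept raw arrays anywhere a node is expected.
tg_wrap <- function(x) if (tg_is_node(x)) x else tg_node(x)

#' @export
print.tg_node <- function(x, ...) {
  cat("<tg_node ", x$id, "> dim ", paste(dim(x$value), collapse = "x"),
      if (is.null(x$vjp)) " (leaf)" else "", "\n", sep = "")
  invisible(x)
}

# Reverse-mode sweep from a scalar root. Fills $grad on every reachable
# node; leaves keep their accumulated gradients for the optimizer.
tg_backward <- function(root) {
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv(), size = 1024L)
  # iterative DFS (graph depth can exceed R's recursion limit)
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(top$node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = top$node, stage = 2L)
      for (p in top$node$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", n_ord))
      order[[n_ord]] <- top$node
    }
  }
  root$grad <- array(1, dim = dim(root$value) %||% 1L)
  for (i in rev(seq_len(n_ord))) {
    nd <- order[[i]]
    if (is.null(nd$vjp) || is.null(nd$grad)) next
    pg <- nd$vjp(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (is.null(pg[[j]])) next
      p$grad <- if (is.null(p$grad)) pg[[j]] else p$grad + pg[[j]]
    }
    nd$grad <- NULL  # free intermediate gradients early
  }
  invisible(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
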