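# Reverse-mode automatic differentiation over matrices.
#
# A "tape" records nodes in creation order (which is topological); backward
# walks the chain in reverse via each node's `prev` pointer, so appending a
# node is O(1) and no list ever has to grow. Nodes are environments: `val`
# holds the matrix, `grad` the accumulated upstream gradient, `back` the
# closure that pushes `grad` into the parents. Parameters are plain matrices
# living in a named list; `ad_par()` wraps each one in at most one node per
# tape so that gradients from every instance of a mini-batch accumulate on
# the same node.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_begin <- function() {
  tp <- new.env(parent = emptyenv())
  tp$last <- NULL
  tp$pcache <- new.env(parent = emptyenv())
  tp$ccache <- new.env(parent = emptyenv()) # per-batch cache (e.g. char reps)
  .ad$tape <- tp
  invisible(tp)
}

ad_tape_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_node <- function(val, back = NULL, pid = NA_character_) {
  tp <- .ad$tape
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$back <- back
  nd$pid <- pid
  nd$prev <- tp$last
  tp$last <- nd
  nd
}

ad_const <- function(val) ad_node(val)

# One node per parameter per tape; grads accumulate across the batch.
ad_par <- function(params, name) {
  tp <- .ad$tape
  nd <- tp$pcache[[name]]
  if (is.null(nd)) {
    nd <- ad_node(params[[name]], pid = name)
    assign(name, nd, envir = tp$pcache)
  }
  nd
}

ad_acc <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Backward pass from a scalar loss node; returns named list of parameter
# gradients (only parameters actually touched by the tape appear).
ad_backward <- function(loss) {
  tp <- .ad$tape
  loss$grad <- matrix(1, 1L, 1L)
  nd <- tp$last
  while (!is.null(nd)) {
    if (!is.null(nd$grad) && !is.null(nd$back)) nd$back(nd)
    nd <- nd$prev
  }
  grads <- list()
  for (name in ls(tp$pcache)) {
    pn <- tp$pcache[[name]]
    if (!is.null(pn$grad)) grads[[name]] <- pn$grad
  }
  grads
}

## ---- primitive operations ------------------------------------------------

ad_mm <- function(a, b) {
  ad_node(a$val %*% b$val, back = function(nd) {
    g <- nd$grad
    ad_acc(a, g %*% t(b$val))
    ad_acc(b, crossprod(a$val, g))
  })
}

ad_add <- function(a, b) {
  ad_node(a$val + b$val, back = function(nd) {
    ad_acc(a, nd$grad)
    ad_acc(b, nd$grad)
  })
}

# A (n x k) + row vector b (1 x k), recycled down the rows.
ad_badd_row <- function(a, b) {
  n <- nrow(a$val)
  ad_node(a$val + matrix(b$val, n, ncol(a$val), byrow = TRUE), back = function(nd) {
    ad_acc(a, nd$grad)
    ad_acc(b, matrix(colSums(nd$grad), 1L))
  })
}

# A (n x k) + column vector b (n x 1), recycled across the columns.
ad_badd_col <- function(a, b) {
  ad_node(a$val + as.vector(b$val), back = function(nd) {
    ad_acc(a, nd$grad)
    ad_acc(b, matrix(rowSums(nd$grad), ncol = 1L))
  })
}

ad_mul <- function(a, b) {
  ad_node(a$val * b$val, back = function(nd) {
    ad_acc(a, nd$grad * b$val)
    ad_acc(b, nd$grad * a$val)
  })
}

ad_scale <- function(a, s) {
  ad_node(a$val * s, back = function(nd) ad_acc(a, nd$grad * s))
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_sq <- function(a) {
  ad_node(a$val * a$val, back = function(nd) ad_acc(a, 2 * nd$grad * a$val))
}

ad_tanh <- function(a) {
  v <- tanh(a$val)
  ad_node(v, back = function(nd) ad_acc(a, nd$grad * (1 - nd$val * nd$val)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$val))
  ad_node(v, back = function(nd) ad_acc(a, nd$grad * nd$val * (1 - nd$val)))
}

ad_rows <- function(a, idx) {
  ad_node(a$val[idx, , drop = FALSE], back = function(nd) {
    g <- nd$grad
    if (is.null(a$grad)) a$grad <- matrix(0, nrow(a$val), ncol(a$val))
    rs <- rowsum(g, group = idx, reorder = TRUE)
    u <- as.integer(rownames(rs))
    a$grad[u, ] <- a$grad[u, , drop = FALSE] + rs
  })
}

ad_cols <- function(a, idx) {
  ad_node(a$val[, idx, drop = FALSE], back = function(nd) {
    if (is.null(a$grad)) a$grad <- matrix(0, nrow(a$val), ncol(a$val))
    a$grad[, idx] <- a$grad[, idx, drop = FALSE] + nd$grad
  })
}

ad_t <- function(a) {
  ad_node(t(a$val), back = function(nd) ad_acc(a, t(nd$grad)))
}

ad_vcat <- function(nodes) {
  vals <- lapply(nodes, function(x) x$val)
  nr <- vapply(vals, nrow, 0L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ad_node(do.call(rbind, vals), back = function(nd) {
    g <- nd$grad
    for (i in seq_along(nodes)) {
      ad_acc(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

ad_hcat <- function(nodes) {
  vals <- lapply(nodes, function(x) x$val)
  nc <- vapply(vals, ncol, 0L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  ad_node(do.call(cbind, vals), back = function(nd) {
    g <- nd$grad
    for (i in seq_along(nodes)) {
      ad_acc(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_sum <- function(a) {
  ad_node(matrix(sum(a$val), 1L, 1L), back = function(nd) {
    ad_acc(a, matrix(nd$grad[1L], nrow(a$val), ncol(a$val)))
  })
}

ad_entry <- function(a, i, j) {
  ad_node(matrix(a$val[i, j], 1L, 1L), back = function(nd) {
    if (is.null(a$grad)) a$grad <- matrix(0, nrow(a$val), ncol(a$val))
    a$grad[i, j] <- a$grad[i, j] + nd$grad[1L]
  })
}

# Column-wise max over rows (1 x k); gradient routes to the first argmax row.
ad_colmax <- function(a) {
  v <- a$val
  arg <- max.col(t(v), ties.method = "first")
  out <- v[cbind(arg, seq_len(ncol(v)))]
  ad_node(matrix(out, 1L), back = function(nd) {
    if (is.null(a$grad)) a$grad <- matrix(0, nrow(v), ncol(v))
    ij <- cbind(arg, seq_len(ncol(v)))
    a$grad[ij] <- a$grad[ij] + as.vector(nd$grad)
  })
}

# Column-wise log-sum-exp over rows (1 x k).
ad_collse <- function(a) {
  v <- a$val
  mx <- v[cbind(max.col(t(v), ties.method = "first"), seq_len(ncol(v)))]
  out <- mx + log(colSums(exp(sweep(v, 2L, mx, "-"))))
  ad_node(matrix(out, 1L), back = function(nd) {
    w <- exp(sweep(v, 2L, out, "-")) # softmax per column
    ad_acc(a, sweep(w, 2L, as.vector(nd$grad), "*"))
  })
}

# Log-sum-exp of every entry of a (scalar).
ad_lse <- function(a) {
  v <- a$val
  mx <- max(v)
  out <- mx + log(sum(exp(v - mx)))
  ad_node(matrix(out, 1L, 1L), back = function(nd) {
    ad_acc(a, nd$grad[1L] * exp(v - out))
  })
}

# Softmax over all entries of a (same shape as a).
ad_softmax <- function(a) {
  v <- a$val
  e <- exp(v - max(v))
  w <- e / sum(e)
  ad_node(w, back = function(nd) {
    g <- nd$grad
    ad_acc(a, (g - sum(g * nd$val)) * nd$val)
  })
}

# Inverted dropout; draws its mask from the current RNG stream.
ad_dropout <- function(a, p) {
  if (p <= 0) return(a)
  keep <- (stats::runif(length(a$val)) >= p) / (1 - p)
  m <- matrix(keep, nrow(a$val), ncol(a$val))
  ad_node(a$val * m, back = function(nd) ad_acc(a, nd$grad * m))
}

ad_zeros <- function(n, k) ad_const(matrix(0, n, k))

# Sum of selected entries a[ij] where ij is a 2-column index matrix (scalar).
ad_pick <- function(a, ij) {
  ad_node(matrix(sum(a$val[ij]), 1L, 1L), back = function(nd) {
    if (is.null(a$grad)) a$grad <- matrix(0, nrow(a$val), ncol(a$val))
    g <- nd$grad[1L]
    for (r in seq_len(nrow(ij))) {
      a$grad[ij[r, 1L], ij[r, 2L]] <- a$grad[ij[r, 1L], ij[r, 2L]] + g
    }
  })
}
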