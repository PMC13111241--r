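#' @title Tape-based reverse-mode automatic differentiation
#'
#' @description
#' A compact reverse-mode automatic differentiation engine over dense numeric
#' matrices. Every differentiable computation in the package (the four physics
#' constraint losses, the rigid-body chain and the neural network) is expressed
#' in these primitives, so analytic gradients are available end-to-end; the
#' test suite verifies them against central finite differences that never touch
#' the tape.
#'
#' Nodes live on a tape in topological order. Each node stores its value
#' (a matrix; scalars are 1x1), an accumulated gradient, and a backward
#' closure that scatters its output gradient to its parents. Broadcasting
#' follows the usual outer-product rules for shapes (n,d), (1,d), (n,1), (1,1),
#' with gradients reduced by summation over broadcast axes.
#'
#' All functions here are internal (`ad_*`); user-facing modules wrap them.
#'
#' @name autodiff
#' @keywords internal
NULL

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = NULL, backward = NULL) {
  # `parents` is documentation only: backward closures capture what they
  # need, so nodes stay lean (value, grad, backward)
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = if (length(x) == 1L) 1L else length(x))
}

#' Create a leaf node (constant or parameter; both may receive gradients)
#' @noRd
ad_leaf <- function(tape, x) ad_node(tape, as_mat(x))

ad_value <- function(nd) nd$value

## accumulate gradient g into node nd, reducing over broadcast axes
ad_acc <- function(nd, g) {
  dv <- dim(nd$value); dg <- dim(g)
  if (dg[1L] != dv[1L]) g <- matrix(colSums(g), 1L, dg[2L])
  if (dg[2L] != dv[2L]) g <- matrix(rowSums(g), nrow(g), 1L)
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

## broadcast matrix x to shape (n, d)
bcast <- function(x, n, d) {
  if (nrow(x) == n && ncol(x) == d) return(x)
  if (nrow(x) == 1L && ncol(x) == d) return(matrix(x, n, d, byrow = TRUE))
  if (nrow(x) == n && ncol(x) == 1L) return(matrix(x, n, d))
  if (nrow(x) == 1L && ncol(x) == 1L) return(matrix(x[1L], n, d))
  stop("incompatible shapes for broadcast: (", nrow(x), ",", ncol(x),
       ") vs (", n, ",", d, ")")
}

## resolve a broadcast pair once; fast path when shapes already agree
bpair <- function(a, b) {
  va <- a$value; vb <- b$value
  da <- dim(va); db <- dim(vb)
  if (da[1L] == db[1L] && da[2L] == db[2L]) return(list(va, vb))
  n <- max(da[1L], db[1L]); d <- max(da[2L], db[2L])
  list(bcast(va, n, d), bcast(vb, n, d))
}

ad_add <- function(tape, a, b) {
  v <- bpair(a, b)
  ad_node(tape, v[[1L]] + v[[2L]], NULL, function(nd) {
    ad_acc(a, nd$grad); ad_acc(b, nd$grad)
  })
}

ad_sub <- function(tape, a, b) {
  v <- bpair(a, b)
  ad_node(tape, v[[1L]] - v[[2L]], NULL, function(nd) {
    ad_acc(a, nd$grad); ad_acc(b, -nd$grad)
  })
}

ad_mul <- function(tape, a, b) {
  v <- bpair(a, b)
  va <- v[[1L]]; vb <- v[[2L]]
  ad_node(tape, va * vb, NULL, function(nd) {
    ad_acc(a, nd$grad * vb); ad_acc(b, nd$grad * va)
  })
}

ad_div <- function(tape, a, b) {
  v <- bpair(a, b)
  va <- v[[1L]]; vb <- v[[2L]]
  ad_node(tape, va / vb, NULL, function(nd) {
    ad_acc(a, nd$grad / vb); ad_acc(b, -nd$grad * va / (vb * vb))
  })
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(nd) ad_acc(a, nd$grad * k))
}

ad_addc <- function(tape, a, k) {
  ad_node(tape, a$value + k, list(a), function(nd) ad_acc(a, nd$grad))
}

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    ad_acc(a, nd$grad %*% t(b$value))
    ad_acc(b, t(a$value) %*% nd$grad)
  })
}

ad_t <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(nd) ad_acc(a, t(nd$grad)))
}

ad_unary <- function(tape, a, fval, fgrad) {
  v <- fval(a$value)
  ad_node(tape, v, list(a), function(nd) ad_acc(a, nd$grad * fgrad(a$value, v)))
}

ad_exp   <- function(tape, a) ad_unary(tape, a, exp, function(x, v) v)
ad_log   <- function(tape, a) ad_unary(tape, a, log, function(x, v) 1 / x)
ad_sin   <- function(tape, a) ad_unary(tape, a, sin, function(x, v) cos(x))
ad_cos   <- function(tape, a) ad_unary(tape, a, cos, function(x, v) -sin(x))
ad_tanh  <- function(tape, a) ad_unary(tape, a, tanh, function(x, v) 1 - v * v)
ad_relu  <- function(tape, a) ad_unary(tape, a, function(x) pmax(x, 0),
                                       function(x, v) (x > 0) + 0)
ad_square <- function(tape, a) ad_unary(tape, a, function(x) x * x,
                                        function(x, v) 2 * x)
ad_sqrt  <- function(tape, a) ad_unary(tape, a, sqrt, function(x, v) 0.5 / v)
ad_sigmoid <- function(tape, a) ad_unary(tape, a, function(x) 1 / (1 + exp(-x)),
                                         function(x, v) v * (1 - v))

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(nd) {
    ad_acc(a, matrix(nd$grad[1L], nrow(a$value), ncol(a$value)))
  })
}

ad_mean <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1L, 1L), list(a), function(nd) {
    ad_acc(a, matrix(nd$grad[1L] / n, nrow(a$value), ncol(a$value)))
  })
}

ad_sumsq <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value^2), 1L, 1L), list(a), function(nd) {
    ad_acc(a, 2 * nd$grad[1L] * a$value)
  })
}

## column means -> 1 x d (temporal average pooling)
ad_colmeans <- function(tape, a) {
  n <- nrow(a$value)
  ad_node(tape, matrix(colMeans(a$value), 1L), list(a), function(nd) {
    ad_acc(a, matrix(nd$grad, nrow(a$value), ncol(a$value), byrow = TRUE) / n)
  })
}

## column-wise max -> 1 x d (temporal max pooling); subgradient to argmax rows
ad_colmax <- function(tape, a) {
  idx <- max.col(t(a$value), ties.method = "first")
  v <- a$value[cbind(idx, seq_len(ncol(a$value)))]
  ad_node(tape, matrix(v, 1L), list(a), function(nd) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[cbind(idx, seq_len(ncol(g)))] <- nd$grad
    ad_acc(a, g)
  })
}

## row-wise softmax
ad_softmax_rows <- function(tape, a) {
  x <- a$value
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  s <- e / rowSums(e)
  ad_node(tape, s, list(a), function(nd) {
    g <- nd$grad
    dot <- rowSums(g * s)
    ad_acc(a, (g - dot) * s)
  })
}

## select / permute rows (also implements cyclic shifts); idx may repeat
ad_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    agg <- rowsum(nd$grad, group = idx)
    g[as.integer(rownames(agg)), ] <- agg
    ad_acc(a, g)
  })
}

## shift rows by s with zero padding: s > 0 shifts down (causal delay),
## s < 0 shifts up (lookahead); used by the kernel-3 convolutions
ad_shift <- function(tape, a, s) {
  n <- nrow(a$value)
  if (s == 0L) return(a)
  if (s > 0L) {
    v <- rbind(matrix(0, s, ncol(a$value)),
               a$value[seq_len(n - s), , drop = FALSE])
    ad_node(tape, v, list(a), function(nd) {
      g <- matrix(0, n, ncol(a$value))
      g[seq_len(n - s), ] <- nd$grad[(s + 1L):n, , drop = FALSE]
      ad_acc(a, g)
    })
  } else {
    k <- -s
    v <- rbind(a$value[(k + 1L):n, , drop = FALSE], matrix(0, k, ncol(a$value)))
    ad_node(tape, v, list(a), function(nd) {
      g <- matrix(0, n, ncol(a$value))
      g[(k + 1L):n, ] <- nd$grad[seq_len(n - k), , drop = FALSE]
      ad_acc(a, g)
    })
  }
}

## fused affine map x %*% W + b (b broadcast over rows)
ad_affine <- function(tape, x, W, b) {
  v <- x$value %*% W$value
  v <- v + matrix(b$value, nrow(v), ncol(v), byrow = TRUE)
  ad_node(tape, v, list(x, W, b), function(nd) {
    ad_acc(x, nd$grad %*% t(W$value))
    ad_acc(W, t(x$value) %*% nd$grad)
    ad_acc(b, matrix(colSums(nd$grad), 1L))
  })
}

## fused dilated kernel-3 convolution along rows (causal, zero-padded):
## y[t] = x[t] W0 + x[t-d] W1 + x[t-2d] W2 + b
ad_conv3 <- function(tape, x, W0, W1, W2, b, dil) {
  xm <- x$value
  n <- nrow(xm)
  shf <- function(m, s) {
    if (s >= n) return(m * 0)
    rbind(matrix(0, s, ncol(m)), m[seq_len(n - s), , drop = FALSE])
  }
  x1 <- shf(xm, dil); x2 <- shf(xm, 2L * dil)
  v <- xm %*% W0$value + x1 %*% W1$value + x2 %*% W2$value
  v <- v + matrix(b$value, n, ncol(v), byrow = TRUE)
  ad_node(tape, v, list(x, W0, W1, W2, b), function(nd) {
    g <- nd$grad
    unshf <- function(m, s) {
      if (s >= n) return(m * 0)
      rbind(m[(s + 1L):n, , drop = FALSE], matrix(0, s, ncol(m)))
    }
    ad_acc(x, g %*% t(W0$value) + unshf(g %*% t(W1$value), dil) +
             unshf(g %*% t(W2$value), 2L * dil))
    ad_acc(W0, t(xm) %*% g)
    ad_acc(W1, t(x1) %*% g)
    ad_acc(W2, t(x2) %*% g)
    ad_acc(b, matrix(colSums(g), 1L))
  })
}

## stack a list of nodes vertically (row-wise)
ad_vstack <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$value)
  rows <- vapply(vals, nrow, 0L)
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  ad_node(tape, do.call(rbind, vals), nodes, function(nd) {
    for (k in seq_along(nodes))
      ad_acc(nodes[[k]], nd$grad[starts[k]:ends[k], , drop = FALSE])
  })
}

ad_cbind <- function(tape, a, b) {
  da <- ncol(a$value)
  ad_node(tape, cbind(a$value, b$value), list(a, b), function(nd) {
    ad_acc(a, nd$grad[, seq_len(da), drop = FALSE])
    ad_acc(b, nd$grad[, (da + 1L):ncol(nd$grad), drop = FALSE])
  })
}

ad_cols <- function(tape, a, j) {
  ad_node(tape, a$value[, j, drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[, j] <- g[, j] + nd$grad
    ad_acc(a, g)
  })
}

## row-wise layer normalisation with learnable gain/bias (1 x d each)
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  g <- bcast(gamma$value, nrow(x), d)
  out <- xhat * g + bcast(beta$value, nrow(x), d)
  ad_node(tape, out, list(a, gamma, beta), function(nd) {
    go <- nd$grad
    ad_acc(gamma, matrix(colSums(go * xhat), 1L))
    ad_acc(beta, matrix(colSums(go), 1L))
    gx <- go * g                         # grad wrt xhat
    t1 <- rowSums(gx) / d                # recycles down columns
    t2 <- rowSums(gx * xhat) / d
    ad_acc(a, inv * (gx - t1 - xhat * t2))
  })
}

## elementwise dropout with a fixed 0/1 mask (mask supplied by caller)
ad_dropout <- function(tape, a, mask, rate) {
  k <- 1 / (1 - rate)
  ad_node(tape, a$value * mask * k, list(a), function(nd) {
    ad_acc(a, nd$grad * mask * k)
  })
}

#' Run reverse pass from a scalar loss node
#' @noRd
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  nodes <- tape$nodes
  n <- tape$n
  for (i in seq_len(n)) nodes[[i]]$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (i in n:1L) {
    nd <- nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

#' Central finite-difference gradient of a scalar function of one matrix input.
#' Used by the test-suite and acceptance checks as the tape-independent oracle.
#' @param f function taking a matrix, returning a scalar
#' @param x matrix input
#' @param eps step size
#' @noRd
fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

## relative discrepancy between analytic and finite-difference gradients
grad_rel_err <- function(ga, gn) {
  den <- max(abs(gn), abs(ga), 1e-8)
  max(abs(ga - gn)) / den
}
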