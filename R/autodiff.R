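# Minimal reverse-mode automatic differentiation over whole-tensor ops.
# A "node" is an environment holding a value, an optional gradient, its
# parent nodes and a backward closure; nodes are appended to a tape in
# creation order, so walking the tape in reverse is a valid topological
# order for backpropagation.  Ops accept either plain arrays (inference
# path, no tape) or nodes (training path).

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (ag_is_node(x)) x$value else x

ag_node <- function(tape, value, parents = list(), bwd = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  class(nd) <- "ag_node"
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      length(tape$nodes) <- 2L * length(tape$nodes)
    tape$nodes[[tape$n]] <- nd
    nd$tape <- tape
  }
  nd
}

ag_leaf <- function(tape, value) ag_node(tape, value)

# Tape of the first node argument; ops require all node inputs share it.
ag_tape_of <- function(...) {
  for (x in list(...)) if (ag_is_node(x)) return(x$tape)
  NULL
}

ag_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the whole tape.  Once a
# node's backward has run, its value, gradient and backward closure (which
# captures the forward intermediates) are released so peak memory stays
# close to a single forward pass; leaf nodes keep their gradients.
ag_backward <- function(loss) {
  tape <- loss$tape
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$bwd)) next
    if (!is.null(nd$grad)) {
      gs <- nd$bwd(nd$grad)
      for (j in seq_along(nd$parents)) {
        if (!is.null(gs[[j]])) ag_accum(nd$parents[[j]], gs[[j]])
      }
    }
    nd$bwd <- NULL
    nd$value <- NULL
    nd$grad <- NULL
    nd$parents <- NULL
  }
  invisible(NULL)
}

# ---- ops ----

# `b = NULL` gives a bias-free convolution (the norm for convolutions
# feeding batch-norm, where a bias would be cancelled by mean subtraction).
ag_conv <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  bv <- if (is.null(b)) numeric(0) else ag_value(b)
  y <- .conv2d_fwd(ag_value(x), ag_value(w), bv, stride, pad, dil)
  tape <- if (is.null(b)) ag_tape_of(x, w) else ag_tape_of(x, w, b)
  if (is.null(tape)) return(y)
  xv <- ag_value(x); wv <- ag_value(w)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(tape, y, parents, function(g) {
    r <- .conv2d_bwd(xv, wv, g, stride, pad, dil, ag_is_node(x),
                     !is.null(b) && ag_is_node(b))
    gs <- list(if (ag_is_node(x)) r$gx else NULL, r$gw)
    if (!is.null(b)) gs <- c(gs, list(r$gb))
    gs
  })
}

ag_relu <- function(x) {
  y <- .relu_fwd(ag_value(x))
  if (!ag_is_node(x)) return(y)
  ag_node(x$tape, y, list(x), function(g) list(.relu_bwd(g, y)))
}

ag_add <- function(x, y) {
  v <- ag_value(x) + ag_value(y)
  tape <- ag_tape_of(x, y)
  if (is.null(tape)) return(v)
  ag_node(tape, v, list(x, y), function(g) {
    list(if (ag_is_node(x)) g else NULL, if (ag_is_node(y)) g else NULL)
  })
}

# Concatenate along the channel axis.
ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_value)
  ch <- vapply(vals, function(v) dim(v)[3L], integer(1))
  v <- .concat_c(vals)
  ends <- cumsum(ch)
  starts <- ends - ch
  tape <- do.call(ag_tape_of, xs)
  if (is.null(tape)) return(v)
  ag_node(tape, v, xs, function(g) {
    lapply(seq_along(xs), function(i) {
      if (!ag_is_node(xs[[i]])) return(NULL)
      .slice_c(g, starts[i], ends[i])
    })
  })
}

ag_bilinear <- function(x, Ho, Wo) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- .bilinear_fwd(xv, Ho, Wo)
  if (!ag_is_node(x)) return(y)
  ag_node(x$tape, y, list(x), function(g) list(.bilinear_bwd(g, d[1L], d[2L])))
}

ag_adapool <- function(x, bh, bw = bh) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- .adapool_fwd(xv, bh, bw)
  if (!ag_is_node(x)) return(y)
  ag_node(x$tape, y, list(x), function(g) list(.adapool_bwd(g, d[1L], d[2L])))
}

# Global average pooling: (H, W, C, N) -> (C, N).
ag_gap <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  v <- matrix(.colMeans(xv, d[1L] * d[2L], d[3L] * d[4L]), d[3L], d[4L])
  if (!ag_is_node(x)) return(v)
  ag_node(x$tape, v, list(x), function(g) {
    list(array(rep(as.vector(g), each = d[1L] * d[2L]), d) / (d[1L] * d[2L]))
  })
}

# Fully connected layer on (Cin, N) feature columns.
ag_dense <- function(x, w, b) {
  xv <- ag_value(x); wv <- ag_value(w)
  v <- wv %*% xv + ag_value(b)
  tape <- ag_tape_of(x, w, b)
  if (is.null(tape)) return(v)
  ag_node(tape, v, list(x, w, b), function(g) {
    list(if (ag_is_node(x)) crossprod(wv, g) else NULL,
         tcrossprod(g, xv), rowSums(g))
  })
}

# Batch normalisation over (H, W, N) per channel, with an optional fused
# ReLU.  `stats` is an environment holding running_mean / running_var,
# updated in train mode (side effect).  The normalised intermediate is not
# stored; the backward kernel recomputes it from the input.
ag_bn_act <- function(x, gamma, beta, stats, train, relu,
                      momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(x)
  d <- dim(xv)
  m <- d[1L] * d[2L] * d[4L]
  if (train) {
    s <- .ch_sums2(xv, xv)
    mu <- s$sa / m
    va <- s$sab / m - mu * mu
    va[va < 0] <- 0
    stats$running_mean <- (1 - momentum) * stats$running_mean + momentum * mu
    stats$running_var <- (1 - momentum) * stats$running_var +
      momentum * va * m / max(m - 1, 1)
  } else {
    mu <- stats$running_mean
    va <- stats$running_var
  }
  istd <- 1 / sqrt(va + eps)
  gv <- ag_value(gamma)
  y <- .bn_act_fwd(xv, gv, ag_value(beta), mu, istd, relu)
  tape <- ag_tape_of(x, gamma, beta)
  if (is.null(tape)) return(y)
  ag_node(tape, y, list(x, gamma, beta), function(g) {
    r <- .bn_act_bwd(g, xv, if (relu) y else NULL, gv, mu, istd, train)
    list(if (ag_is_node(x)) r$gx else NULL, r$dgamma, r$dbeta)
  })
}

ag_bn <- function(x, gamma, beta, stats, train, momentum = 0.1, eps = 1e-5) {
  ag_bn_act(x, gamma, beta, stats, train, relu = FALSE, momentum, eps)
}

# Fused batch-norm + ReLU (the standard conv-bn-relu tail); semantics
# identical to ag_relu(ag_bn(...)).
ag_bn_relu <- function(x, gamma, beta, stats, train, momentum = 0.1,
                       eps = 1e-5) {
  ag_bn_act(x, gamma, beta, stats, train, relu = TRUE, momentum, eps)
}

# Mean binary cross-entropy of per-pixel logits against a {0,1} target,
# numerically stable: max(z,0) - z*t + log1p(exp(-|z|)).
ag_bce_logits <- function(z, target) {
  zv <- ag_value(z)
  n <- length(zv)
  v <- sum(pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))) / n
  if (!ag_is_node(z)) return(v)
  ag_node(z$tape, v, list(z), function(g) {
    list(g * (1 / (1 + exp(-zv)) - target) / n)
  })
}

# Mean softmax cross-entropy of (C, N) logits against 0-based class labels.
ag_softmax_ce <- function(z, labels) {
  zv <- ag_value(z)
  n <- ncol(zv)
  zs <- sweep(zv, 2L, apply(zv, 2L, max))
  p <- exp(zs)
  p <- sweep(p, 2L, colSums(p), "/")
  idx <- cbind(labels + 1L, seq_len(n))
  v <- -sum(log(pmax(p[idx], 1e-300))) / n
  if (!ag_is_node(z)) return(v)
  ag_node(z$tape, v, list(z), function(g) {
    d <- p
    d[idx] <- d[idx] - 1
    list(g * d / n)
  })
}

# a + lambda * b for scalar loss nodes.
ag_axpy <- function(a, b, lambda) {
  v <- ag_value(a) + lambda * ag_value(b)
  tape <- ag_tape_of(a, b)
  if (is.null(tape)) return(v)
  ag_node(tape, v, list(a, b), function(g) {
    list(if (ag_is_node(a)) g else NULL,
         if (ag_is_node(b)) g * lambda else NULL)
  })
}
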