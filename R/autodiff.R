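# Minimal reverse-mode automatic differentiation over dense arrays.
#
# The network graph is rebuilt for every forward pass (define-by-run): each
# operation appends a node carrying its value and a backward closure to a
# tape, and `ad_backward()` replays the tape in reverse. Nodes are
# environments so gradient accumulation mutates in place. Heavy kernels
# (3D convolution, trilinear resize) live in src/kernels.cpp; everything
# else is vectorised base R. Single-threaded and therefore bit-reproducible.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$k <- 0L
  tp
}

ad_node <- function(tape, value, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$bw <- bw
  if (!is.null(tape)) {
    k <- tape$k + 1L
    if (k > length(tape$nodes)) length(tape$nodes) <- 2L * k
    tape$nodes[[k]] <- nd
    tape$k <- k
  }
  nd
}

# Leaf (parameter or input) node: participates in gradient accumulation.
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Run backpropagation from a scalar loss node.
ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (k in seq(tape$k, 1L)) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$bw) && !is.null(nd$grad)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# ---- array ops -------------------------------------------------------------

ad_conv3 <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  y <- conv3_fwd(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  ad_node(tape, y, bw = function(g) {
    gr <- conv3_bwd(x$value, w$value, g, as.integer(stride), as.integer(pad))
    ad_acc(x, gr$gx)
    ad_acc(w, gr$gw)
    ad_acc(b, gr$gb)
  })
}

# Instance normalisation: per channel, statistics over the spatial volume.
# A single-voxel spatial grid (the deepest level of a 16^3 input) has no
# usable statistics; normalisation degenerates to exactly 0 there and kills
# the layer, so we fall back to the pure affine transform.
ad_instnorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  n <- prod(d[1:3])
  C <- d[4]
  if (n == 1L) {
    y <- x$value * array(gamma$value, d) + array(beta$value, d)
    return(ad_node(tape, y, bw = function(g) {
      ad_acc(x, g * array(gamma$value, d))
      ad_acc(gamma, as.vector(g * x$value))
      ad_acc(beta, as.vector(g))
    }))
  }
  xm <- matrix(x$value, n, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  sig <- sqrt(colMeans(xc * xc) + eps)
  xhat <- sweep(xc, 2L, sig, "/")
  ym <- sweep(xhat, 2L, gamma$value, "*")
  ym <- sweep(ym, 2L, beta$value, "+")
  y <- array(ym, d)
  ad_node(tape, y, bw = function(g) {
    gm <- matrix(g, n, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gh <- sweep(gm, 2L, gamma$value, "*")
    m1 <- colMeans(gh)
    m2 <- colMeans(gh * xhat)
    dx <- sweep(gh, 2L, m1) - sweep(xhat, 2L, m2, "*")
    dx <- sweep(dx, 2L, sig, "/")
    ad_acc(x, array(dx, d))
    ad_acc(gamma, dgamma)
    ad_acc(beta, dbeta)
  })
}

ad_relu <- function(tape, x) {
  y <- x$value
  y[y < 0] <- 0
  ad_node(tape, y, bw = function(g) ad_acc(x, g * (x$value > 0)))
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, bw = function(g) ad_acc(x, g * s * (1 - s)))
}

ad_add <- function(tape, x, y) {
  ad_node(tape, x$value + y$value, bw = function(g) {
    ad_acc(x, g)
    ad_acc(y, g)
  })
}

ad_scale <- function(tape, x, a) {
  ad_node(tape, x$value * a, bw = function(g) ad_acc(x, g * a))
}

ad_add_const <- function(tape, x, cst) {
  ad_node(tape, x$value + cst, bw = function(g) ad_acc(x, g))
}

ad_mul <- function(tape, x, y) {
  ad_node(tape, x$value * y$value, bw = function(g) {
    ad_acc(x, g * y$value)
    ad_acc(y, g * x$value)
  })
}

# Multiply a (H,W,L,C) feature block by a single-channel (H,W,L,1) weight,
# broadcasting the weight across feature channels.
ad_mul_bcast <- function(tape, x, r) {
  d <- dim(x$value)
  rv <- as.vector(r$value)
  y <- array(as.vector(x$value) * rv, d) # recycles over channels
  ad_node(tape, y, bw = function(g) {
    ad_acc(x, array(as.vector(g) * rv, d))
    n <- prod(d[1:3])
    gr <- rowSums(matrix(as.vector(g) * as.vector(x$value), n, d[4]))
    ad_acc(r, array(gr, c(d[1:3], 1L)))
  })
}

ad_concat_ch <- function(tape, x, y) {
  dx <- dim(x$value)
  dy <- dim(y$value)
  d <- c(dx[1:3], dx[4] + dy[4])
  ad_node(tape, array(c(x$value, y$value), d), bw = function(g) {
    nx <- prod(dx)
    ad_acc(x, array(g[seq_len(nx)], dx))
    ad_acc(y, array(g[-seq_len(nx)], dy))
  })
}

# Trilinear resize (align_corners = FALSE) to a new spatial shape.
ad_resize <- function(tape, x, out_shape) {
  d <- dim(x$value)
  if (all(d[1:3] == out_shape)) return(x)
  y <- resize3(x$value, out_shape[1], out_shape[2], out_shape[3])
  ad_node(tape, y, bw = function(g) {
    ad_acc(x, resize3_bwd(g, d[1], d[2], d[3]))
  })
}

# Mean over the channel axis: (H,W,L,C) -> (H,W,L,1).
ad_mean_ch <- function(tape, x) {
  d <- dim(x$value)
  n <- prod(d[1:3])
  y <- array(rowMeans(matrix(x$value, n, d[4])), c(d[1:3], 1L))
  ad_node(tape, y, bw = function(g) {
    ad_acc(x, array(rep(as.vector(g) / d[4], d[4]), d))
  })
}

# 1 - x, elementwise (the "reverse" operation).
ad_one_minus <- function(tape, x) {
  ad_node(tape, 1 - x$value, bw = function(g) ad_acc(x, -g))
}

# Weighted sum of scalar nodes: sum(coefs[i] * xs[[i]]).
ad_scalar_comb <- function(tape, xs, coefs) {
  v <- 0
  for (i in seq_along(xs)) v <- v + coefs[i] * xs[[i]]$value
  ad_node(tape, v, bw = function(g) {
    for (i in seq_along(xs)) ad_acc(xs[[i]], g * coefs[i])
  })
}

# Soft Dice loss against a fixed binary target, averaged over channels.
# L_c = 1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)
ad_dice_loss <- function(tape, pred, target, eps = 1) {
  d <- dim(pred$value)
  C <- d[4]
  n <- prod(d[1:3])
  pm <- matrix(pred$value, n, C)
  tm <- matrix(target, n, C)
  inter <- colSums(pm * tm)
  den <- colSums(pm) + colSums(tm)
  lc <- 1 - (2 * inter + eps) / (den + eps)
  ad_node(tape, mean(lc), bw = function(g) {
    gp <- matrix(0, n, C)
    for (cc in seq_len(C)) {
      gp[, cc] <- -(2 * tm[, cc] * (den[cc] + eps) - (2 * inter[cc] + eps)) /
        (den[cc] + eps)^2
    }
    ad_acc(pred, array(g * gp / C, d))
  })
}

# Weighted binary cross-entropy on logits against a fixed binary target with
# fixed per-voxel weights; per channel sum(w*bce)/sum(w), then channel mean.
ad_wbce <- function(tape, logit, target, w) {
  d <- dim(logit$value)
  C <- d[4]
  n <- prod(d[1:3])
  xm <- matrix(logit$value, n, C)
  tm <- matrix(target, n, C)
  wm <- matrix(w, n, C)
  bce <- pmax(xm, 0) - xm * tm + log1p(exp(-abs(xm)))
  wsum <- colSums(wm)
  lc <- colSums(wm * bce) / wsum
  ad_node(tape, mean(lc), bw = function(g) {
    sg <- 1 / (1 + exp(-xm))
    gx <- sweep(wm * (sg - tm), 2L, wsum, "/") / C
    ad_acc(logit, array(g * gx, d))
  })
}
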