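# Shared fixtures and independent scalar-loop oracles. Oracles deliberately
# avoid the package's vectorised/C++ code paths.

rand_grid <- function(shape, channels = NULL, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  d <- if (is.null(channels)) shape else c(shape, channels)
  array(rnorm(prod(d), 0, sd), d)
}

rand_mask <- function(shape, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(as.double(runif(prod(shape)) < p), shape)
}

small_phantom <- function(seed = 7L, ...) {
  generate_phantom(phantom_spec(seed = seed, ...))
}

tiny_net <- function(base_filters = 2L, n_pairs = 2L, seed = 5L, ...) {
  create_network(network_config(
    base_filters = base_filters, n_pairs = n_pairs, seed = seed, ...
  ))
}

# scalar-loop reverse attention: 1 - 1/(1+exp(-m)) elementwise
oracle_reverse_attention <- function(m) {
  out <- m
  for (i in seq_along(m)) out[i] <- 1 - 1 / (1 + exp(-m[i]))
  out
}

# scalar-loop soft dice (channel-last stack)
oracle_dice_loss <- function(p, t, eps = 1) {
  C <- dim(p)[4]
  tot <- 0
  for (cc in seq_len(C)) {
    inter <- den <- 0
    pc <- p[, , , cc]
    tc <- t[, , , cc]
    for (i in seq_along(pc)) {
      inter <- inter + pc[i] * tc[i]
      den <- den + pc[i] + tc[i]
    }
    tot <- tot + 1 - (2 * inter + eps) / (den + eps)
  }
  tot / C
}

# scalar-loop box-mean weight + weighted BCE
oracle_boxmean <- function(g, k) {
  d <- dim(g)
  r <- k %/% 2
  out <- g
  for (cc in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      for (y in seq_len(d[2])) {
        for (x in seq_len(d[1])) {
          xs <- max(1, x - r):min(d[1], x + r)
          ys <- max(1, y - r):min(d[2], y + r)
          zs <- max(1, z - r):min(d[3], z + r)
          out[x, y, z, cc] <- mean(g[xs, ys, zs, cc])
        }
      }
    }
  }
  out
}

oracle_weighted_bce <- function(x, t, lambda_w = 5, window = 3) {
  w <- 1 + lambda_w * abs(oracle_boxmean(t, window) - t)
  C <- dim(x)[4]
  tot <- 0
  for (cc in seq_len(C)) {
    num <- den <- 0
    xc <- x[, , , cc]
    tc <- t[, , , cc]
    wc <- w[, , , cc]
    for (i in seq_along(xc)) {
      bce <- max(xc[i], 0) - xc[i] * tc[i] + log1p(exp(-abs(xc[i])))
      num <- num + wc[i] * bce
      den <- den + wc[i]
    }
    tot <- tot + num / den
  }
  tot / C
}

# brute-force O(|S||P|) HD-percentile oracle
oracle_hd95 <- function(s, p, spacing = c(1, 1, 1), q = 0.95) {
  si <- which(s == 1, arr.ind = TRUE)
  pi <- which(p == 1, arr.ind = TRUE)
  si <- sweep(si, 2, spacing, "*")
  pi <- sweep(pi, 2, spacing, "*")
  dmat <- matrix(0, nrow(si), nrow(pi))
  for (a in seq_len(nrow(si))) {
    for (b in seq_len(nrow(pi))) {
      dmat[a, b] <- sqrt(sum((si[a, ] - pi[b, ])^2))
    }
  }
  d_sp <- apply(dmat, 1, min)
  d_ps <- apply(dmat, 2, min)
  max(
    quantile(d_sp, q, names = FALSE, type = 7),
    quantile(d_ps, q, names = FALSE, type = 7)
  )
}

# hierarchical_masks from a labels array without going through map_labels
masks_from_labels_oracle <- function(labels) {
  list(
    wt = array(as.integer(labels %in% c(1L, 2L, 4L)), dim(labels)),
    tc = array(as.integer(labels %in% c(1L, 4L)), dim(labels)),
    et = array(as.integer(labels == 4L), dim(labels))
  )
}
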