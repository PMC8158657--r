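ns <- asNamespace("coattseg")

test_that("encoder emits a five-level dyadic pyramid with doubling channels", {
  net <- tiny_net(base_filters = 4L)
  x <- rand_grid(c(32, 32, 32), 2, seed = 1)
  pyr <- encode_pair(net, x)
  expect_named(pyr, paste0("f", 1:5))
  for (k in 1:5) {
    expect_equal(dim(pyr[[k]])[1:3], rep(32L / 2L^(k - 1), 3))
    expect_equal(dim(pyr[[k]])[4], 4L * 2L^(k - 1))
  }
  expect_error(encode_pair(net, rand_grid(c(30, 30, 30), 2)), "divisible by 16")
})

test_that("both pairs share one encoder parameter set", {
  net <- tiny_net()
  x <- rand_grid(c(16, 16, 16), 2, seed = 2)
  y <- rand_grid(c(16, 16, 16), 2, seed = 3)
  # same instance, same input -> identical output; different input -> differs
  expect_identical(encode_pair(net, x), encode_pair(net, x))
  expect_false(isTRUE(all.equal(encode_pair(net, x)$f5, encode_pair(net, y)$f5)))
})

test_that("encoder gradients from the two branches add into shared parameters", {
  net <- tiny_net()
  cfg <- net$config
  shp <- c(16L, 16L, 16L)
  s1 <- rand_grid(shp, 2, seed = 4)
  s2 <- rand_grid(shp, 2, seed = 5)
  g <- array(as.double(rand_mask(c(shp, 3L), 0.3, seed = 6)), c(shp, 3L))
  w <- wbce_weights(g, 5)

  branch_grads <- function(stacks, keep) {
    tape <- ns$ad_tape()
    P <- ns$wrap_params(tape, net$params)
    terms <- list()
    for (i in seq_along(stacks)) {
      if (!keep[i]) next
      pyr <- ns$ng_encode(tape, P, ns$ad_leaf(tape, stacks[[i]]))
      dec <- ns$ng_partial_decode(tape, P, pyr[[3]], pyr[[4]], pyr[[5]])
      up <- ns$ad_resize(tape, dec$mg, shp)
      terms <- c(terms, list(ns$ad_wbce(tape, up, g, w)))
    }
    loss <- ns$ad_scalar_comb(tape, terms, rep(1, length(terms)))
    ns$ad_backward(tape, loss)
    lapply(P, function(nd) if (is.null(nd$grad)) 0 else nd$grad)
  }
  ga <- branch_grads(list(s1, s2), c(TRUE, FALSE))
  gb <- branch_grads(list(s1, s2), c(FALSE, TRUE))
  gab <- branch_grads(list(s1, s2), c(TRUE, TRUE))
  for (nm in grep("^enc", names(net$params), value = TRUE)) {
    expect_equal(gab[[nm]], ga[[nm]] + gb[[nm]], tolerance = 1e-10)
    expect_gt(max(abs(gab[[nm]])), 0) # gradient actually reaches the encoder
  }
})

test_that("partial decoder contracts: level-3 resolution, one logit map per region", {
  net <- tiny_net(base_filters = 4L)
  pyr <- encode_pair(net, rand_grid(c(32, 32, 32), 2, seed = 7))
  out <- partial_decode(net, pyr$f3, pyr$f4, pyr$f5)
  expect_equal(dim(out$m_g), c(8L, 8L, 8L, 3L))
  expect_equal(dim(out$f_dp)[1:3], c(8L, 8L, 8L))
  expect_error(partial_decode(net, pyr$f3, pyr$f3, pyr$f5), "dyadically")
})

test_that("partial decoder head propagates zeros up to its bias", {
  net <- tiny_net(base_filters = 2L)
  # zero input features with zeroed internal biases -> M_g constant per
  # region channel (only the head bias survives)
  for (nm in names(net$params)) {
    if (grepl("^pd_(red|agg).*_(b|be)$", nm)) net$params[[nm]] <- net$params[[nm]] * 0
  }
  net$params$pd_head_b <- c(0.1, -0.2, 0.3)
  z <- function(C, s) array(0, c(s, s, s, C))
  bf <- 2L
  out <- partial_decode(net, z(4L * bf, 8L), z(8L * bf, 4L), z(16L * bf, 2L))
  for (cc in 1:3) {
    expect_equal(
      as.vector(out$m_g[, , , cc]),
      rep(net$params$pd_head_b[cc], 8L^3),
      tolerance = 1e-12
    )
  }
})

test_that("reverse_attention matches the elementwise oracle and saturates", {
  expect_equal(reverse_attention(array(0, c(2, 2, 2))), array(0.5, c(2, 2, 2)))
  expect_lt(max(reverse_attention(array(20, c(2, 2, 2)))), 1e-8)
  expect_gt(min(reverse_attention(array(-20, c(2, 2, 2)))), 1 - 1e-8)
  set.seed(8)
  for (rep in 1:5) {
    m <- rand_grid(c(4, 4, 4), sd = 3)
    r <- reverse_attention(m)
    expect_lt(max(abs(r - oracle_reverse_attention(m))), 1e-6)
    expect_true(all(r > 0 & r < 1))
  }
  # monotonicity: increasing a logit strictly decreases its weight
  m <- rand_grid(c(3, 3, 3), seed = 9)
  m2 <- m
  m2[2, 2, 2] <- m2[2, 2, 2] + 0.5
  expect_lt(reverse_attention(m2)[2, 2, 2], reverse_attention(m)[2, 2, 2])
  expect_error(reverse_attention(array(NaN, c(2, 2, 2))), "non-finite")
})

test_that("co_attention_average is the elementwise mean", {
  r1 <- array(0.2, c(3, 3, 3))
  r2 <- array(0.6, c(3, 3, 3))
  expect_equal(co_attention_average(r1, r2), array(0.4, c(3, 3, 3)))
  expect_equal(co_attention_average(r1, r1), r1)
  set.seed(10)
  a <- array(runif(64), c(4, 4, 4))
  b <- array(runif(64), c(4, 4, 4))
  got <- co_attention_average(a, b)
  for (i in seq_along(a)) expect_lt(abs(got[i] - (a[i] + b[i]) / 2), 1e-7)
  expect_error(co_attention_average(a, array(0.5, c(2, 2, 2))), "shapes differ")
})

test_that("fuse_features gates features as f * R + 1", {
  net <- tiny_net(base_filters = 2L)
  C5 <- 2L * 16L
  f1 <- rand_grid(c(4, 4, 4), C5, seed = 11)
  f2 <- rand_grid(c(4, 4, 4), C5, seed = 12)

  out <- fuse_features(net, 5L, f1, f2, array(1, c(4, 4, 4)))
  expect_equal(out$attended[[1]], f1 + 1, tolerance = 1e-12)
  expect_equal(out$attended[[2]], f2 + 1, tolerance = 1e-12)

  out0 <- fuse_features(net, 5L, f1, f2, array(0, c(4, 4, 4)))
  expect_true(all(abs(out0$attended[[1]] - 1) < 1e-12))

  set.seed(13)
  r <- array(runif(64), c(4, 4, 4))
  out <- fuse_features(net, 5L, f1, f2, r)
  orc <- array(0, dim(f1))
  for (cc in seq_len(C5)) orc[, , , cc] <- f1[, , , cc] * r + 1
  expect_lt(max(abs(out$attended[[1]] - orc)), 1e-6)
  expect_equal(dim(out$m), c(4L, 4L, 4L, 3L))
  expect_equal(dim(out$fused)[4], C5)

  # region-channel attention maps are averaged before gating
  r3 <- array(runif(64 * 3), c(4, 4, 4, 3))
  out3 <- fuse_features(net, 5L, f1, f2, r3)
  ravg <- (r3[, , , 1] + r3[, , , 2] + r3[, , , 3]) / 3
  orc <- array(0, dim(f1))
  for (cc in seq_len(C5)) orc[, , , cc] <- f1[, , , cc] * ravg + 1
  expect_lt(max(abs(out3$attended[[1]] - orc)), 1e-6)
})

test_that("map_residual mode adds the previous map to the side-output logits", {
  net <- tiny_net(base_filters = 2L, residual_mode = "map_residual")
  netl <- tiny_net(base_filters = 2L) # same seed -> same params
  C5 <- 32L
  f1 <- rand_grid(c(4, 4, 4), C5, seed = 14)
  f2 <- rand_grid(c(4, 4, 4), C5, seed = 15)
  r <- array(0.5, c(4, 4, 4))
  prev <- rand_grid(c(4, 4, 4), 3, seed = 16)
  expect_error(fuse_features(net, 5L, f1, f2, r), "prev_map is required")
  out <- fuse_features(net, 5L, f1, f2, r, prev_map = prev)
  # attended features drop the +1 in this mode
  expect_lt(max(abs(out$attended[[1]] - (f1 * 0.5))), 1e-12)
  # same computation in literal mode, gated on f*0.5+1 instead
  outl <- fuse_features(netl, 5L, f1, f2, r, prev_map = prev)
  expect_false(isTRUE(all.equal(out$m, outl$m)))
})

test_that("forward pass contracts: shape, range, determinism", {
  ph <- small_phantom(seed = 41L)
  st <- normalize_study(ph$study)
  net <- tiny_net(base_filters = 4L)
  t0 <- proc.time()
  out <- forward_segment(net, st)
  elapsed <- (proc.time() - t0)[3]
  expect_equal(dim(out$prob), c(32L, 32L, 32L, 3L))
  expect_true(all(out$prob > 0 & out$prob < 1))
  expect_length(out$global_maps, 2L)
  expect_equal(dim(out$side_maps$m5), c(2L, 2L, 2L, 3L))
  expect_equal(dim(out$side_maps$m4), c(4L, 4L, 4L, 3L))
  expect_equal(dim(out$side_maps$m3), c(8L, 8L, 8L, 3L))
  out2 <- forward_segment(net, st)
  expect_identical(out$prob, out2$prob)
  expect_lt(elapsed, 5)
})

test_that("pair order is irrelevant under weight-symmetric fusing", {
  # make each fusing mix treat the two concatenated halves identically;
  # the co-attention average is symmetric, so swapping pairs must not
  # change fused outputs
  net <- tiny_net(base_filters = 2L)
  ch <- 2L * 2L^(0:4)
  for (i in 3:5) {
    w <- net$params[[paste0("fu", i, "_mix_w")]]
    C <- ch[i]
    w[, , , (C + 1):(2 * C), ] <- w[, , , 1:C, ]
    net$params[[paste0("fu", i, "_mix_w")]] <- w
  }
  shp <- c(16L, 16L, 16L)
  a <- rand_grid(shp, 2, seed = 17)
  b <- rand_grid(shp, 2, seed = 18)
  o1 <- forward_segment(net, list(a, b))
  o2 <- forward_segment(net, list(b, a))
  expect_equal(o1$side_maps$m3, o2$side_maps$m3, tolerance = 1e-10)
  expect_equal(o1$prob, o2$prob, tolerance = 1e-10)
})

test_that("config variants run end to end and gate as documented", {
  x <- rand_grid(c(16, 16, 16), 2, seed = 19)
  y <- rand_grid(c(16, 16, 16), 2, seed = 20)
  for (rm in c("literal_plus_one", "map_residual")) {
    for (bc in c("region_average", "per_channel")) {
      net <- tiny_net(residual_mode = rm, attention_broadcast = bc)
      out <- forward_segment(net, list(x, y))
      expect_true(all(is.finite(out$prob)))
      expect_equal(dim(out$prob), c(16L, 16L, 16L, 3L))
    }
  }
  # per-channel broadcast: feature channel c is gated by region channel
  # (c - 1) %% 3 + 1
  net <- tiny_net(base_filters = 2L, attention_broadcast = "per_channel")
  C5 <- 32L
  f1 <- rand_grid(c(4, 4, 4), C5, seed = 21)
  f2 <- rand_grid(c(4, 4, 4), C5, seed = 22)
  r3 <- array(runif(64 * 3), c(4, 4, 4, 3))
  out <- fuse_features(net, 5L, f1, f2, r3)
  idx <- ((seq_len(C5) - 1L) %% 3L) + 1L
  orc <- f1 * r3[, , , idx] + 1
  expect_lt(max(abs(out$attended[[1]] - orc)), 1e-12)
})

test_that("binarize_prediction thresholds and enforces nesting", {
  pr <- array(0.4, c(2, 2, 2, 3))
  pr[1, 1, 1, ] <- c(0.6, 0.6, 0.6)
  mk <- binarize_prediction(pr)
  expect_equal(mk$wt[1, 1, 1], 1L)
  expect_equal(sum(mk$wt), 1L)

  # ties at the threshold go to 1
  tie <- array(0.5, c(2, 2, 2, 3))
  expect_equal(sum(binarize_prediction(tie)$wt), 8L)

  # nesting enforced by intersection even when channels disagree
  pr <- array(0, c(2, 2, 2, 3))
  pr[1, 1, 1, 3] <- 0.9 # ET fires without WT/TC support
  pr[2, 2, 2, 1] <- 0.9
  mk <- binarize_prediction(pr)
  expect_equal(sum(mk$et), 0L)
  expect_equal(sum(mk$wt), 1L)
  expect_error(binarize_prediction(pr * 3), "probabilities")
})
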