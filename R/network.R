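# Segmentation network: shared-parameter pair encoder, partial decoder over
# high-level features, and the reverse co-attention fusing cascade.
#
# Topology for one forward pass (full model):
#   split pairs -> shared 5-level encoder per pair
#               -> partial decoder per pair (global map M_g, level-3 grid)
#               -> cascade i = 5, 4, 3:
#                    R_p   = 1 - sigmoid(current map of pair p)
#                    Rbar  = (R_g1 + R_g2) / 2          (reverse co-attention)
#                    f̄_p  = f_i_p * Rbar + 1            (literal residual)
#                    fused = conv(concat(f̄_g1, f̄_g2)); M_i = head(fused)
#               -> prediction = sigmoid(upsample(M_3)) at full resolution.
# All maps have three region channels (WT, TC, ET) supervised independently.

#' Network configuration
#'
#' @param base_filters Channels at level 1; doubled per level (paper-scale
#'   16, desk-scale default 4).
#' @param levels Pyramid depth; fixed at 5.
#' @param region_channels Output channels, one logit map per region
#'   (WT, TC, ET).
#' @param residual_mode `"literal_plus_one"` applies the `f * R + 1` form of
#'   the fusing equation; `"map_residual"` drops the scalar `+1` and instead
#'   adds the previous-level map to the side-output logits (the form used in
#'   the reverse-attention literature).
#' @param attention_broadcast `"region_average"` averages the attention map
#'   over region channels before gating all feature channels;
#'   `"per_channel"` gates feature channel c with region channel
#'   `(c - 1) %% 3 + 1`.
#' @param n_pairs 2 for the full two-pair model, 1 for single-pair ablations.
#' @param seed Seed for the He-style weight initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(base_filters = 4L, levels = 5L,
                           region_channels = 3L,
                           residual_mode = c("literal_plus_one", "map_residual"),
                           attention_broadcast = c("region_average", "per_channel"),
                           n_pairs = 2L, seed = 1L) {
  if (levels != 5L) stop("the feature pyramid is fixed at five levels")
  if (base_filters < 1L) stop("base_filters must be >= 1")
  structure(list(
    base_filters = as.integer(base_filters), levels = 5L,
    region_channels = as.integer(region_channels),
    residual_mode = match.arg(residual_mode),
    attention_broadcast = match.arg(attention_broadcast),
    n_pairs = as.integer(n_pairs),
    upsample = "trilinear_align_corners_off",
    seed = as.integer(seed)
  ), class = "network_config")
}

level_channels <- function(cfg) cfg$base_filters * 2L^(0:4)

he_w <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))), c(k, k, k, cin, cout))
}

new_conv <- function(params, name, k, cin, cout, norm = TRUE) {
  params[[paste0(name, "_w")]] <- he_w(k, cin, cout)
  params[[paste0(name, "_b")]] <- numeric(cout)
  if (norm) {
    params[[paste0(name, "_g")]] <- rep(1, cout)
    params[[paste0(name, "_be")]] <- numeric(cout)
  }
  params
}

#' Create a segmentation network
#'
#' Initializes all parameters with seeded He-style draws (random
#' initialization; no pre-trained weights are used).
#'
#' @param config A [network_config()].
#' @return An object of class `coattseg_net` with fields `config` and
#'   `params` (named list of arrays).
#' @export
create_network <- function(config = network_config()) {
  set.seed(config$seed)
  ch <- level_channels(config)
  rc <- config$region_channels
  p <- list()
  # shared encoder: level 1 two stride-1 convs; levels 2-5 strided + regular
  p <- new_conv(p, "enc1_a", 3L, 2L, ch[1])
  p <- new_conv(p, "enc1_b", 3L, ch[1], ch[1])
  for (k in 2:5) {
    p <- new_conv(p, paste0("enc", k, "_a"), 3L, ch[k - 1], ch[k])
    p <- new_conv(p, paste0("enc", k, "_b"), 3L, ch[k], ch[k])
  }
  # partial decoder: 1x1 reductions to the level-3 width, cascade, head
  d <- ch[3]
  p <- new_conv(p, "pd_red3", 1L, ch[3], d)
  p <- new_conv(p, "pd_red4", 1L, ch[4], d)
  p <- new_conv(p, "pd_red5", 1L, ch[5], d)
  p <- new_conv(p, "pd_agg", 3L, 3L * d, d)
  p <- new_conv(p, "pd_head", 1L, d, rc, norm = FALSE)
  # fusing blocks, one per level 3..5
  for (i in 3:5) {
    p <- new_conv(p, paste0("fu", i, "_mix"), 3L, config$n_pairs * ch[i], ch[i])
    p <- new_conv(p, paste0("fu", i, "_head"), 1L, ch[i], rc, norm = FALSE)
  }
  structure(list(config = config, params = p), class = "coattseg_net")
}

wrap_params <- function(tape, params) lapply(params, function(a) ad_leaf(tape, a))

conv_block <- function(tape, P, name, x, stride = 1L, pad = 1L) {
  y <- ad_conv3(
    tape, x, P[[paste0(name, "_w")]], P[[paste0(name, "_b")]],
    stride = stride, pad = pad
  )
  y <- ad_instnorm(tape, y, P[[paste0(name, "_g")]], P[[paste0(name, "_be")]])
  ad_relu(tape, y)
}

conv_head <- function(tape, P, name, x) {
  ad_conv3(tape, x, P[[paste0(name, "_w")]], P[[paste0(name, "_b")]],
    stride = 1L, pad = 0L
  )
}

# ---- graph builders --------------------------------------------------------

ng_encode <- function(tape, P, x) {
  f <- vector("list", 5L)
  h <- conv_block(tape, P, "enc1_a", x)
  f[[1]] <- conv_block(tape, P, "enc1_b", h)
  for (k in 2:5) {
    h <- conv_block(tape, P, paste0("enc", k, "_a"), f[[k - 1]], stride = 2L)
    f[[k]] <- conv_block(tape, P, paste0("enc", k, "_b"), h)
  }
  f
}

ng_partial_decode <- function(tape, P, f3, f4, f5) {
  d3 <- dim(f3$value)[1:3]
  d4 <- dim(f4$value)[1:3]
  a5 <- conv_block(tape, P, "pd_red5", f5, pad = 0L)
  a4 <- conv_block(tape, P, "pd_red4", f4, pad = 0L)
  a4 <- ad_mul(tape, a4, ad_resize(tape, a5, d4))
  a3 <- conv_block(tape, P, "pd_red3", f3, pad = 0L)
  a3 <- ad_mul(tape, a3, ad_resize(tape, a4, d3))
  cat <- ad_concat_ch(
    tape, a3,
    ad_concat_ch(tape, ad_resize(tape, a4, d3), ad_resize(tape, a5, d3))
  )
  fdp <- conv_block(tape, P, "pd_agg", cat)
  mg <- conv_head(tape, P, "pd_head", fdp)
  list(fdp = fdp, mg = mg)
}

# attention weight map -> single-channel (or per-channel) gating node
ng_gate <- function(tape, feat, R, broadcast) {
  if (broadcast == "region_average") {
    ad_mul_bcast(tape, feat, ad_mean_ch(tape, R))
  } else {
    d <- dim(feat$value)
    rc <- dim(R$value)[4]
    idx <- ((seq_len(d[4]) - 1L) %% rc) + 1L
    Rv <- R$value[, , , idx, drop = FALSE]
    y <- feat$value * Rv
    ad_node(tape, y, bw = function(g) {
      ad_acc(feat, g * Rv)
      gr <- array(0, dim(R$value))
      for (j in seq_len(rc)) {
        sel <- which(idx == j)
        gsum <- 0
        for (s in sel) gsum <- gsum + g[, , , s] * feat$value[, , , s]
        gr[, , , j] <- gsum
      }
      ad_acc(R, gr)
    })
  }
}

ng_fuse <- function(tape, P, cfg, level, feats, gates, prev_avg) {
  # feats / gates: one entry per pair; gates already in attention-weight form
  attended <- vector("list", length(feats))
  for (p in seq_along(feats)) {
    a <- ng_gate(tape, feats[[p]], gates[[p]], cfg$attention_broadcast)
    if (cfg$residual_mode == "literal_plus_one") a <- ad_add_const(tape, a, 1)
    attended[[p]] <- a
  }
  cat <- attended[[1]]
  if (length(attended) > 1L) {
    for (p in 2:length(attended)) cat <- ad_concat_ch(tape, cat, attended[[p]])
  }
  fused <- conv_block(tape, P, paste0("fu", level, "_mix"), cat)
  m <- conv_head(tape, P, paste0("fu", level, "_head"), fused)
  if (cfg$residual_mode == "map_residual") m <- ad_add(tape, m, prev_avg)
  list(fused = fused, m = m, attended = attended)
}

# Full forward graph. `pair_stacks` is a list of one or two 4D arrays
# (H,W,L,2). `mode` selects the attention strategy:
#   full               reverse co-attention (average of the pairs' R maps)
#   no_coattention     each pair gated by its own reverse attention
#   saliency_attention forward attention sigma(M), averaged across pairs
ng_forward <- function(tape, P, cfg, pair_stacks,
                       mode = c("full", "no_coattention", "saliency_attention")) {
  mode <- match.arg(mode)
  np <- length(pair_stacks)
  shp <- dim(pair_stacks[[1]])[1:3]
  if (any(shp %% 16L != 0L)) {
    stop(
      "spatial dims must be divisible by 16 (five dyadic levels), got ",
      paste(shp, collapse = "x")
    )
  }
  pyrs <- vector("list", np)
  mgs <- vector("list", np)
  for (p in seq_len(np)) {
    x <- ad_leaf(tape, pair_stacks[[p]])
    pyrs[[p]] <- ng_encode(tape, P, x)
    dec <- ng_partial_decode(
      tape, P, pyrs[[p]][[3]], pyrs[[p]][[4]], pyrs[[p]][[5]]
    )
    mgs[[p]] <- dec$mg
  }
  cur <- mgs
  side <- list()
  for (i in c(5L, 4L, 3L)) {
    tdim <- shp %/% 2L^(i - 1L)
    prev <- lapply(cur, function(m) ad_resize(tape, m, tdim))
    prev_avg <- if (np == 1L) {
      prev[[1]]
    } else {
      ad_scale(tape, ad_add(tape, prev[[1]], prev[[2]]), 0.5)
    }
    gates <- switch(mode,
      full = {
        Rs <- lapply(prev, function(m) {
          ad_one_minus(tape, ad_sigmoid(tape, m))
        })
        rbar <- if (np == 1L) {
          Rs[[1]]
        } else {
          ad_scale(tape, ad_add(tape, Rs[[1]], Rs[[2]]), 0.5)
        }
        rep(list(rbar), np)
      },
      no_coattention = lapply(prev, function(m) {
        ad_one_minus(tape, ad_sigmoid(tape, m))
      }),
      saliency_attention = {
        As <- lapply(prev, function(m) ad_sigmoid(tape, m))
        abar <- if (np == 1L) {
          As[[1]]
        } else {
          ad_scale(tape, ad_add(tape, As[[1]], As[[2]]), 0.5)
        }
        rep(list(abar), np)
      }
    )
    feats <- lapply(pyrs, function(py) py[[i]])
    fu <- ng_fuse(tape, P, cfg, i, feats, gates, prev_avg)
    side[[paste0("m", i)]] <- fu$m
    cur <- rep(list(fu$m), np)
  }
  logits <- ad_resize(tape, side$m3, shp)
  prob <- ad_sigmoid(tape, logits)
  list(mgs = mgs, side = side, logits = logits, prob = prob, pyramids = pyrs)
}

# ---- public (array-level) operations ---------------------------------------

as_pair_stack <- function(pair) {
  if (inherits(pair, "modality_pair")) pair$channels else pair
}

#' Encode a modality pair into the five-level feature pyramid
#'
#' The same parameter set processes both modality pairs (parameter sharing).
#'
#' @param net A `coattseg_net`.
#' @param pair A `modality_pair` or a 4D array (H,W,L,2); spatial dims must
#'   be divisible by 16.
#' @return List `f1`..`f5` of feature arrays, class `feature_pyramid`.
#' @export
encode_pair <- function(net, pair) {
  x <- as_pair_stack(pair)
  shp <- dim(x)[1:3]
  if (any(shp %% 16L != 0L)) {
    stop(
      "spatial dims must be divisible by 16 (five dyadic levels), got ",
      paste(shp, collapse = "x")
    )
  }
  tape <- ad_tape()
  P <- wrap_params(tape, net$params)
  f <- ng_encode(tape, P, ad_leaf(tape, x))
  structure(
    setNames(lapply(f, function(nd) nd$value), paste0("f", 1:5)),
    class = "feature_pyramid"
  )
}

#' Aggregate high-level features with the partial decoder
#'
#' Only levels 3-5 are aggregated; deeper features are upsampled,
#' elementwise-multiplied into shallower ones, concatenated and convolved
#' down to the region-channel global map.
#'
#' @param net A `coattseg_net`.
#' @param f3,f4,f5 Level 3-5 feature arrays of one pair's pyramid.
#' @return List with `f_dp` (aggregated feature) and `m_g` (region-channel
#'   logit map), both at level-3 resolution.
#' @export
partial_decode <- function(net, f3, f4, f5) {
  d3 <- dim(f3)[1:3]
  if (!all(dim(f4)[1:3] * 2L == d3) || !all(dim(f5)[1:3] * 4L == d3)) {
    stop("pyramid level shapes are not dyadically consistent")
  }
  tape <- ad_tape()
  P <- wrap_params(tape, net$params)
  out <- ng_partial_decode(
    tape, P,
    ad_leaf(tape, f3), ad_leaf(tape, f4), ad_leaf(tape, f5)
  )
  list(f_dp = out$fdp$value, m_g = out$mg$value)
}

#' Reverse attention weights
#'
#' `R = 1 - sigmoid(M)`: large logits (confident tumor) get weights near 0,
#' emphasising the not-yet-predicted (normal brain) regions.
#'
#' @param m Logit array.
#' @return Array of weights, strictly inside (0, 1) for finite logits.
#' @export
reverse_attention <- function(m) {
  if (!all(is.finite(m))) stop("logit map contains non-finite values")
  1 - 1 / (1 + exp(-m))
}

#' Average two pairs' reverse attention weights
#'
#' @param r_g1,r_g2 Attention weight arrays of identical shape.
#' @return Elementwise average.
#' @export
co_attention_average <- function(r_g1, r_g2) {
  if (!identical(dim(r_g1), dim(r_g2))) {
    stop("attention weight shapes differ between pairs")
  }
  (r_g1 + r_g2) / 2
}

#' Fuse both pairs' level-i features under a shared attention weight
#'
#' Each pair's features are gated by the (region-averaged) attention weight,
#' offset by the literal `+1` residual, concatenated channel-wise, reduced by
#' the level's mixing convolution and emitted with a side-output logit map.
#'
#' @param net A `coattseg_net` (two-pair configuration).
#' @param level Pyramid level, 3, 4 or 5.
#' @param f_g1,f_g2 Level-`level` feature arrays of the two pairs.
#' @param rbar Attention weight array: (H,W,L), (H,W,L,1) or region-channel
#'   (H,W,L,3) (averaged over region channels before gating).
#' @param prev_map Previous map (global map for level 5, upsampled next-level
#'   side map otherwise); required for `residual_mode = "map_residual"`.
#' @return List with `fused` (mixed feature), `m` (side-output logits) and
#'   `attended` (per-pair gated features, before concatenation).
#' @export
fuse_features <- function(net, level, f_g1, f_g2, rbar, prev_map = NULL) {
  cfg <- net$config
  d <- dim(f_g1)[1:3]
  if (!identical(dim(f_g1), dim(f_g2))) stop("pair feature shapes differ")
  if (is.null(dim(rbar)) || length(dim(rbar)) == 3L) {
    rbar <- array(rbar, c(d, 1L))
  }
  if (!identical(dim(rbar)[1:3], d)) stop("attention weight shape mismatch")
  tape <- ad_tape()
  P <- wrap_params(tape, net$params)
  rn <- ad_leaf(tape, rbar)
  gate <- if (dim(rbar)[4] > 1L && cfg$attention_broadcast == "region_average") {
    ad_mean_ch(tape, rn)
  } else {
    rn
  }
  feats <- list(ad_leaf(tape, f_g1), ad_leaf(tape, f_g2))
  prev <- if (!is.null(prev_map)) {
    ad_resize(tape, ad_leaf(tape, prev_map), d)
  } else if (cfg$residual_mode == "map_residual") {
    stop("prev_map is required under residual_mode = 'map_residual'")
  } else {
    NULL
  }
  out <- ng_fuse(tape, P, cfg, level, feats, rep(list(gate), 2L), prev)
  list(
    fused = out$fused$value, m = out$m$value,
    attended = lapply(out$attended, function(nd) nd$value)
  )
}

#' Run the full segmentation forward pass
#'
#' @param net A `coattseg_net`.
#' @param study A normalized [multimodal_study()], a list of pair stacks, or
#'   a single 4D pair stack (single-pair configurations).
#' @param mode Attention strategy; defaults to the full reverse co-attention
#'   model. See [run_ablation()] for the ablation variants.
#' @param pair_select For `n_pairs = 1` networks fed a full study: which pair
#'   to use ("g1" or "g2").
#' @return List with `global_maps` (per pair), `side_maps` (`m3`, `m4`,
#'   `m5`), `logits` and `prob` (3-channel full-resolution probabilities).
#' @export
forward_segment <- function(net, study,
                            mode = c("full", "no_coattention", "saliency_attention"),
                            pair_select = "g1") {
  mode <- match.arg(mode)
  cfg <- net$config
  stacks <- study_to_stacks(study, cfg, pair_select)
  tape <- ad_tape()
  P <- wrap_params(tape, net$params)
  out <- ng_forward(tape, P, cfg, stacks, mode)
  list(
    global_maps = lapply(out$mgs, function(nd) nd$value),
    side_maps = lapply(out$side, function(nd) nd$value),
    logits = out$logits$value,
    prob = out$prob$value
  )
}

study_to_stacks <- function(study, cfg, pair_select = "g1") {
  if (inherits(study, "multimodal_study")) {
    pr <- split_modality_pairs(study)
    if (cfg$n_pairs == 2L) {
      list(pr$g1$channels, pr$g2$channels)
    } else {
      list(pr[[pair_select]]$channels)
    }
  } else if (is.list(study)) {
    lapply(study, as_pair_stack)
  } else {
    list(as_pair_stack(study))
  }
}

#' Threshold probability maps into nested hierarchical masks
#'
#' Channels are thresholded independently (ties, i.e. values equal to the
#' threshold, map to 1), then nesting is enforced constructively:
#' `tc <- tc & wt`, `et <- et & tc`.
#'
#' @param prob 4D array (H,W,L,3) of probabilities in order WT, TC, ET.
#' @param threshold Decision threshold, default 0.5.
#' @return A [hierarchical_masks()] object.
#' @export
binarize_prediction <- function(prob, threshold = 0.5) {
  if (min(prob) < 0 || max(prob) > 1) stop("probabilities must lie in [0, 1]")
  wt <- array(as.integer(prob[, , , 1] >= threshold), dim(prob)[1:3])
  tc <- array(as.integer(prob[, , , 2] >= threshold), dim(prob)[1:3]) * wt
  et <- array(as.integer(prob[, , , 3] >= threshold), dim(prob)[1:3]) * tc
  hierarchical_masks(wt, tc, et)
}
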