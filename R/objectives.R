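# Training objective: soft Dice segmentation loss plus deeply supervised
# weighted binary cross-entropy on the global and side-output maps, combined
# as L_total = alpha * L_sg + (1 - alpha) * L_deep with alpha = 0.7.

as_region_stack <- function(x) {
  if (inherits(x, "hierarchical_masks")) {
    array(c(x$wt, x$tc, x$et), c(dim(x$wt), 3L))
  } else if (length(dim(x)) == 3L) {
    array(x, c(dim(x), 1L))
  } else {
    x
  }
}

#' Soft Dice loss
#'
#' `1 - (2 |Y * S| + eps) / (|Y| + |S| + eps)` with soft (probability)
#' intersection and sizes, computed per region channel and averaged over
#' channels. The smoothing constant keeps empty targets well-defined and the
#' loss differentiable.
#'
#' @param prediction Probabilities in \[0, 1\]; 3D array, 4D region stack, or
#'   anything [binarize_prediction()] consumes.
#' @param target Binary masks of the same shape (or `hierarchical_masks`).
#' @param eps Smoothing constant added to numerator and denominator.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(prediction, target, eps = 1) {
  p <- as_region_stack(prediction)
  t <- as_region_stack(target)
  if (!identical(dim(p), dim(t))) stop("prediction/target shape mismatch")
  C <- dim(p)[4]
  n <- prod(dim(p)[1:3])
  pm <- matrix(p, n, C)
  tm <- matrix(t, n, C)
  lc <- 1 - (2 * colSums(pm * tm) + eps) / (colSums(pm) + colSums(tm) + eps)
  mean(lc)
}

# Window size for the hard-pixel weighting, scaled from the 31-voxel window
# used at 128^3 training resolution down to the current grid.
wbce_window <- function(n) {
  max(3L, 2L * as.integer(floor(31 * n / 128 / 2)) + 1L)
}

#' Per-voxel hard-pixel weights for the weighted BCE
#'
#' `w = 1 + lambda_w * |boxmean_k(G) - G|`: voxels whose label differs from
#' their neighbourhood average (boundaries, thin structures) get up to
#' `1 + lambda_w` weight.
#'
#' @param target Binary region stack (H,W,L,C).
#' @param lambda_w Weight amplitude (default 5).
#' @param window Odd cubic window size; default scaled from the grid.
#' @return Array of weights, same shape as `target`.
#' @export
wbce_weights <- function(target, lambda_w = 5, window = NULL) {
  t <- as_region_stack(target)
  if (is.null(window)) window <- wbce_window(max(dim(t)[1:3]))
  1 + lambda_w * abs(boxmean3(t * 1.0, as.integer(window)) - t)
}

#' Weighted binary cross-entropy on logits
#'
#' Numerically stable BCE with per-voxel hard-pixel weights, normalized by
#' the weight sum per region channel and averaged over channels.
#'
#' @param logit_map Logit array (3D or region stack).
#' @param target_map Binary target of the same shape.
#' @param lambda_w,window Passed to [wbce_weights()].
#' @param weights Optional precomputed weights (overrides the former).
#' @return Scalar loss.
#' @export
weighted_bce <- function(logit_map, target_map, lambda_w = 5, window = NULL,
                         weights = NULL) {
  x <- as_region_stack(logit_map)
  t <- as_region_stack(target_map)
  if (!identical(dim(x), dim(t))) stop("logit/target shape mismatch")
  w <- if (is.null(weights)) wbce_weights(t, lambda_w, window) else weights
  C <- dim(x)[4]
  n <- prod(dim(x)[1:3])
  xm <- matrix(x, n, C)
  tm <- matrix(t, n, C)
  wm <- matrix(w, n, C)
  bce <- pmax(xm, 0) - xm * tm + log1p(exp(-abs(xm)))
  mean(colSums(wm * bce) / colSums(wm))
}

#' Deep supervision loss over the global and side-output maps
#'
#' Each map is upsampled (trilinear) to the ground-truth resolution and
#' scored with [weighted_bce()]; the four terms are summed. When two global
#' maps are supplied (one per modality pair) their terms are averaged so the
#' sum keeps the printed four-term structure.
#'
#' @param m_g Global logit map, or list of per-pair global maps.
#' @param m3,m4,m5 Side-output logit maps at their native levels.
#' @param g Ground-truth region stack (or `hierarchical_masks`).
#' @param lambda_w,window Passed to [weighted_bce()].
#' @return Scalar loss.
#' @export
deep_supervision_loss <- function(m_g, m3, m4, m5, g, lambda_w = 5,
                                  window = NULL) {
  gt <- as_region_stack(g)
  shp <- dim(gt)[1:3]
  w <- wbce_weights(gt, lambda_w, window)
  up <- function(m) {
    m <- as_region_stack(m)
    if (all(dim(m)[1:3] == shp)) m else resize3(m, shp[1], shp[2], shp[3])
  }
  term <- function(m) weighted_bce(up(m), gt, weights = w)
  mg_term <- if (is.list(m_g)) mean(vapply(m_g, term, 0)) else term(m_g)
  mg_term + term(m3) + term(m4) + term(m5)
}

#' Total training loss
#'
#' `L_total = alpha * L_sg + (1 - alpha) * L_deep` with the Dice
#' segmentation loss and the deep-supervision sum; alpha defaults to 0.7.
#'
#' @param prediction Full-resolution probability stack.
#' @param maps List with `m_g` (map or per-pair list), `m3`, `m4`, `m5`.
#' @param y Ground-truth masks for the Dice term.
#' @param g Ground-truth masks for the deep-supervision term (defaults to
#'   `y`).
#' @param alpha Mixing weight in \[0, 1\].
#' @param eps,lambda_w,window Component settings.
#' @return A `loss_breakdown` list: `l_sg`, `l_deep`, `l_total`, `alpha`.
#' @export
total_loss <- function(prediction, maps, y, g = y, alpha = 0.7, eps = 1,
                       lambda_w = 5, window = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  l_sg <- dice_loss(prediction, y, eps = eps)
  l_deep <- deep_supervision_loss(
    maps$m_g, maps$m3, maps$m4, maps$m5, g,
    lambda_w = lambda_w, window = window
  )
  structure(list(
    l_sg = l_sg, l_deep = l_deep,
    l_total = alpha * l_sg + (1 - alpha) * l_deep, alpha = alpha
  ), class = "loss_breakdown")
}
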