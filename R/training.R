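# Training engine: dataset splitting, foreground-biased patch sampling, the
# Adam optimization loop with the composite loss, whole-volume prediction
# with tiled overlap averaging, and the ablation study driver.
#
# The "desk" profile (default) trains a 32^3 / base-4-filter model on one
# CPU; the "paper" profile carries the published training scale (128^3
# patches, 16 base filters, learning rate 1e-4) and is not exercised by the
# test suite.

#' Training configuration
#'
#' @param profile `"desk"` (CPU-scale defaults, tested) or `"paper"`
#'   (published training scale).
#' @param learning_rate Adam step size.
#' @param patch_size Cubic patch edge length (divisible by 16).
#' @param batch_size Subjects per optimization step.
#' @param steps Number of optimization steps.
#' @param split_fraction Training fraction of the cohort, in (0, 1).
#' @param p_fg Probability that a sampled patch is centred inside WT.
#' @param master_seed Seed controlling initialization and sampling.
#' @param ablation_mode One of `"full"`, `"g1_only"`, `"g2_only"`,
#'   `"average_fusion"`, `"no_coattention"`, `"saliency_attention"`.
#' @param base_filters Encoder width at level 1.
#' @param alpha,lambda_w,eps Loss settings (see [total_loss()]).
#' @param residual_mode,attention_broadcast Passed to [network_config()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(profile = c("desk", "paper"),
                         learning_rate = NULL, patch_size = NULL,
                         batch_size = NULL, steps = NULL,
                         split_fraction = 0.8, p_fg = 0.5, master_seed = 1L,
                         ablation_mode = c(
                           "full", "g1_only", "g2_only", "average_fusion",
                           "no_coattention", "saliency_attention"
                         ),
                         base_filters = NULL, alpha = 0.7, lambda_w = 5,
                         eps = 1, residual_mode = "literal_plus_one",
                         attention_broadcast = "region_average") {
  profile <- match.arg(profile)
  def <- if (profile == "desk") {
    list(learning_rate = 1e-3, patch_size = 32L, batch_size = 2L,
         steps = 200L, base_filters = 4L)
  } else {
    list(learning_rate = 1e-4, patch_size = 128L, batch_size = 2L,
         steps = 20000L, base_filters = 16L)
  }
  if (is.null(learning_rate)) learning_rate <- def$learning_rate
  if (is.null(patch_size)) patch_size <- def$patch_size
  if (is.null(batch_size)) batch_size <- def$batch_size
  if (is.null(steps)) steps <- def$steps
  if (is.null(base_filters)) base_filters <- def$base_filters
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must lie strictly inside (0, 1)")
  }
  if (any(patch_size %% 16L != 0L)) {
    stop("patch dims must be divisible by 16")
  }
  structure(list(
    profile = profile, learning_rate = learning_rate,
    optimizer = "adam", patch_size = as.integer(patch_size),
    batch_size = as.integer(batch_size), steps = as.integer(steps),
    split_fraction = split_fraction, p_fg = p_fg,
    master_seed = as.integer(master_seed),
    ablation_mode = match.arg(ablation_mode),
    base_filters = as.integer(base_filters), alpha = alpha,
    lambda_w = lambda_w, eps = eps, residual_mode = residual_mode,
    attention_broadcast = attention_broadcast
  ), class = "train_config")
}

#' Split subject ids into train and test sets
#'
#' Disjoint, exhaustive, seed-reproducible; `|train| = round(fraction * n)`.
#'
#' @param subject_ids Character/integer vector of ids (n >= 2).
#' @param fraction Training fraction.
#' @param seed Seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_dataset <- function(subject_ids, fraction = 0.8, seed = 1L) {
  n <- length(subject_ids)
  if (n < 2L) stop("need at least 2 subjects to split")
  n_train <- round(fraction * n)
  if (n_train < 1L || n_train >= n) {
    stop("cohort too small for a nonempty train and test set at fraction ",
         fraction)
  }
  set.seed(seed)
  perm <- sample(subject_ids)
  list(train = perm[seq_len(n_train)], test = perm[(n_train + 1L):n])
}

#' Sample an axis-aligned patch from a study and its masks
#'
#' The same crop is applied to all four modalities and all masks. With
#' probability `p_fg` (and a nonempty WT) the patch centre is a random WT
#' voxel. Uses the current RNG state; seed the caller for reproducibility.
#'
#' @param study A [multimodal_study()].
#' @param masks A [hierarchical_masks()] object.
#' @param patch_size Cubic edge length or length-3 vector.
#' @param p_fg Foreground-bias probability.
#' @return List with cropped `study` and `masks`.
#' @export
sample_patch <- function(study, masks, patch_size, p_fg = 0.5) {
  shp <- dim(study$t1)
  ps <- rep(as.integer(patch_size), length.out = 3L)
  if (any(ps > shp)) stop("patch larger than volume")
  center <- if (runif(1) < p_fg && sum(masks$wt) > 0) {
    fg <- which(masks$wt == 1L)
    arrayInd(fg[sample.int(length(fg), 1L)], shp)[1, ]
  } else {
    c(
      sample.int(shp[1], 1L), sample.int(shp[2], 1L),
      sample.int(shp[3], 1L)
    )
  }
  start <- pmin(pmax(center - ps %/% 2L, 1L), shp - ps + 1L)
  ix <- lapply(1:3, function(a) start[a]:(start[a] + ps[a] - 1L))
  crop <- function(v) v[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  st <- study
  for (m in MODALITIES) st[[m]] <- crop(st[[m]])
  mk <- hierarchical_masks(crop(masks$wt), crop(masks$tc), crop(masks$et))
  list(study = st, masks = mk)
}

# Precompute everything the step loop needs for one subject.
prepare_subject <- function(ph, cfg) {
  study <- normalize_study(ph$study)
  masks <- if (!is.null(ph$masks)) ph$masks else map_labels(ph$labels)
  list(study = study, masks = masks)
}

mode_to_forward <- function(ablation_mode) {
  switch(ablation_mode,
    full = list(mode = "full", n_pairs = 2L, pair_select = "g1"),
    g1_only = list(mode = "full", n_pairs = 1L, pair_select = "g1"),
    g2_only = list(mode = "full", n_pairs = 1L, pair_select = "g2"),
    no_coattention = list(mode = "no_coattention", n_pairs = 2L, pair_select = "g1"),
    saliency_attention = list(mode = "saliency_attention", n_pairs = 2L, pair_select = "g1"),
    stop("unknown ablation mode: ", ablation_mode)
  )
}

# Build the loss graph for one subject patch and backpropagate.
# Returns list(l_sg, l_deep, l_total); parameter gradients accumulate in P.
step_loss <- function(tape, P, cfg_net, stacks, gstack, w_full, tcfg,
                      fwd_mode) {
  out <- ng_forward(tape, P, cfg_net, stacks, fwd_mode)
  shp <- dim(gstack)[1:3]
  l_sg <- ad_dice_loss(tape, out$prob, gstack, eps = tcfg$eps)
  np <- length(out$mgs)
  terms <- list()
  coefs <- numeric(0)
  for (m in out$mgs) {
    up <- ad_resize(tape, m, shp)
    terms <- c(terms, list(ad_wbce(tape, up, gstack, w_full)))
    coefs <- c(coefs, 1 / np)
  }
  for (nm in c("m3", "m4", "m5")) {
    up <- ad_resize(tape, out$side[[nm]], shp)
    terms <- c(terms, list(ad_wbce(tape, up, gstack, w_full)))
    coefs <- c(coefs, 1)
  }
  l_deep <- ad_scalar_comb(tape, terms, coefs)
  l_total <- ad_scalar_comb(
    tape, list(l_sg, l_deep),
    c(tcfg$alpha, 1 - tcfg$alpha)
  )
  ad_backward(tape, l_total)
  list(l_sg = l_sg$value, l_deep = l_deep$value, l_total = l_total$value)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

#' Train a segmentation network on a phantom cohort
#'
#' Adam on the composite loss, fully seed-deterministic on one thread.
#'
#' @param cohort List of subjects as produced by [generate_cohort()] (fields
#'   `study` and `labels` or `masks`).
#' @param config A [train_config()].
#' @param net Optional pre-initialized network (checkpoint resume); default
#'   a fresh seeded network matching the config.
#' @return An object of class `coattseg_fit`: `net`, `history` (data frame
#'   with per-step `l_sg`, `l_deep`, `l_total`), `train_config`.
#' @export
train_model <- function(cohort, config = train_config(), net = NULL) {
  if (length(cohort) < 1L) stop("training cohort is empty")
  fwd <- mode_to_forward(config$ablation_mode)
  if (is.null(net)) {
    net <- create_network(network_config(
      base_filters = config$base_filters, n_pairs = fwd$n_pairs,
      residual_mode = config$residual_mode,
      attention_broadcast = config$attention_broadcast,
      seed = config$master_seed
    ))
  }
  cfg_net <- net$config
  subjects <- lapply(cohort, prepare_subject, cfg = config)
  set.seed(config$master_seed + 1L)
  astate <- adam_init(net$params)
  hist <- data.frame(
    step = integer(0), l_sg = numeric(0), l_deep = numeric(0),
    l_total = numeric(0)
  )
  if (config$steps == 0L) {
    return(structure(
      list(net = net, history = hist, train_config = config),
      class = "coattseg_fit"
    ))
  }
  for (step in seq_len(config$steps)) {
    idx <- sample.int(length(subjects), config$batch_size, replace = TRUE)
    grads <- NULL
    ls <- ld <- lt <- 0
    for (b in idx) {
      su <- subjects[[b]]
      pat <- sample_patch(su$study, su$masks, config$patch_size, config$p_fg)
      stacks <- study_to_stacks(pat$study, cfg_net, fwd$pair_select)
      gstack <- as_region_stack(pat$masks)
      w_full <- wbce_weights(gstack, config$lambda_w)
      tape <- ad_tape()
      P <- wrap_params(tape, net$params)
      lo <- step_loss(
        tape, P, cfg_net, stacks, gstack, w_full, config, fwd$mode
      )
      g <- lapply(P, function(nd) if (is.null(nd$grad)) nd$value * 0 else nd$grad)
      grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      ls <- ls + lo$l_sg
      ld <- ld + lo$l_deep
      lt <- lt + lo$l_total
    }
    nb <- length(idx)
    grads <- lapply(grads, function(g) g / nb)
    if (!is.finite(lt / nb)) {
      stop("training diverged at step ", step, ": non-finite loss")
    }
    up <- adam_step(net$params, grads, astate, config$learning_rate)
    net$params <- up$params
    astate <- up$state
    hist <- rbind(hist, data.frame(
      step = step, l_sg = ls / nb, l_deep = ld / nb, l_total = lt / nb
    ))
  }
  structure(
    list(net = net, history = hist, train_config = config),
    class = "coattseg_fit"
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the network config, parameters, training config and
#' history.
#'
#' @param fit A `coattseg_fit`.
#' @param path Destination file.
#' @return `save_checkpoint`: invisibly `path`; `load_checkpoint`: the fit.
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(
    list(
      config = fit$net$config, params = fit$net$params,
      train_config = fit$train_config, history = fit$history
    ),
    path
  )
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(
    net = structure(
      list(config = ck$config, params = ck$params),
      class = "coattseg_net"
    ),
    history = ck$history, train_config = ck$train_config
  ), class = "coattseg_fit")
}

#' Predict hierarchical masks for a whole study
#'
#' Volumes matching the patch size are segmented in one forward pass; larger
#' volumes are tiled with half-patch stride and overlapping probabilities
#' averaged.
#'
#' @param fit A `coattseg_fit` (or a bare `coattseg_net`, then `mode` and
#'   `pair_select` apply directly).
#' @param study A [multimodal_study()]; normalized internally unless
#'   `normalize = FALSE`.
#' @param patch_size Tile size; defaults to the training patch size.
#' @param threshold Binarization threshold.
#' @param normalize Normalize the study first.
#' @return List with `masks` ([hierarchical_masks()]) and `prob`.
#' @export
predict_study <- function(fit, study, patch_size = NULL, threshold = 0.5,
                          normalize = TRUE) {
  if (inherits(fit, "coattseg_fit")) {
    net <- fit$net
    fwd <- mode_to_forward(fit$train_config$ablation_mode)
    if (is.null(patch_size)) patch_size <- fit$train_config$patch_size
  } else {
    net <- fit
    fwd <- list(mode = "full", pair_select = "g1")
  }
  if (normalize) study <- normalize_study(study)
  shp <- dim(study$t1)
  if (is.null(patch_size)) patch_size <- min(shp)
  ps <- rep(as.integer(patch_size), length.out = 3L)
  ps <- pmin(ps, shp)
  prob <- array(0, c(shp, net$config$region_channels))
  count <- array(0, shp)
  starts <- lapply(1:3, function(a) {
    if (shp[a] == ps[a]) {
      return(1L)
    }
    s <- seq(1L, shp[a] - ps[a] + 1L, by = max(1L, ps[a] %/% 2L))
    unique(c(s, shp[a] - ps[a] + 1L))
  })
  for (sx in starts[[1]]) {
    for (sy in starts[[2]]) {
      for (sz in starts[[3]]) {
        ix <- list(sx:(sx + ps[1] - 1L), sy:(sy + ps[2] - 1L),
                   sz:(sz + ps[3] - 1L))
        sub <- study
        for (m in MODALITIES) {
          sub[[m]] <- study[[m]][ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
        }
        stacks <- study_to_stacks(sub, net$config, fwd$pair_select)
        tape <- ad_tape()
        P <- wrap_params(tape, net$params)
        out <- ng_forward(tape, P, net$config, stacks, fwd$mode)
        prob[ix[[1]], ix[[2]], ix[[3]], ] <-
          prob[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE] + out$prob$value
        count[ix[[1]], ix[[2]], ix[[3]]] <-
          count[ix[[1]], ix[[2]], ix[[3]]] + 1
      }
    }
  }
  prob <- prob / as.vector(count) # broadcast over channels
  list(masks = binarize_prediction(prob, threshold), prob = prob)
}

# Average-fusion prediction: mean of two single-pair probability maps.
predict_average <- function(fit_g1, fit_g2, study, threshold = 0.5) {
  p1 <- predict_study(fit_g1, study)$prob
  p2 <- predict_study(fit_g2, study)$prob
  prob <- (p1 + p2) / 2
  list(masks = binarize_prediction(prob, threshold), prob = prob)
}

#' Run an ablation study
#'
#' Trains each requested mode with identical budgets and seeds on the same
#' cohort split and evaluates on the held-out subjects. `average_fusion`
#' reuses the trained `g1_only` and `g2_only` models and averages their
#' probability maps.
#'
#' @param modes Character vector of ablation modes, or `"all"`.
#' @param cohort Phantom cohort (see [generate_cohort()]).
#' @param config Base [train_config()]; its `ablation_mode` is overridden
#'   per mode.
#' @return Named list per mode with `aggregate`, `per_subject` and `fit`
#'   (NULL for `average_fusion`).
#' @export
run_ablation <- function(modes, cohort, config = train_config()) {
  all_modes <- c(
    "full", "g1_only", "g2_only", "average_fusion", "no_coattention",
    "saliency_attention"
  )
  if (identical(modes, "all")) modes <- all_modes
  bad <- setdiff(modes, all_modes)
  if (length(bad) > 0L) stop("unknown ablation mode(s): ", paste(bad, collapse = ", "))

  ids <- seq_along(cohort)
  sp <- split_dataset(ids, config$split_fraction, config$master_seed)
  train_set <- cohort[sp$train]
  test_set <- cohort[sp$test]
  gt <- lapply(test_set, function(ph) {
    if (!is.null(ph$masks)) ph$masks else map_labels(ph$labels)
  })

  need_train <- union(
    setdiff(modes, "average_fusion"),
    if ("average_fusion" %in% modes) c("g1_only", "g2_only") else character(0)
  )
  fits <- list()
  for (m in need_train) {
    cfg <- config
    cfg$ablation_mode <- m
    fits[[m]] <- train_model(train_set, cfg)
  }

  out <- list()
  for (m in modes) {
    preds <- if (m == "average_fusion") {
      lapply(test_set, function(ph) {
        predict_average(fits$g1_only, fits$g2_only, ph$study)$masks
      })
    } else {
      lapply(test_set, function(ph) predict_study(fits[[m]], ph$study)$masks)
    }
    ev <- evaluate_cohort(preds, gt,
      spacing = test_set[[1]]$study$spacing,
      subject_ids = vapply(
        test_set,
        function(ph) ph$study$subject_id, ""
      )
    )
    out[[m]] <- list(
      aggregate = ev$aggregate, per_subject = ev$per_subject,
      fit = if (m == "average_fusion") NULL else fits[[m]]
    )
  }
  out
}
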