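# Model assembly: shared convolutional backbone, activation branch (1x1 conv,
# 2 classes), affinity branch (per-level 1x1 convs -> upsample -> concat ->
# merge 1x1 conv), random-walk refinement, bilinear upsampling to image
# resolution and softmax. The backward pass is implemented by hand as the
# exact adjoint of each forward step, so the whole model trains end-to-end
# with gradients flowing through the random walk into both branches and the
# shared backbone.

backbone_presets <- list(
  # stage channels / stride of the first conv in the stage / convs per stage
  tiny  = list(channels = c(4L, 6L, 8L), strides = c(1L, 1L, 1L), depth = c(1L, 1L, 1L)),
  small = list(channels = c(8L, 16L, 32L), strides = c(2L, 2L, 2L), depth = c(1L, 1L, 1L)),
  # output stride 4: keeps the feature-grid-to-object ratio of the full-scale
  # setup when images (and fish) are only ~100 px across
  small4 = list(channels = c(8L, 16L, 32L), strides = c(2L, 2L, 1L), depth = c(1L, 1L, 1L)),
  resnet38_style = list(channels = c(16L, 32L, 64L), strides = c(2L, 2L, 2L), depth = c(2L, 2L, 2L))
)

default_affinity_channels <- list(
  tiny = c(2L, 3L, 4L),
  small = c(8L, 16L, 24L),
  small4 = c(8L, 16L, 24L),
  resnet38_style = c(64L, 128L, 256L)
)

#' Model configuration
#'
#' @param backbone one of `"small"` (desk-scale, strides 2/4/8), `"small4"`
#'   (same but output stride 4 — the right grid density for ~100-px images
#'   with small fish), `"tiny"` (stride 1, for gradient checks on toy grids)
#'   or `"resnet38_style"` (deeper stages with the 64/128/256-channel
#'   affinity branch merging into 448 affinity features, mirroring the
#'   full-scale architecture).
#' @param affinity_enabled when `FALSE` the random-walk refinement is skipped
#'   (plain LCFCN mode); everything else is unchanged.
#' @param affinity_channels per-level 1x1-conv channel counts for the affinity
#'   branch; the merged affinity feature dimension is their sum.
#' @param num_classes number of output classes (2: background, fish).
#' @param beta Hadamard exponent of the transition operator.
#' @param iterations random-walk steps.
#' @param radius affinity neighbourhood radius in feature-grid cells.
#' @param normalization per-channel `mean`/`sd` applied to images before the
#'   backbone (ImageNet statistics by default).
#' @return an `alcfcn_config` list.
#' @export
model_config <- function(backbone = "small", affinity_enabled = TRUE,
                         affinity_channels = NULL, num_classes = 2L,
                         beta = 8, iterations = 8, radius = 5,
                         normalization = list(mean = IMAGENET_MEAN, sd = IMAGENET_SD)) {
  if (!backbone %in% names(backbone_presets))
    stop("unknown backbone: ", backbone)
  affinity_channels <- affinity_channels %||% default_affinity_channels[[backbone]]
  stopifnot(length(affinity_channels) == 3L)
  structure(
    list(backbone = backbone, affinity_enabled = affinity_enabled,
         affinity_channels = as.integer(affinity_channels),
         merged_channels = sum(as.integer(affinity_channels)),
         num_classes = as.integer(num_classes),
         beta = beta, iterations = iterations, radius = radius,
         normalization = normalization),
    class = "alcfcn_config"
  )
}

he_init <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

# Small random bias init: keeps pre-activations off the exact ReLU kink that
# zero biases put fully-clamped pixels on (which breaks differentiability at
# the initial point), without affecting training behaviour.
bias_init <- function(n) stats::rnorm(n, 0, 1e-2)

#' Initialise a model
#'
#' Weights are drawn from the current RNG state (He initialisation), so
#' wrapping the call in `set.seed()` gives reproducible models.
#'
#' @param config an [model_config()].
#' @return an `alcfcn_model` (config + parameter list).
#' @export
init_model <- function(config = model_config()) {
  bp <- backbone_presets[[config$backbone]]
  params <- list(backbone = list())
  cin <- 3L
  for (s in 1:3) {
    stage <- list()
    for (d in seq_len(bp$depth[s])) {
      cout <- bp$channels[s]
      stage[[d]] <- list(W = he_init(9L * cin, cout), b = bias_init(cout))
      cin <- cout
    }
    params$backbone[[s]] <- stage
  }
  c3 <- bp$channels[3]
  params$act <- list(W = he_init(c3, config$num_classes), b = bias_init(config$num_classes))
  ac <- config$affinity_channels
  params$aff <- list(
    levels = lapply(1:3, function(l) list(W = he_init(bp$channels[l], ac[l]), b = bias_init(ac[l]))),
    # Small-scale init keeps initial pairwise L1 distances O(1), so the walk
    # starts as local averaging instead of a frozen identity (W_ij = exp(-L1)
    # vanishes, and with it the affinity gradient, when distances are large).
    merge = list(W = 0.05 * he_init(sum(ac), config$merged_channels),
                 b = bias_init(config$merged_channels))
  )
  structure(list(config = config, params = params), class = "alcfcn_model")
}

normalize_image <- function(image, normalization) {
  for (ch in 1:3)
    image[, , ch] <- (image[, , ch] - normalization$mean[ch]) / normalization$sd[ch]
  image
}

#' Run the shared backbone
#'
#' @param model an `alcfcn_model`.
#' @param image `H x W x 3` array in `[0, 1]` (normalisation is applied
#'   internally).
#' @return list with `levels` (three feature arrays of increasing depth),
#'   `last` (the deepest), and a backward cache.
#' @export
backbone_forward <- function(model, image) {
  bp <- backbone_presets[[model$config$backbone]]
  x <- normalize_image(image, model$config$normalization)
  levels <- vector("list", 3L)
  caches <- vector("list", 3L)
  for (s in 1:3) {
    stage_cache <- list()
    for (d in seq_len(bp$depth[s])) {
      stride <- if (d == 1L) bp$strides[s] else 1L
      p <- model$params$backbone[[s]][[d]]
      cv <- conv2d_forward(x, p$W, p$b, k = 3L, stride = stride, pad = 1L)
      pre <- cv$out
      x <- relu(pre)
      stage_cache[[d]] <- list(conv = cv, pre = pre)
    }
    levels[[s]] <- x
    caches[[s]] <- stage_cache
  }
  list(levels = levels, last = levels[[3L]], cache = caches)
}

backbone_backward <- function(model, bb, grad_levels) {
  bp <- backbone_presets[[model$config$backbone]]
  grads <- list()
  gx <- NULL
  for (s in 3:1) {
    g_out <- grad_levels[[s]]
    if (!is.null(gx)) g_out <- g_out + gx
    stage_grads <- vector("list", bp$depth[s])
    for (d in rev(seq_len(bp$depth[s]))) {
      sc <- bb$cache[[s]][[d]]
      g_pre <- g_out * (sc$pre > 0)
      bk <- conv2d_backward(sc$conv, model$params$backbone[[s]][[d]]$W, g_pre)
      stage_grads[[d]] <- list(W = bk$weights, b = bk$bias)
      g_out <- bk$input
    }
    grads[[s]] <- stage_grads
    gx <- g_out
  }
  list(stage_grads = grads, grad_image = gx)
}

#' Activation branch: per-pixel class scores
#'
#' A single 1x1 convolution with `num_classes` output channels applied to the
#' deepest backbone feature map.
#'
#' @param model an `alcfcn_model`.
#' @param features a [backbone_forward()] result.
#' @return `h x w x num_classes` raw score array at feature resolution.
#' @export
activation_branch <- function(model, features) {
  L3 <- features$last
  n3 <- dim(L3)[1] * dim(L3)[2]
  A <- conv1x1_forward(matrix(L3, n3, dim(L3)[3]),
                       model$params$act$W, model$params$act$b)
  array(A, c(dim(L3)[1], dim(L3)[2], model$config$num_classes))
}

#' Affinity branch: per-pixel affinity features
#'
#' Per-level 1x1 convolutions (ReLU), bilinear upsampling of each result to
#' the deepest grid, channel concatenation, and a final linear 1x1 merge
#' convolution producing the affinity feature map.
#'
#' @param model an `alcfcn_model`.
#' @param features a [backbone_forward()] result.
#' @return list with `features` (`h x w x merged_channels` array) and a
#'   backward cache.
#' @export
affinity_branch <- function(model, features) {
  if (length(features$levels) < 3L) stop("affinity branch needs 3 feature levels")
  L3 <- features$levels[[3L]]
  h3 <- dim(L3)[1]; w3 <- dim(L3)[2]
  per <- vector("list", 3L)
  for (l in 1:3) {
    Ll <- features$levels[[l]]
    nl <- dim(Ll)[1] * dim(Ll)[2]
    p <- model$params$aff$levels[[l]]
    pre <- conv1x1_forward(matrix(Ll, nl, dim(Ll)[3]), p$W, p$b)
    act <- relu(pre)
    U <- bilinear_operator(dim(Ll)[1], dim(Ll)[2], h3, w3)
    per[[l]] <- list(pre = pre, act = act, up = as.matrix(U %*% act), U = U,
                     dims = dim(Ll))
  }
  concat <- cbind(per[[1]]$up, per[[2]]$up, per[[3]]$up)
  Fm <- conv1x1_forward(concat, model$params$aff$merge$W, model$params$aff$merge$b)
  list(features = array(Fm, c(h3, w3, model$config$merged_channels)),
       cache = list(per = per, concat = concat, h3 = h3, w3 = w3))
}

affinity_branch_backward <- function(model, features, cache, grad_F) {
  ac <- model$config$affinity_channels
  dConcat <- grad_F %*% t(model$params$aff$merge$W)
  g_merge <- list(W = crossprod(cache$concat, grad_F), b = colSums(grad_F))
  col0 <- c(0L, cumsum(ac))
  g_levels <- vector("list", 3L)
  grad_level_arrays <- vector("list", 3L)
  for (l in 1:3) {
    dUp <- dConcat[, (col0[l] + 1L):col0[l + 1L], drop = FALSE]
    pl <- cache$per[[l]]
    dAct <- as.matrix(Matrix::t(pl$U) %*% dUp)
    dPre <- dAct * (pl$pre > 0)
    Ll <- features$levels[[l]]
    nl <- dim(Ll)[1] * dim(Ll)[2]
    Lmat <- matrix(Ll, nl, dim(Ll)[3])
    g_levels[[l]] <- list(W = crossprod(Lmat, dPre), b = colSums(dPre))
    grad_level_arrays[[l]] <- array(dPre %*% t(model$params$aff$levels[[l]]$W), dim(Ll))
  }
  list(levels = g_levels, merge = g_merge, grad_level_arrays = grad_level_arrays)
}

#' Full forward pass
#'
#' Backbone, both branches, affinity graph and transition operator, random
#' walk on the raw activations, bilinear upsampling to image resolution, and
#' softmax. With `affinity_enabled = FALSE` in the config the refinement is
#' bypassed and the raw activations are upsampled directly.
#'
#' @param model an `alcfcn_model`.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param keep_cache keep intermediate values for [model_backward()].
#' @return list with `prob` (`H x W x 2`, channels sum to 1), `refined` (the
#'   feature-resolution refined score map), `graph` (the affinity graph, or
#'   `NULL` when disabled), and `cache` when requested.
#' @export
model_forward <- function(model, image, keep_cache = FALSE) {
  cfg <- model$config
  H <- dim(image)[1]; W <- dim(image)[2]
  bb <- backbone_forward(model, image)
  A <- activation_branch(model, bb)
  h3 <- dim(A)[1]; w3 <- dim(A)[2]
  graph <- NULL; op <- NULL; rw <- NULL; aff <- NULL
  if (cfg$affinity_enabled) {
    aff <- affinity_branch(model, bb)
    graph <- build_affinity_graph(aff$features, radius = cfg$radius)
    op <- build_transition(graph, beta = cfg$beta)
    rw <- rw_forward(A, op, cfg$iterations)
    refined <- rw$out
  } else {
    refined <- A
  }
  Uimg <- bilinear_operator(h3, w3, H, W)
  S <- as.matrix(Uimg %*% matrix(refined, h3 * w3, cfg$num_classes))
  P <- softmax2(S)
  out <- list(
    prob = array(P, c(H, W, cfg$num_classes)),
    refined = refined, graph = graph
  )
  if (keep_cache) {
    out$cache <- list(bb = bb, A = A, aff = aff, op = op, rw = rw,
                      Uimg = Uimg, P = P, H = H, W = W, h3 = h3, w3 = w3)
  }
  out
}

# Backward pass for the full model given dLoss/dProb (H x W x 2).
# Returns a gradient tree matching model$params.
model_backward <- function(model, fwd, grad_prob) {
  cfg <- model$config
  ca <- fwd$cache
  n_img <- ca$H * ca$W
  Gp <- matrix(grad_prob, n_img, cfg$num_classes)
  P <- ca$P
  inner <- rowSums(Gp * P)
  dS <- P * (Gp - inner)                      # softmax adjoint
  dRef <- as.matrix(Matrix::t(ca$Uimg) %*% dS)
  grads <- list()
  if (cfg$affinity_enabled) {
    rwb <- rw_backward(ca$op, ca$rw$traj, dRef)
    dA <- array(rwb$grad_activations, dim(ca$A))
    dWpairs <- transition_backward(ca$op, rwb$grad_T)
    dF <- graph_backward(fwd$graph, ca$aff$features, dWpairs)
    affb <- affinity_branch_backward(model, ca$bb, ca$aff$cache, dF)
    grads$aff <- list(levels = affb$levels, merge = affb$merge)
    grad_levels <- affb$grad_level_arrays
  } else {
    dA <- array(dRef, dim(ca$A))
    grad_levels <- lapply(ca$bb$levels, function(L) array(0, dim(L)))
    grads$aff <- zero_like(model$params$aff)
  }
  # activation branch
  L3 <- ca$bb$last
  n3 <- ca$h3 * ca$w3
  dAmat <- matrix(dA, n3, cfg$num_classes)
  L3mat <- matrix(L3, n3, dim(L3)[3])
  grads$act <- list(W = crossprod(L3mat, dAmat), b = colSums(dAmat))
  dL3 <- array(dAmat %*% t(model$params$act$W), dim(L3))
  grad_levels[[3L]] <- grad_levels[[3L]] + dL3
  bbk <- backbone_backward(model, ca$bb, grad_levels)
  grads$backbone <- bbk$stage_grads
  grads[names(model$params)]
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

# ---- Adam optimiser -------------------------------------------------------

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# ---- checkpointing --------------------------------------------------------

#' Save / load a model checkpoint
#' @param model an `alcfcn_model`.
#' @param path destination `.rds` path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = structure(x$config, class = "alcfcn_config"),
                 params = x$params),
            class = "alcfcn_model")
}

# ---- gradient checking ----------------------------------------------------

# Flatten a parameter tree into a named numeric vector of (path, index).
param_paths <- function(p, prefix = character()) {
  if (is.list(p)) {
    out <- list()
    nm <- names(p) %||% as.character(seq_along(p))
    if (is.null(names(p))) names(p) <- nm
    for (k in seq_along(p))
      out <- c(out, param_paths(p[[k]], c(prefix, nm[k])))
    out
  } else {
    lapply(seq_along(p), function(i) list(path = prefix, index = i))
  }
}

path_key <- function(tree, k) {
  if (!is.null(names(tree)) && k %in% names(tree)) k else as.integer(k)
}

get_param <- function(tree, path, index) {
  for (k in path) tree <- tree[[path_key(tree, k)]]
  tree[index]
}

set_param <- function(tree, path, index, value) {
  if (length(path) == 0L) { tree[index] <- value; return(tree) }
  k <- path_key(tree, path[1])
  tree[[k]] <- set_param(tree[[k]], path[-1], index, value)
  tree
}

#' Finite-difference gradient check of the full model + LCFCN loss
#'
#' Compares the analytic end-to-end gradient (through softmax, upsampling,
#' random walk, affinity graph, both branches and the shared backbone)
#' against central finite differences for a random sample of parameters.
#'
#' @param model an `alcfcn_model` (use the `"tiny"` backbone on a toy grid).
#' @param image `H x W x 3` array.
#' @param points annotation points for the loss.
#' @param n_sample number of parameters to probe (all if fewer).
#' @param eps finite-difference step.
#' @return tibble with one row per probed parameter: analytic and numeric
#'   derivatives and their relative error.
#' @export
gradient_check <- function(model, image, points = NULL, n_sample = 60L,
                           eps = 1e-5) {
  points <- normalize_points(points)
  loss_at <- function(params) {
    m <- model; m$params <- params
    fwd <- model_forward(m, image)
    lcfcn_loss(fwd$prob, points)$total
  }
  fwd <- model_forward(model, image, keep_cache = TRUE)
  rep <- lcfcn_loss(fwd$prob, points, with_grad = TRUE)
  grads <- model_backward(model, fwd, attr(rep, "grad"))
  slots <- param_paths(model$params)
  if (length(slots) > n_sample)
    slots <- slots[sort(sample.int(length(slots), n_sample))]
  rows <- lapply(slots, function(sl) {
    a <- get_param(grads, sl$path, sl$index)
    v0 <- get_param(model$params, sl$path, sl$index)
    lp <- loss_at(set_param(model$params, sl$path, sl$index, v0 + eps))
    lm <- loss_at(set_param(model$params, sl$path, sl$index, v0 - eps))
    num <- (lp - lm) / (2 * eps)
    tibble::tibble(
      path = paste(sl$path, collapse = "/"), index = sl$index,
      analytic = a, numeric = num,
      rel_error = abs(a - num) / max(abs(a) + abs(num), 1e-6)
    )
  })
  do.call(rbind, rows)
}
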