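# Pseudo-mask self-distillation: a trained weak model labels its own training
# images (upsampled refined scores, per-pixel argmax) and a fully supervised
# student is trained on those pseudo masks with boundary-weighted
# cross-entropy + IoU losses.

#' Generate pseudo ground-truth masks
#'
#' For each scene the refined activations are upsampled bilinearly to image
#' resolution and the per-pixel argmax over {background, fish} gives a binary
#' pseudo mask. Ties go to background.
#'
#' @param model a trained `alcfcn_model`.
#' @param scenes list of [scene()] objects (typically the train split).
#' @return named list of `alcfcn_pseudo_mask` objects (`mask`, `source_id`),
#'   keyed by scene id.
#' @export
generate_pseudo_masks <- function(model, scenes) {
  out <- lapply(scenes, function(s) {
    fwd <- model_forward(model, s$image)
    m <- (prob_channel(fwd$prob, 2L) > prob_channel(fwd$prob, 1L)) * 1L
    structure(list(mask = m, source_id = s$id), class = "alcfcn_pseudo_mask")
  })
  names(out) <- vapply(scenes, function(s) s$id, character(1))
  out
}

# Box-filtered mean of a matrix with an odd window, edge-clipped (each pixel
# normalised by the number of in-image window cells), via integral images.
box_mean <- function(m, window) {
  stopifnot(window %% 2 == 1)
  r <- (window - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(H) - r, 1L); r2 <- pmin(seq_len(H) + r, H)
  c1 <- pmax(seq_len(W) - r, 1L); c2 <- pmin(seq_len(W) + r, W)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  area <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / area
}

#' Boundary-emphasising pixel weights
#'
#' `w = 1 + lambda * |boxmean(g) - g|`: weights are 1 far from label
#' boundaries and rise towards them, counteracting the background/foreground
#' pixel imbalance at object edges.
#'
#' @param target `H x W` binary mask.
#' @param lambda emphasis strength.
#' @param window odd box-filter size in pixels; scaled down automatically for
#'   images smaller than the reference 256-pixel height.
#' @return `H x W` weight matrix, `>= 1` everywhere.
#' @export
boundary_weights <- function(target, lambda = 5, window = 31) {
  H <- nrow(target)
  win <- max(3L, round(window * H / 256))
  if (win %% 2 == 0) win <- win + 1L
  1 + lambda * abs(box_mean(target, win) - target)
}

#' Weighted cross-entropy loss
#'
#' `sum(w * -log p(target)) / sum(w)` over pixels.
#'
#' @param pred `H x W x 2` probability array.
#' @param target `H x W` binary mask.
#' @param weights `H x W` non-negative weights.
#' @return scalar loss.
#' @export
weighted_ce_loss <- function(pred, target, weights) {
  weighted_ce_term(pred, target, weights)$value
}

weighted_ce_term <- function(pred, target, weights) {
  stopifnot(all(dim(pred)[1:2] == dim(target)), all(dim(target) == dim(weights)),
            all(weights >= 0))
  wsum <- sum(weights)
  if (wsum == 0) stop("total pixel weight is zero")
  p_t <- ifelse(target == 1, prob_channel(pred, 2L), prob_channel(pred, 1L))
  value <- sum(weights * neg_log(p_t)) / wsum
  g <- weights * neg_log_grad(p_t) / wsum
  grad <- array(0, dim(pred))
  grad[, , 1L] <- g * (target == 0)
  grad[, , 2L] <- g * (target == 1)
  list(value = value, grad = grad)
}

#' Weighted IoU loss
#'
#' Soft-IoU on the fish channel:
#' `1 - (sum(w p g) + 1) / (sum(w (p + g - p g)) + 1)`.
#'
#' @inheritParams weighted_ce_loss
#' @return scalar loss.
#' @export
weighted_iou_loss <- function(pred, target, weights) {
  weighted_iou_term(pred, target, weights)$value
}

weighted_iou_term <- function(pred, target, weights) {
  stopifnot(all(dim(pred)[1:2] == dim(target)), all(dim(target) == dim(weights)))
  p <- prob_channel(pred, 2L); g <- target
  I <- sum(weights * p * g) + 1
  U <- sum(weights * (p + g - p * g)) + 1
  value <- 1 - I / U
  # d/dp of 1 - I/U
  dI <- weights * g
  dU <- weights * (1 - g)
  gp <- -(dI * U - I * dU) / U^2
  grad <- array(0, dim(pred))
  grad[, , 2L] <- gp
  list(value = value, grad = grad)
}

# ---- fully supervised student (FCN-style head) ----------------------------

#' Initialise the fully supervised student
#'
#' Shared-preset backbone plus an FCN8-style head: 1x1 score convolutions on
#' the two deepest feature levels, the deeper one upsampled and summed with
#' the shallower, then bilinearly upsampled to image resolution.
#'
#' @param backbone backbone preset name (see [model_config()]).
#' @param num_classes output classes.
#' @return an `alcfcn_student`.
#' @export
init_student <- function(backbone = "small", num_classes = 2L) {
  bp <- backbone_presets[[backbone]]
  cfg <- model_config(backbone = backbone, affinity_enabled = FALSE)
  params <- init_model(cfg)$params["backbone"]
  params$score3 <- list(W = he_init(bp$channels[3], num_classes), b = bias_init(num_classes))
  params$score2 <- list(W = he_init(bp$channels[2], num_classes), b = bias_init(num_classes))
  structure(list(config = cfg, params = params, num_classes = num_classes),
            class = "alcfcn_student")
}

student_forward <- function(student, image, keep_cache = FALSE) {
  shim <- structure(list(config = student$config, params = student$params),
                    class = "alcfcn_model")
  bb <- backbone_forward(shim, image)
  L2 <- bb$levels[[2L]]; L3 <- bb$levels[[3L]]
  n2 <- dim(L2)[1] * dim(L2)[2]; n3 <- dim(L3)[1] * dim(L3)[2]
  s3 <- conv1x1_forward(matrix(L3, n3, dim(L3)[3]), student$params$score3$W,
                        student$params$score3$b)
  s2 <- conv1x1_forward(matrix(L2, n2, dim(L2)[3]), student$params$score2$W,
                        student$params$score2$b)
  U32 <- bilinear_operator(dim(L3)[1], dim(L3)[2], dim(L2)[1], dim(L2)[2])
  s <- s2 + as.matrix(U32 %*% s3)
  H <- dim(image)[1]; W <- dim(image)[2]
  Uimg <- bilinear_operator(dim(L2)[1], dim(L2)[2], H, W)
  S <- as.matrix(Uimg %*% s)
  P <- softmax2(S)
  out <- list(prob = array(P, c(H, W, student$num_classes)))
  if (keep_cache)
    out$cache <- list(bb = bb, U32 = U32, Uimg = Uimg, P = P,
                      L2 = L2, L3 = L3, H = H, W = W)
  out
}

student_backward <- function(student, fwd, grad_prob) {
  ca <- fwd$cache
  shim <- structure(list(config = student$config, params = student$params),
                    class = "alcfcn_model")
  n_img <- ca$H * ca$W
  Gp <- matrix(grad_prob, n_img, student$num_classes)
  inner <- rowSums(Gp * ca$P)
  dS <- ca$P * (Gp - inner)
  ds <- as.matrix(Matrix::t(ca$Uimg) %*% dS)
  ds3 <- as.matrix(Matrix::t(ca$U32) %*% ds)
  n2 <- dim(ca$L2)[1] * dim(ca$L2)[2]; n3 <- dim(ca$L3)[1] * dim(ca$L3)[2]
  L2m <- matrix(ca$L2, n2, dim(ca$L2)[3]); L3m <- matrix(ca$L3, n3, dim(ca$L3)[3])
  grads <- list(backbone = NULL,
                score3 = list(W = crossprod(L3m, ds3), b = colSums(ds3)),
                score2 = list(W = crossprod(L2m, ds), b = colSums(ds)))
  gl2 <- array(ds %*% t(student$params$score2$W), dim(ca$L2))
  gl3 <- array(ds3 %*% t(student$params$score3$W), dim(ca$L3))
  grad_levels <- list(array(0, dim(ca$bb$levels[[1L]])), gl2, gl3)
  bbk <- backbone_backward(shim, ca$bb, grad_levels)
  grads$backbone <- bbk$stage_grads
  grads
}

# Student prediction: binary mask at image resolution.
student_predict <- function(student, image) {
  p <- student_forward(student, image)$prob
  (prob_channel(p, 2L) > prob_channel(p, 1L)) * 1L
}
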