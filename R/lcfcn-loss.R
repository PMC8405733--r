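# The four-term LCFCN objective on per-pixel probabilities and point
# annotations. Each term is a sum of -log probabilities over a structurally
# selected pixel set (max pixel, clicks, watershed ridges, unannotated
# blobs); the structure (blobs, watershed basins) is treated as fixed within
# a training step, so gradients flow only through the -log terms.

#' Extract predicted blobs and assign annotation points
#'
#' The predicted foreground is the per-pixel argmax (fish where the fish
#' probability strictly exceeds background); its 8-connected components are
#' the blobs. Each annotation point is assigned to the blob containing it,
#' if any.
#'
#' @param probs `H x W x 2` probability array (channel 1 background, 2 fish).
#' @param points integer matrix of `(row, col)` clicks.
#' @return an `alcfcn_blobs`: label matrix plus per-blob pixel and point sets.
#' @export
find_blobs <- function(probs, points = NULL) {
  points <- normalize_points(points)
  fg <- (prob_channel(probs, 2L) > prob_channel(probs, 1L)) * 1L
  labels <- .cc_label8(fg)
  n_blobs <- max(labels)
  blob_points <- rep(list(integer(0)), n_blobs)
  if (nrow(points) > 0L && n_blobs > 0L) {
    lab_at <- labels[cbind(points[, 1], points[, 2])]
    for (p in which(lab_at > 0L))
      blob_points[[lab_at[p]]] <- c(blob_points[[lab_at[p]]], p)
  }
  blobs <- lapply(seq_len(n_blobs), function(k) {
    list(pixels = which(labels == k), contained_points = blob_points[[k]])
  })
  structure(list(labels = labels, blobs = blobs, points = points),
            class = "alcfcn_blobs")
}

#' Image-level loss
#'
#' For annotated images, `-log` of the maximum fish probability (some pixel
#' must be fish); for empty images, `-log(1 - max fish probability)` (no
#' pixel may be fish).
#'
#' @inheritParams find_blobs
#' @return scalar loss.
#' @export
image_level_loss <- function(probs, points = NULL) {
  image_level_term(probs, points)$value
}

image_level_term <- function(probs, points) {
  points <- normalize_points(points)
  pf <- prob_channel(probs, 2L)
  idx <- which.max(pf)
  grad <- array(0, dim(probs))
  gf <- matrix(0, dim(probs)[1], dim(probs)[2])
  if (nrow(points) > 0L) {
    value <- neg_log(pf[idx])
    gf[idx] <- neg_log_grad(pf[idx])
  } else {
    q <- 1 - pf[idx]
    value <- neg_log(q)
    gf[idx] <- -neg_log_grad(q)   # d/dpf of -log(1 - pf)
  }
  grad[, , 2L] <- gf
  list(value = value, grad = grad)
}

#' Point-level loss
#'
#' Cross-entropy at the annotated pixels: the sum over clicks of `-log` fish
#' probability. Zero when there are no points.
#'
#' @inheritParams find_blobs
#' @return scalar loss.
#' @export
point_level_loss <- function(probs, points = NULL) {
  point_level_term(probs, points)$value
}

point_level_term <- function(probs, points) {
  points <- normalize_points(points)
  grad <- array(0, dim(probs))
  if (nrow(points) == 0L) return(list(value = 0, grad = grad))
  pf <- prob_channel(probs, 2L)
  p_at <- pf[cbind(points[, 1], points[, 2])]
  gf <- matrix(0, dim(probs)[1], dim(probs)[2])
  gf[cbind(points[, 1], points[, 2])] <- neg_log_grad(p_at)
  grad[, , 2L] <- gf
  list(value = sum(neg_log(p_at)), grad = grad)
}

#' Split-level loss
#'
#' For each blob containing two or more annotation points, a seeded watershed
#' (topography = negative fish probability, seeds = the contained points,
#' restricted to the blob) partitions the blob; the watershed-line (dam)
#' pixels where basins meet are pushed towards background with weight equal
#' to the number of points in the blob.
#'
#' @inheritParams find_blobs
#' @param blobs a [find_blobs()] result for `probs`.
#' @return scalar loss.
#' @export
split_level_loss <- function(probs, blobs) {
  split_level_term(probs, blobs)$value
}

split_level_term <- function(probs, blobs) {
  stopifnot(inherits(blobs, "alcfcn_blobs"))
  H <- dim(probs)[1]; W <- dim(probs)[2]
  pb <- prob_channel(probs, 1L)
  value <- 0
  gb <- matrix(0, H, W)
  for (b in blobs$blobs) {
    nb <- length(b$contained_points)
    if (nb < 2L) next
    region <- matrix(FALSE, H, W); region[b$pixels] <- TRUE
    seeds <- matrix(0L, H, W)
    pts <- blobs$points[b$contained_points, , drop = FALSE]
    seeds[cbind(pts[, 1], pts[, 2])] <- seq_len(nb)
    ws <- .watershed_seeded(-prob_channel(probs, 2L), seeds, region)
    ridge <- which(ws == -1L)
    if (length(ridge) == 0L) next
    value <- value + nb * sum(neg_log(pb[ridge]))
    gb[ridge] <- gb[ridge] + nb * neg_log_grad(pb[ridge])
  }
  grad <- array(0, dim(probs))
  grad[, , 1L] <- gb
  list(value = value, grad = grad)
}

#' False-positive loss
#'
#' Every pixel of a blob containing no annotation point is pushed towards
#' background: the sum of `-log` background probability over those pixels.
#'
#' @inheritParams split_level_loss
#' @return scalar loss.
#' @export
false_positive_loss <- function(probs, blobs) {
  false_positive_term(probs, blobs)$value
}

false_positive_term <- function(probs, blobs) {
  stopifnot(inherits(blobs, "alcfcn_blobs"))
  pb <- prob_channel(probs, 1L)
  gb <- matrix(0, dim(probs)[1], dim(probs)[2])
  value <- 0
  for (b in blobs$blobs) {
    if (length(b$contained_points) > 0L) next
    value <- value + sum(neg_log(pb[b$pixels]))
    gb[b$pixels] <- gb[b$pixels] + neg_log_grad(pb[b$pixels])
  }
  grad <- array(0, dim(probs))
  grad[, , 1L] <- gb
  list(value = value, grad = grad)
}

#' The LCFCN loss
#'
#' Sum of the image-level, point-level, split-level and false-positive terms
#' (all with unit coefficients). Together they drive the model towards
#' exactly one predicted blob per annotated fish.
#'
#' @inheritParams find_blobs
#' @param with_grad also return the gradient with respect to `probs`.
#' @return an `alcfcn_loss_report` with fields `total`, `image_level`,
#'   `point_level`, `split_level`, `false_positive` (and attribute `grad`
#'   when requested).
#' @export
lcfcn_loss <- function(probs, points = NULL, with_grad = FALSE) {
  points <- normalize_points(points)
  blobs <- find_blobs(probs, points)
  tI <- image_level_term(probs, points)
  tP <- point_level_term(probs, points)
  tS <- split_level_term(probs, blobs)
  tF <- false_positive_term(probs, blobs)
  rep <- structure(
    list(total = tI$value + tP$value + tS$value + tF$value,
         image_level = tI$value, point_level = tP$value,
         split_level = tS$value, false_positive = tF$value),
    class = "alcfcn_loss_report"
  )
  if (with_grad) attr(rep, "grad") <- tI$grad + tP$grad + tS$grad + tF$grad
  rep
}

#' @export
print.alcfcn_loss_report <- function(x, ...) {
  cat(sprintf("LCFCN loss %.4f (image %.4f + point %.4f + split %.4f + fp %.4f)\n",
              x$total, x$image_level, x$point_level, x$split_level, x$false_positive))
  invisible(x)
}
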