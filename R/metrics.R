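# Evaluation metrics: micro-averaged per-class IoU / mIoU, counting MAE, and
# grid-localised counting error GAME(L).

#' Pool IoU counts over a set of mask pairs
#'
#' True/false positives and false negatives are summed over all images
#' (micro-average) before taking the ratio `IoU = TP / (TP + FP + FN)` per
#' class. A class absent from both prediction and truth (0/0) scores 1.
#'
#' @param pred_masks list of `H x W` binary matrices (predictions).
#' @param true_masks list of matching ground-truth masks.
#' @return an `alcfcn_iou` with pooled counts, per-class IoU and mIoU.
#' @export
iou_accumulate <- function(pred_masks, true_masks) {
  stopifnot(length(pred_masks) == length(true_masks))
  tp <- c(background = 0, foreground = 0)
  fp <- tp; fn <- tp
  for (i in seq_along(pred_masks)) {
    p <- pred_masks[[i]]; g <- true_masks[[i]]
    if (!all(dim(p) == dim(g))) stop("mask shape mismatch at image ", i)
    for (cls in 0:1) {
      pc <- p == cls; gc <- g == cls
      tp[cls + 1L] <- tp[cls + 1L] + sum(pc & gc)
      fp[cls + 1L] <- fp[cls + 1L] + sum(pc & !gc)
      fn[cls + 1L] <- fn[cls + 1L] + sum(!pc & gc)
    }
  }
  iou <- ifelse(tp + fp + fn == 0, 1, tp / (tp + fp + fn))
  structure(
    list(tp = tp, fp = fp, fn = fn,
         iou_background = unname(iou[1]), iou_foreground = unname(iou[2]),
         miou = mean(iou)),
    class = "alcfcn_iou"
  )
}

#' Count predicted instances in a mask
#'
#' The predicted count is the number of 8-connected foreground components
#' (blobs).
#'
#' @param pred_mask `H x W` binary matrix.
#' @return integer count.
#' @export
count_predictions <- function(pred_mask) {
  max(.cc_label8(check_binary_mask(pred_mask)), 0L)
}

#' Mean absolute counting error
#'
#' `MAE = mean(|predicted count - true count|)`, paired per image.
#'
#' @param counts_pred,counts_true equal-length numeric vectors.
#' @return scalar MAE.
#' @export
count_mae <- function(counts_pred, counts_true) {
  if (length(counts_pred) != length(counts_true))
    stop("count vectors have different lengths")
  mean(abs(counts_pred - counts_true))
}

# 0-based grid-cell index of positions `x` in 1..n split into 2^L cells with
# floor(n*k/2^L) boundaries.
grid_cell <- function(x, n, L) {
  if (L == 0) return(rep(0L, length(x)))
  b <- floor(n * seq_len(2^L - 1) / 2^L)
  vapply(x, function(v) sum(v > b), integer(1))
}

blob_centroids <- function(mask) {
  lab <- .cc_label8(check_binary_mask(mask))
  n <- max(lab)
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  t(vapply(seq_len(n), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }, numeric(2)))
}

#' Grid Average Mean Absolute Error
#'
#' Each image is partitioned into a `2^L x 2^L` grid of (near-)equal cells;
#' per cell, the absolute difference between the number of predicted blob
#' centroids and the number of true annotation points falling in it is taken,
#' summed over cells and averaged over images. `GAME(0)` equals the counting
#' MAE; larger `L` additionally penalises mislocalised counts.
#'
#' @param pred_masks list of predicted binary masks (blob centroids are
#'   computed from their 8-connected components).
#' @param true_points list of `(row, col)` point matrices, one per image.
#' @param L grid level (`>= 0`); `L = 4` uses 256 cells.
#' @return scalar GAME(L).
#' @export
game <- function(pred_masks, true_points, L = 4) {
  if (L < 0) stop("GAME level must be >= 0")
  stopifnot(length(pred_masks) == length(true_points))
  per_image <- vapply(seq_along(pred_masks), function(i) {
    m <- pred_masks[[i]]
    H <- nrow(m); W <- ncol(m)
    cent <- blob_centroids(m)
    pts <- normalize_points(true_points[[i]])
    pc <- if (nrow(cent)) grid_cell(cent[, 1], H, L) * 2^L + grid_cell(cent[, 2], W, L) else integer(0)
    tc <- if (nrow(pts)) grid_cell(pts[, 1], H, L) * 2^L + grid_cell(pts[, 2], W, L) else integer(0)
    cells <- sort(unique(c(pc, tc)))
    sum(vapply(cells, function(cl) abs(sum(pc == cl) - sum(tc == cl)), numeric(1)))
  }, numeric(1))
  mean(per_image)
}

#' Full metric report over an evaluation set
#'
#' @param pred_masks list of predicted binary masks.
#' @param true_masks optional list of ground-truth masks (IoU skipped when
#'   absent).
#' @param true_points list of annotation point matrices (for counts and GAME).
#' @param game_levels GAME levels to report.
#' @return an `alcfcn_metrics` list; see [tidy.alcfcn_metrics()].
#' @export
metric_report <- function(pred_masks, true_masks = NULL, true_points,
                          game_levels = c(0, 1, 2, 4)) {
  counts_pred <- vapply(pred_masks, count_predictions, integer(1))
  counts_true <- vapply(true_points, function(p) nrow(normalize_points(p)), integer(1))
  out <- list(
    n_images = length(pred_masks),
    mae = count_mae(counts_pred, counts_true),
    game = setNames(
      vapply(game_levels, function(L) game(pred_masks, true_points, L), numeric(1)),
      paste0("game_", game_levels)
    )
  )
  if (!is.null(true_masks)) {
    iou <- iou_accumulate(pred_masks, true_masks)
    out <- c(out, iou[c("tp", "fp", "fn", "iou_background", "iou_foreground", "miou")])
  }
  structure(out, class = "alcfcn_metrics")
}

#' @export
print.alcfcn_metrics <- function(x, ...) {
  cat(sprintf("<metrics over %d images>\n", x$n_images))
  if (!is.null(x$miou))
    cat(sprintf("  IoU bg %.3f / fg %.3f, mIoU %.3f\n",
                x$iou_background, x$iou_foreground, x$miou))
  cat(sprintf("  MAE %.3f; %s\n", x$mae,
              paste(sprintf("%s %.3f", names(x$game), x$game), collapse = ", ")))
  invisible(x)
}

#' Tidy a metric report
#' @param x an `alcfcn_metrics`.
#' @param ... unused.
#' @return a tibble with one row per metric (`metric`, `value`).
#' @export
tidy.alcfcn_metrics <- function(x, ...) {
  vals <- c(
    if (!is.null(x$miou)) c(iou_background = x$iou_background,
                            iou_foreground = x$iou_foreground, miou = x$miou),
    mae = x$mae, x$game
  )
  tibble::tibble(metric = names(vals), value = unname(vals))
}
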