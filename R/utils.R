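# Internal numeric helpers shared across modules.

.op_cache <- new.env(parent = emptyenv())

#' Sparse bilinear interpolation operator
#'
#' Builds the (`H*W`) x (`h*w`) sparse matrix that maps a column-major
#' flattened `h` x `w` grid to its bilinear resampling at `H` x `W`
#' (half-pixel-centre convention). Cached per geometry, so repeated
#' forward/backward passes reuse the same operator; the transpose of the
#' returned matrix is the exact adjoint used during backpropagation.
#'
#' @param h,w source grid size.
#' @param H,W target grid size.
#' @return a `dgCMatrix` of interpolation weights; rows sum to 1.
#' @keywords internal
bilinear_operator <- function(h, w, H, W) {
  key <- paste("bil", h, w, H, W, sep = "_")
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  # continuous source coordinate of each target pixel centre (1-based)
  src <- function(i, n_to, n_from) (i - 0.5) * (n_from / n_to) + 0.5
  ur <- src(seq_len(H), H, h)
  uc <- src(seq_len(W), W, w)
  r0 <- pmin(pmax(floor(ur), 1), h); fr <- pmin(pmax(ur - r0, 0), 1)
  c0 <- pmin(pmax(floor(uc), 1), w); fc <- pmin(pmax(uc - c0, 0), 1)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr[r1 == r0] <- 0; fc[c1 == c0] <- 0
  # outer combination of row/col anchors
  rows <- rep(seq_len(H), times = W)
  cols <- rep(seq_len(W), each = H)
  i_out <- rep(seq_len(H * W), 4L)
  j_src <- c(
    (c0[cols] - 1) * h + r0[rows],
    (c0[cols] - 1) * h + r1[rows],
    (c1[cols] - 1) * h + r0[rows],
    (c1[cols] - 1) * h + r1[rows]
  )
  wgt <- c(
    (1 - fr[rows]) * (1 - fc[cols]),
    fr[rows] * (1 - fc[cols]),
    (1 - fr[rows]) * fc[cols],
    fr[rows] * fc[cols]
  )
  keep <- wgt > 0
  op <- Matrix::sparseMatrix(
    i = i_out[keep], j = j_src[keep], x = wgt[keep],
    dims = c(H * W, h * w)
  )
  .op_cache[[key]] <- op
  op
}

# Nearest-neighbour index map from (h, w) to (H, W); returns linear indices
# into the source for each target pixel (column-major).
nearest_index <- function(h, w, H, W) {
  src <- function(i, n_to, n_from) pmin(pmax(round((i - 0.5) * (n_from / n_to) + 0.5), 1), n_from)
  r <- src(seq_len(H), H, h)
  c <- src(seq_len(W), W, w)
  (rep(c, each = H) - 1) * h + rep(r, times = W)
}

# Resize an H x W matrix bilinearly (for images) to (H2, W2).
resize_bilinear <- function(m, H2, W2) {
  op <- bilinear_operator(nrow(m), ncol(m), H2, W2)
  matrix(as.numeric(op %*% as.vector(m)), H2, W2)
}

# Resize a label matrix with nearest-neighbour sampling.
resize_nearest <- function(m, H2, W2) {
  idx <- nearest_index(nrow(m), ncol(m), H2, W2)
  matrix(m[idx], H2, W2)
}

# Numerically stable two-class softmax on an n x 2 matrix of scores.
softmax2 <- function(s) {
  m <- pmax(s[, 1L], s[, 2L])
  e1 <- exp(s[, 1L] - m); e2 <- exp(s[, 2L] - m)
  z <- e1 + e2
  cbind(e1 / z, e2 / z)
}

# Probability floor used by every -log() term in the losses.
PROB_EPS <- 1e-8

neg_log <- function(p) -log(pmax(p, PROB_EPS))

# Gradient of -log(clamp(p)): zero where the clamp is active.
neg_log_grad <- function(p) ifelse(p > PROB_EPS, -1 / p, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Channel slice of an H x W x C array that never drops to a vector.
prob_channel <- function(a, k) matrix(a[, , k], dim(a)[1], dim(a)[2])
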