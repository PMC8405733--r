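# Minimal convolution engine: im2col forward, exact adjoint backward.
# Geometry-dependent index structures are cached, so a training loop touching
# a fixed image size pays the indexing cost once.

conv_geom <- function(H, W, Cin, k, stride, pad) {
  key <- paste("conv", H, W, Cin, k, stride, pad, sep = "_")
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  out_r <- rep(seq_len(Ho), times = Wo)
  out_c <- rep(seq_len(Wo), each = Ho)
  top <- (out_r - 1L) * stride   # 0-based offsets of each patch in padded input
  left <- (out_c - 1L) * stride
  # patch-position offsets (column-major within k x k x Cin)
  pr <- rep(seq_len(k) - 1L, times = k * Cin)
  pc <- rep(rep(seq_len(k) - 1L, each = k), times = Cin)
  pch <- rep(seq_len(Cin) - 1L, each = k * k)
  # linear index into padded array (Hp x Wp x Cin), column-major, 1-based
  idx <- outer(top + left * Hp, pr + pc * Hp + pch * (Hp * Wp), `+`) + 1L
  storage.mode(idx) <- "integer"
  # scatter matrix for the input gradient: maps vec(dPatches) back to padded grid
  G <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx),
                            x = 1, dims = c(Hp * Wp * Cin, length(idx)))
  geom <- list(H = H, W = W, Cin = Cin, k = k, stride = stride, pad = pad,
               Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, idx = idx, scatter = G)
  .op_cache[[key]] <- geom
  geom
}

pad_input <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# Forward 3x3 (or kxk) convolution + bias. weights: (k*k*Cin) x Cout matrix.
# Returns list(out = Ho x Wo x Cout array, cache for backward).
conv2d_forward <- function(x, weights, bias, k, stride, pad) {
  d <- dim(x)
  g <- conv_geom(d[1], d[2], d[3], k, stride, pad)
  xp <- pad_input(x, pad)
  P <- matrix(as.vector(xp)[g$idx], nrow(g$idx), ncol(g$idx))
  out <- P %*% weights
  out <- sweep(out, 2L, bias, `+`)
  list(out = array(out, c(g$Ho, g$Wo, ncol(weights))), P = P, geom = g)
}

# Backward pass; grad_out is Ho x Wo x Cout. Returns gradients for weights,
# bias, and the input (H x W x Cin).
conv2d_backward <- function(cache, weights, grad_out) {
  g <- cache$geom
  GO <- matrix(grad_out, g$Ho * g$Wo, ncol(weights))
  dW <- crossprod(cache$P, GO)
  db <- colSums(GO)
  dP <- GO %*% t(weights)
  dxp <- as.numeric(g$scatter %*% as.vector(dP))
  dxp <- array(dxp, c(g$Hp, g$Wp, g$Cin))
  dx <- if (g$pad > 0)
    dxp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , drop = FALSE]
  else dxp
  list(weights = dW, bias = db, input = dx)
}

# 1x1 convolution is a per-pixel linear map: x is (n_pix x Cin).
conv1x1_forward <- function(xmat, weights, bias) {
  sweep(xmat %*% weights, 2L, bias, `+`)
}

relu <- function(x) pmax(x, 0)
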