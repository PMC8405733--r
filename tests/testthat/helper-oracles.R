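# Independent brute-force oracles, written plainly and kept free of the
# package's internal code paths.

# 8-connected component labeling by BFS flood fill.
oracle_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (c in seq_len(W)) for (r in seq_len(H)) {
    if (mask[r, c] == 0 || lab[r, c] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(r, c)); lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        nr <- p[1] + dr; nc <- p[2] + dc
        if (nr < 1 || nr > H || nc < 1 || nc > W) next
        if (mask[nr, nc] != 0 && lab[nr, nc] == 0) {
          lab[nr, nc] <- nxt
          queue[[length(queue) + 1]] <- c(nr, nc)
        }
      }
    }
  }
  lab
}

# Per-pixel Euclidean distance to the nearest background (0) pixel.
oracle_distance_transform <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- which(mask == 0, arr.ind = TRUE)
  dt <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (mask[r, c] == 0) next
    dt[r, c] <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  }
  dt
}

# Max-distance-transform point per component, ties by smallest row then col.
oracle_points_from_mask <- function(mask) {
  lab <- oracle_label8(mask)
  dt <- oracle_distance_transform(mask)
  n <- max(lab)
  if (n == 0) return(matrix(integer(0), ncol = 2))
  out <- matrix(0L, n, 2)
  for (k in seq_len(n)) {
    best <- c(NA, NA); bestd <- -1
    for (c in seq_len(ncol(mask))) for (r in seq_len(nrow(mask))) {
      if (lab[r, c] != k) next
      if (dt[r, c] > bestd ||
          (dt[r, c] == bestd && (r < best[1] || (r == best[1] && c < best[2])))) {
        bestd <- dt[r, c]; best <- c(r, c)
      }
    }
    out[k, ] <- best
  }
  out
}

# Dense transition matrix D^-1 W^beta from a dense affinity matrix.
oracle_transition <- function(W, beta) {
  U <- W^beta
  U / rowSums(U)
}

# t-step random walk by explicit dense matrix powers.
oracle_random_walk <- function(Tdense, v, t) {
  out <- v
  if (t > 0) for (k in seq_len(t)) out <- Tdense %*% out
  out
}

# Meyer flooding with watershed lines, plain R: pixels popped from a
# min-height frontier; a pixel seeing two basin labels becomes a dam (-1).
oracle_watershed <- function(topo, seeds, region) {
  H <- nrow(topo); W <- ncol(topo)
  lab <- matrix(0L, H, W)
  lab[seeds > 0 & region] <- seeds[seeds > 0 & region]
  frontier_h <- numeric(0); frontier_o <- numeric(0); frontier_i <- integer(0)
  queued <- matrix(FALSE, H, W)
  ord <- 0
  push_nb <- function(r, c) {
    for (dc in -1:1) for (dr in -1:1) {
      if (dr == 0 && dc == 0) next
      nr <- r + dr; nc <- c + dc
      if (nr < 1 || nr > H || nc < 1 || nc > W) next
      if (!region[nr, nc] || lab[nr, nc] != 0 || queued[nr, nc]) next
      queued[nr, nc] <<- TRUE
      ord <<- ord + 1
      frontier_h <<- c(frontier_h, topo[nr, nc])
      frontier_o <<- c(frontier_o, ord)
      frontier_i <<- c(frontier_i, (nc - 1) * H + nr)
    }
  }
  for (c in seq_len(W)) for (r in seq_len(H))
    if (region[r, c] && seeds[r, c] > 0) push_nb(r, c)
  while (length(frontier_i)) {
    k <- order(frontier_h, frontier_o)[1]
    idx <- frontier_i[k]
    frontier_h <- frontier_h[-k]; frontier_o <- frontier_o[-k]; frontier_i <- frontier_i[-k]
    r <- (idx - 1) %% H + 1; c <- (idx - 1) %/% H + 1
    labs <- integer(0)
    for (dc in -1:1) for (dr in -1:1) {
      if (dr == 0 && dc == 0) next
      nr <- r + dr; nc <- c + dc
      if (nr < 1 || nr > H || nc < 1 || nc > W) next
      if (lab[nr, nc] > 0) labs <- c(labs, lab[nr, nc])
    }
    u <- unique(labs)
    if (length(u) == 1) {
      lab[r, c] <- u
      push_nb(r, c)
    } else {
      lab[r, c] <- -1L
    }
  }
  lab
}

# Straight-line reimplementation of the four LCFCN loss terms.
oracle_lcfcn <- function(probs, points) {
  eps <- 1e-8
  nlog <- function(p) -log(pmax(p, eps))
  pf <- probs[, , 2]; pb <- probs[, , 1]
  n_pts <- if (is.null(points)) 0 else nrow(points)
  # image-level
  L_I <- if (n_pts > 0) nlog(max(pf)) else nlog(1 - max(pf))
  # point-level
  L_P <- 0
  if (n_pts > 0) for (i in seq_len(n_pts)) L_P <- L_P + nlog(pf[points[i, 1], points[i, 2]])
  # blobs
  fg <- (pf > pb) * 1L
  lab <- oracle_label8(fg)
  n_blobs <- max(lab)
  L_S <- 0; L_F <- 0
  if (n_blobs > 0) for (k in seq_len(n_blobs)) {
    inside <- integer(0)
    if (n_pts > 0) for (i in seq_len(n_pts))
      if (lab[points[i, 1], points[i, 2]] == k) inside <- c(inside, i)
    if (length(inside) == 0) {
      L_F <- L_F + sum(nlog(pb[lab == k]))
    } else if (length(inside) >= 2) {
      seeds <- matrix(0L, nrow(pf), ncol(pf))
      for (j in seq_along(inside))
        seeds[points[inside[j], 1], points[inside[j], 2]] <- j
      ws <- oracle_watershed(-pf, seeds, lab == k)
      ridge <- ws == -1
      L_S <- L_S + length(inside) * sum(nlog(pb[ridge]))
    }
  }
  list(image = L_I, point = L_P, split = L_S, fp = L_F,
       total = L_I + L_P + L_S + L_F)
}

# Pixel-counting IoU over a set (micro-average), 0/0 -> 1.
oracle_iou <- function(preds, trues) {
  tp <- c(0, 0); fp <- c(0, 0); fn <- c(0, 0)
  for (i in seq_along(preds)) for (cls in 0:1) {
    p <- preds[[i]] == cls; g <- trues[[i]] == cls
    tp[cls + 1] <- tp[cls + 1] + sum(p & g)
    fp[cls + 1] <- fp[cls + 1] + sum(p & !g)
    fn[cls + 1] <- fn[cls + 1] + sum(!p & g)
  }
  iou <- ifelse(tp + fp + fn == 0, 1, tp / (tp + fp + fn))
  list(bg = iou[1], fg = iou[2], miou = mean(iou))
}

# Cell-counting GAME by explicit per-cell loops over floor-partitioned grids.
oracle_game <- function(pred_masks, true_points, L) {
  per <- numeric(length(pred_masks))
  for (i in seq_along(pred_masks)) {
    m <- pred_masks[[i]]
    H <- nrow(m); W <- ncol(m)
    lab <- oracle_label8(m)
    cent <- NULL
    if (max(lab) > 0) {
      cent <- t(sapply(seq_len(max(lab)), function(k) {
        idx <- which(lab == k, arr.ind = TRUE)
        c(mean(idx[, 1]), mean(idx[, 2]))
      }))
    }
    pts <- true_points[[i]]
    tot <- 0
    for (kr in 0:(2^L - 1)) for (kc in 0:(2^L - 1)) {
      r_lo <- floor(H * kr / 2^L); r_hi <- floor(H * (kr + 1) / 2^L)
      c_lo <- floor(W * kc / 2^L); c_hi <- floor(W * (kc + 1) / 2^L)
      np <- 0
      if (!is.null(cent) && nrow(cent) > 0)
        np <- sum(cent[, 1] > r_lo & cent[, 1] <= r_hi &
                  cent[, 2] > c_lo & cent[, 2] <= c_hi)
      nt <- 0
      if (!is.null(pts) && nrow(pts) > 0)
        nt <- sum(pts[, 1] > r_lo & pts[, 1] <= r_hi &
                  pts[, 2] > c_lo & pts[, 2] <= c_hi)
      tot <- tot + abs(np - nt)
    }
    per[i] <- tot
  }
  mean(per)
}

# Random two-channel probability map.
random_probmap <- function(H, W) {
  a <- matrix(runif(H * W, 0.01, 0.99), H, W)
  probs <- array(0, c(H, W, 2))
  probs[, , 1] <- 1 - a
  probs[, , 2] <- a
  probs
}

# Random binary mask with a few blobby rectangles.
random_mask <- function(H, W, n_blocks = 3) {
  m <- matrix(0L, H, W)
  for (b in seq_len(sample(0:n_blocks, 1))) {
    r <- sort(sample(H, 2)); c <- sort(sample(W, 2))
    m[r[1]:r[2], c[1]:c[2]] <- 1L
  }
  m
}
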