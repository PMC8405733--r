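# Pairwise pixel-affinity graph, transition operator, and random-walk
# refinement of activation maps.
#
# Affinities follow the AffinityNet form: for feature vectors f_i, f_j on the
# backbone-stride grid, W_ij = exp(-||f_i - f_j||_1), restricted to pixel
# pairs within a Euclidean grid radius. The transition operator is the
# row-normalised Hadamard power, T = D^-1 W^beta with D_ii = sum_j W_ij^beta,
# and refinement applies T to each class channel t times. All three steps are
# differentiable; the *_backward() functions implement the exact adjoints used
# during end-to-end training.
#
# The neighbourhood structure, sparse pattern and the index machinery used by
# the adjoints depend only on (h, w, radius), so they are built once per
# geometry and cached; per-step work is limited to the feature-dependent
# values.

# Canonical half of the neighbourhood: offsets (dr, dc) with dc > 0, or
# dc == 0 and dr > 0, within Euclidean distance `radius`.
neighbour_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = 0:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 & (g$dc > 0 | (g$dc == 0 & g$dr > 0)), ]
  as.matrix(g)
}

# Geometry-level structures shared by every graph on the same grid.
graph_geometry <- function(h, w, radius) {
  key <- paste("geom", h, w, radius, sep = "_")
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  off <- neighbour_offsets(radius)
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    if (abs(dr) >= h || dc >= w) next
    rows <- seq_len(h - abs(dr))
    if (dr < 0) rows <- rows + abs(dr)
    cols <- seq_len(w - dc)          # canonical offsets have dc >= 0
    if (length(rows) == 0L || length(cols) == 0L) next
    i <- as.vector(outer(rows, (cols - 1) * h, `+`))
    j <- i + dc * h + dr
    ii <- c(ii, i); jj <- c(jj, j)
  }
  n <- h * w
  np <- length(ii)
  i_all <- c(ii, jj, seq_len(n))
  j_all <- c(jj, ii, seq_len(n))
  # CSC template; filling @x with triplet ids recovers the storage order
  perm <- Matrix::sparseMatrix(i = i_all, j = j_all, x = as.numeric(seq_along(i_all)),
                               dims = c(n, n))
  triplet_of_slot <- as.integer(perm@x)
  slot_of_triplet <- integer(length(i_all))
  slot_of_triplet[triplet_of_slot] <- seq_along(perm@x)
  nnz_row <- perm@i + 1L
  nnz_col <- rep(seq_len(n), diff(perm@p))
  # row aggregation over nonzeros, and pair->node incidence for dF
  rowagg <- Matrix::sparseMatrix(i = nnz_row, j = seq_along(nnz_row), x = 1,
                                 dims = c(n, length(nnz_row)))
  incid <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(seq_len(np), seq_len(np)), x = c(rep(-1, np), rep(1, np)),
    dims = c(n, np)
  )
  geom <- list(h = h, w = w, radius = radius, n = n, n_pairs = np,
               pair_i = ii, pair_j = jj,
               template = perm, slot_of_triplet = slot_of_triplet,
               triplet_of_slot = triplet_of_slot,
               nnz_row = nnz_row, nnz_col = nnz_col,
               rowagg = rowagg, incid = incid)
  .op_cache[[key]] <- geom
  geom
}

#' Build the local pixel-affinity graph
#'
#' Connects every pair of grid cells within Euclidean distance `radius` and
#' weights the edge by `exp(-L1)` of the corresponding affinity feature
#' vectors. Self-pairs always carry weight 1 (`exp(0)`); the graph is
#' symmetric by construction and stored as a canonical pair list, so memory
#' scales with the number of neighbour pairs, not with `(h*w)^2`.
#'
#' @param features `h x w x d` numeric array of affinity features.
#' @param radius neighbourhood radius in grid cells (`>= 1`).
#' @return an `alcfcn_graph` with the pair list, weights and grid geometry.
#' @export
build_affinity_graph <- function(features, radius = 5) {
  stopifnot(length(dim(features)) == 3L)
  if (radius < 1) stop("affinity radius must be >= 1")
  if (!all(is.finite(features))) stop("affinity features must be finite")
  h <- dim(features)[1]; w <- dim(features)[2]; d <- dim(features)[3]
  geom <- graph_geometry(h, w, radius)
  fmat <- matrix(features, h * w, d)
  wgt <- if (geom$n_pairs)
    exp(-rowSums(abs(fmat[geom$pair_i, , drop = FALSE] -
                     fmat[geom$pair_j, , drop = FALSE])))
  else numeric(0)
  structure(
    list(h = h, w = w, d = d, radius = radius,
         pair_i = geom$pair_i, pair_j = geom$pair_j, weight = wgt,
         geom = geom),
    class = "alcfcn_graph"
  )
}

# Dense symmetric W (unit diagonal) -- used by tests and small oracles.
graph_dense_w <- function(graph) {
  n <- graph$h * graph$w
  W <- diag(1, n)
  W[cbind(graph$pair_i, graph$pair_j)] <- graph$weight
  W[cbind(graph$pair_j, graph$pair_i)] <- graph$weight
  W
}

#' Convert an affinity graph to a random-walk transition operator
#'
#' Applies the element-wise (Hadamard) power `beta` to the affinity weights,
#' then normalises each row by its sum: `T = D^-1 W^beta`. Larger `beta`
#' sharpens the affinities, making the subsequent propagation more
#' conservative.
#'
#' @param graph an [build_affinity_graph()] result.
#' @param beta Hadamard exponent (`>= 1`).
#' @return an `alcfcn_transition` holding the sparse row-stochastic matrix.
#' @export
build_transition <- function(graph, beta = 8) {
  stopifnot(inherits(graph, "alcfcn_graph"))
  if (beta < 1) stop("beta must be >= 1")
  geom <- graph$geom
  wb <- graph$weight^beta
  x_triplet <- c(wb, wb, rep(1, geom$n))
  U <- geom$template
  U@x <- x_triplet[geom$triplet_of_slot]  # place values in CSC order
  deg <- Matrix::rowSums(U)
  Tm <- U
  Tm@x <- U@x / deg[geom$nnz_row]
  structure(
    list(T = Tm, beta = beta, degree = deg, graph = graph,
         nnz_row = geom$nnz_row, nnz_col = geom$nnz_col,
         n_pairs = geom$n_pairs),
    class = "alcfcn_transition"
  )
}

#' Refine an activation map by random walk
#'
#' Flattens each class channel (column-major) and applies the transition
#' operator `iterations` times: `v <- T^t v`. With `iterations = 0` the input
#' is returned unchanged.
#'
#' @param activations `h x w x C` numeric array at the operator's grid size.
#' @param operator an [build_transition()] result.
#' @param iterations number of walk steps `t >= 0`.
#' @return refined `h x w x C` array.
#' @export
random_walk_refine <- function(activations, operator, iterations = 8) {
  rw_forward(activations, operator, iterations)$out
}

# Forward pass keeping the per-step trajectory for backpropagation.
rw_forward <- function(activations, operator, iterations) {
  stopifnot(inherits(operator, "alcfcn_transition"), iterations >= 0)
  d <- dim(activations)
  h <- operator$graph$h; w <- operator$graph$w
  if (d[1] != h || d[2] != w)
    stop(sprintf("activation grid %dx%d does not match operator grid %dx%d",
                 d[1], d[2], h, w))
  C <- d[3]
  V <- matrix(activations, h * w, C)
  traj <- vector("list", iterations + 1L)
  traj[[1L]] <- V
  if (iterations > 0) for (k in seq_len(iterations)) {
    V <- as.matrix(operator$T %*% V)
    traj[[k + 1L]] <- V
  }
  list(out = array(V, c(h, w, C)), traj = traj)
}

# Adjoint of rw_forward: returns the gradient w.r.t. the input activations and
# w.r.t. the nonzero entries of T (aligned with operator$nnz_*).
rw_backward <- function(operator, traj, grad_out) {
  t_iter <- length(traj) - 1L
  n <- nrow(traj[[1L]]); C <- ncol(traj[[1L]])
  A <- matrix(grad_out, n, C)
  gT <- numeric(length(operator$nnz_row))
  Tt <- Matrix::t(operator$T)
  if (t_iter > 0) for (k in t_iter:1) {
    Vprev <- traj[[k]]
    # sum over channels of A[i] * Vprev[j] on the sparsity pattern
    gT <- gT + rowSums(A[operator$nnz_row, , drop = FALSE] *
                       Vprev[operator$nnz_col, , drop = FALSE])
    A <- as.matrix(Tt %*% A)
  }
  list(grad_activations = A, grad_T = gT)
}

# Adjoint of build_transition: gradient w.r.t. T's nonzeros -> gradient
# w.r.t. the pair weights W_p (self-weights are constant 1 and get none).
transition_backward <- function(operator, grad_T) {
  geom <- operator$graph$geom
  deg <- operator$degree
  ir <- operator$nnz_row
  # d/dU_ij of sum G o T, with T_ij = U_ij / deg_i:
  rowdot <- as.numeric(geom$rowagg %*% (grad_T * operator$T@x))
  dU <- (grad_T - rowdot[ir]) / deg[ir]
  # chain through U = W^beta; route CSC slots back to triplets, then pairs
  beta <- operator$beta
  np <- geom$n_pairs
  dU_triplet <- dU[geom$slot_of_triplet]       # triplet order: (i,j), (j,i), diag
  dU_pair <- dU_triplet[seq_len(np)] + dU_triplet[np + seq_len(np)]
  beta * operator$graph$weight^(beta - 1) * dU_pair
}

# Adjoint of build_affinity_graph: gradient w.r.t. pair weights -> gradient
# w.r.t. the affinity features (h*w x d matrix).
graph_backward <- function(graph, features, grad_w) {
  h <- graph$h; w <- graph$w; d <- graph$d
  fmat <- matrix(features, h * w, d)
  if (graph$geom$n_pairs == 0L) return(matrix(0, h * w, d))
  S <- sign(fmat[graph$pair_i, , drop = FALSE] - fmat[graph$pair_j, , drop = FALSE])
  contrib <- (grad_w * graph$weight) * S   # dW/dF_i = -W * sign(F_i - F_j)
  as.matrix(graph$geom$incid %*% contrib)
}
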