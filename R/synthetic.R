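# Synthetic underwater-style scenes: low-contrast deformable elliptical
# "fish" on a smoothly textured background, with ground-truth masks, counts,
# and point annotations derived by the max-distance-transform rule. The
# generator makes the full pipeline testable without any external dataset.

#' Scene-generator specification
#'
#' @param height,width image size in pixels.
#' @param n_fish_range `(min, max)` number of fish per image.
#' @param fish_scale_range `(min, max)` semi-major axis in pixels.
#' @param contrast foreground/background intensity separation in `(0, 1]`;
#'   the default emulates the low-contrast regime of real underwater imagery.
#' @param texture_strength amplitude of the background texture (`>= 0`).
#' @param occlusion_prob probability that a fish is placed overlapping a
#'   previous one.
#' @param seed optional integer seed stored with the spec.
#' @return an `alcfcn_scene_spec`.
#' @export
scene_spec <- function(height = 96, width = 96, n_fish_range = c(0, 3),
                       fish_scale_range = c(6, 12), contrast = 0.25,
                       texture_strength = 0.5, occlusion_prob = 0.1,
                       seed = NULL) {
  stopifnot(height >= 8, width >= 8,
            length(n_fish_range) == 2L, n_fish_range[1] <= n_fish_range[2],
            length(fish_scale_range) == 2L,
            fish_scale_range[1] <= fish_scale_range[2],
            contrast > 0, contrast <= 1, texture_strength >= 0,
            occlusion_prob >= 0, occlusion_prob <= 1)
  structure(
    list(height = height, width = width, n_fish_range = n_fish_range,
         fish_scale_range = fish_scale_range, contrast = contrast,
         texture_strength = texture_strength, occlusion_prob = occlusion_prob,
         seed = seed),
    class = "alcfcn_scene_spec"
  )
}

#' High-contrast preset for fast mechanism tests
#' @param ... overrides passed to [scene_spec()].
#' @return an `alcfcn_scene_spec` with `contrast = 0.8`.
#' @export
easy_scene_spec <- function(...) {
  args <- utils::modifyList(list(contrast = 0.8), list(...))
  do.call(scene_spec, args)
}

# Smooth noise field: coarse Gaussian noise bilinearly upsampled.
smooth_noise <- function(H, W, cell = 8) {
  h <- max(2L, ceiling(H / cell)); w <- max(2L, ceiling(W / cell))
  resize_bilinear(matrix(stats::rnorm(h * w), h, w), H, W)
}

# Rasterise one randomly rotated, sinusoidally deformed ellipse.
rasterize_fish <- function(H, W, cy, cx, a, b, theta, amp, freq, phase) {
  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- row - cy; dx <- col - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  phi <- atan2(v / b, u / a)
  r <- sqrt((u / a)^2 + (v / b)^2)
  (r <= 1 + amp * sin(freq * phi + phase)) * 1L
}

dilate1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  out <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1)
    out <- out | pad[(2:(H + 1L)) + dr, (2:(W + 1L)) + dc]
  out * 1L
}

#' Generate one synthetic scene
#'
#' Draws a textured background, places the requested number of deformed
#' elliptical fish (optionally overlapping with probability
#' `occlusion_prob`), and derives the mask, count and point annotations. With
#' a fixed seed the scene is bit-identical across calls.
#'
#' @param spec an [scene_spec()].
#' @param id scene identifier.
#' @param seed integer seed; defaults to the spec's seed (or the current RNG
#'   state when both are `NULL`).
#' @param split split tag for the resulting scene.
#' @return an [scene()] with image, mask and derived points.
#' @export
generate_scene <- function(spec, id = "scene", seed = spec$seed, split = "train") {
  stopifnot(inherits(spec, "alcfcn_scene_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  H <- spec$height; W <- spec$width
  bg <- 0.4 + spec$texture_strength * (0.15 * smooth_noise(H, W, 8) +
                                       0.05 * smooth_noise(H, W, 2))
  counts <- seq(spec$n_fish_range[1], spec$n_fish_range[2])
  n_fish <- counts[sample.int(length(counts), 1L)]
  mask <- matrix(0L, H, W)
  shading <- matrix(0, H, W)
  placed <- 0L
  tries <- 0L
  while (placed < n_fish && tries < 200L) {
    tries <- tries + 1L
    a <- stats::runif(1, spec$fish_scale_range[1], spec$fish_scale_range[2])
    b <- a * stats::runif(1, 0.4, 0.7)
    amp <- stats::runif(1, 0.05, 0.2)
    margin <- a * (1 + amp) + 1
    occlude <- placed > 0L && stats::runif(1) < spec$occlusion_prob
    if (occlude) {
      prev <- which(mask == 1L, arr.ind = TRUE)
      anchor <- prev[sample.int(nrow(prev), 1L), ]
      cy <- min(max(anchor[1] + stats::rnorm(1, 0, a / 2), margin), H - margin + 1)
      cx <- min(max(anchor[2] + stats::rnorm(1, 0, a / 2), margin), W - margin + 1)
    } else {
      cy <- stats::runif(1, margin, H - margin + 1)
      cx <- stats::runif(1, margin, W - margin + 1)
    }
    fish <- rasterize_fish(H, W, cy, cx, a, b,
                           theta = stats::runif(1, 0, pi),
                           amp = amp, freq = sample(2:4, 1L),
                           phase = stats::runif(1, 0, 2 * pi))
    if (sum(fish) < 8L) next
    if (!occlude && any(fish & dilate1(mask))) next  # keep instances separate
    mask <- pmax(mask, fish)
    shading <- shading + fish * spec$contrast * stats::runif(1, 0.85, 1)
    placed <- placed + 1L
  }
  img <- pmin(pmax(bg + pmin(shading, spec$contrast), 0), 1)
  points <- derive_points_from_mask(mask)
  scene(id, array(rep(img, 3L), c(H, W, 3L)), points, mask, split)
}

#' Generate a full train/val/test split
#'
#' Scene seeds for the three splits are drawn from disjoint, seed-derived
#' streams, so regenerating with the same arguments reproduces the dataset
#' exactly. When `root` is given the dataset is also written to disk in the
#' standard folder layout (images/, points/, masks/, split listings).
#'
#' @param spec an [scene_spec()].
#' @param n_train,n_val,n_test split sizes.
#' @param seed integer master seed.
#' @param root optional output directory.
#' @return an `alcfcn_manifest` (invisibly when writing to disk).
#' @export
generate_split <- function(spec, n_train, n_val, n_test, seed = 1L, root = NULL) {
  stopifnot(n_train >= 0, n_val >= 0, n_test >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  total <- n_train + n_val + n_test
  scene_seeds <- sample.int(.Machine$integer.max - 1L, max(total, 1L))
  splits <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  scenes <- vector("list", total)
  counters <- c(train = 0L, val = 0L, test = 0L)
  for (i in seq_len(total)) {
    sp <- splits[i]
    counters[sp] <- counters[sp] + 1L
    id <- sprintf("%s_%04d", sp, counters[sp])
    scenes[[i]] <- generate_scene(spec, id = id, seed = scene_seeds[i], split = sp)
  }
  man <- manifest(scenes)
  if (!is.null(root)) {
    write_manifest(man, root)
    return(invisible(man))
  }
  man
}

#' Write a manifest to disk in the standard layout
#' @param man an `alcfcn_manifest`.
#' @param root output directory (created if needed).
#' @export
write_manifest <- function(man, root) {
  for (sp in c("train", "val", "test")) {
    sc <- split_scenes(man, sp)
    if (length(sc) == 0L) next
    for (d in c("images", "points", "masks"))
      dir.create(file.path(root, d, sp), recursive = TRUE, showWarnings = FALSE)
    writeLines(vapply(sc, function(s) s$id, character(1)),
               file.path(root, paste0(sp, ".txt")))
    for (s in sc) {
      png::writePNG(s$image, file.path(root, "images", sp, paste0(s$id, ".png")))
      write_points_map(s$points, dim(s$image)[1], dim(s$image)[2],
                       file.path(root, "points", sp, paste0(s$id, ".png")))
      if (!is.null(s$mask))
        write_mask(s$mask, file.path(root, "masks", sp, paste0(s$id, ".png")))
    }
  }
  invisible(root)
}
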