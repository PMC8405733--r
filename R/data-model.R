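# Scenes, dataset layout, and point-annotation derivation.
#
# A dataset on disk mirrors the DeepFish folder convention:
#   root/<split>.txt             one scene id per line
#   root/images/<split>/<id>.png RGB (or grayscale) image
#   root/points/<split>/<id>.png single-channel map, non-zero pixels = clicks
#   root/masks/<split>/<id>.png  single-channel {0,255} ground-truth mask
# masks/ entries are optional per scene.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD   <- c(0.229, 0.224, 0.225)

#' Construct a scene
#'
#' A scene bundles one image with its point-level annotations (one click per
#' fish) and, when available, a full binary segmentation mask.
#'
#' @param id scene identifier (string).
#' @param image `H x W x 3` numeric array with values in `[0, 1]`.
#' @param points integer matrix with columns `(row, col)` (1-based), one row
#'   per annotated fish; `NULL` or a 0-row matrix means no fish.
#' @param mask optional `H x W` matrix with values in `{0, 1}`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return an object of class `alcfcn_scene`.
#' @export
scene <- function(id, image, points = NULL, mask = NULL, split = "train") {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  H <- dim(image)[1]; W <- dim(image)[2]
  points <- normalize_points(points)
  split <- match.arg(split, c("train", "val", "test"))
  if (nrow(points) > 0L) {
    if (any(points[, 1] < 1L | points[, 1] > H | points[, 2] < 1L | points[, 2] > W))
      stop("scene '", id, "': point outside image bounds")
    if (anyDuplicated(points))
      stop("scene '", id, "': duplicated points")
  }
  if (!is.null(mask)) {
    mask <- check_binary_mask(mask)
    stopifnot(all(dim(mask) == c(H, W)))
    if (nrow(points) > 0L) {
      on_fg <- mask[cbind(points[, 1], points[, 2])] == 1
      if (!all(on_fg))
        warning("scene '", id, "': ", sum(!on_fg),
                " point(s) fall outside the mask foreground; kept as annotated")
    }
  }
  structure(
    list(id = id, image = image, points = points, mask = mask, split = split),
    class = "alcfcn_scene"
  )
}

normalize_points <- function(points) {
  if (is.null(points) || length(points) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("row", "col"))))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  storage.mode(points) <- "integer"
  colnames(points) <- c("row", "col")
  points
}

check_binary_mask <- function(mask) {
  mask <- as.matrix(mask)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1))) stop("mask is not binary (values other than {0,1} found)")
  storage.mode(mask) <- "integer"
  mask
}

#' @export
print.alcfcn_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<scene '%s'> %dx%d, %d point(s), mask: %s, split: %s\n",
              x$id, d[1], d[2], nrow(x$points),
              if (is.null(x$mask)) "no" else "yes", x$split))
  invisible(x)
}

#' Derive point annotations from a segmentation mask
#'
#' One point per 8-connected foreground component: the pixel of that component
#' with the largest Euclidean distance transform (distance to the nearest
#' background pixel). This is the convention used to turn full masks into
#' point-level supervision. Ties are broken by smallest row, then smallest
#' column, so the result is deterministic.
#'
#' @param mask `H x W` matrix with values in `{0, 1}`.
#' @return integer matrix with columns `(row, col)`, one row per component;
#'   zero rows for an all-background mask.
#' @export
derive_points_from_mask <- function(mask) {
  mask <- check_binary_mask(mask)
  if (!any(mask == 1L)) return(normalize_points(NULL))
  lab <- .cc_label8(mask)
  dt <- distance_transform(mask)
  pts <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    d <- dt[idx]
    best <- which(d == max(d))
    cand <- idx[best, , drop = FALSE]
    cand[order(cand[, 1], cand[, 2])[1L], ]
  })
  normalize_points(do.call(rbind, pts))
}

# Euclidean distance to the nearest in-image background pixel (0 on background).
distance_transform <- function(mask) {
  d <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

#' Write a binary mask as a single-channel PNG
#'
#' Stored as `{0, 255}` grayscale on disk; reading it back with
#' [read_mask_file()] reproduces the input exactly.
#'
#' @param mask `H x W` matrix in `{0, 1}`.
#' @param path output file path.
#' @export
write_mask <- function(mask, path) {
  mask <- check_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), target = path)
  invisible(path)
}

#' Read a binary mask PNG written by [write_mask()]
#' @param path file path.
#' @return `H x W` integer matrix in `{0, 1}`; `{0, 255}` files are normalised.
#' @export
read_mask_file <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  check_binary_mask((m > 0.5) * 1L)
}

# Point maps are single-channel PNGs with non-zero pixels at click locations.
write_points_map <- function(points, H, W, path) {
  m <- matrix(0, H, W)
  points <- normalize_points(points)
  if (nrow(points) > 0L) m[cbind(points[, 1], points[, 2])] <- 1
  png::writePNG(m, target = path)
  invisible(path)
}

read_points_map <- function(path) {
  if (!file.exists(path)) stop("point map not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  idx <- which(m > 0, arr.ind = TRUE)
  p <- normalize_points(idx)
  list(points = p[order(p[, 1], p[, 2]), , drop = FALSE], size = dim(m))
}

read_image_file <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    a <- EBImage::imageData(EBImage::readImage(path))  # x,y[,c] orientation
    img <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  }
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

# Round-half-down coordinate rescaling (keeps scaled clicks inside objects).
scale_point_coord <- function(coord, n_from, n_to) {
  scaled <- (coord - 1) * (n_to / n_from)
  as.integer(ceiling(scaled - 0.5)) + 1L
}

#' Load a dataset manifest from a DeepFish-style folder layout
#'
#' Reads every split listing present under `root`, loading images, point maps
#' and (when present) masks. All scenes are resized to `resize_target`:
#' images bilinearly, masks with nearest-neighbour sampling, and point
#' coordinates by scaling with round-half-down.
#'
#' @param root dataset root directory.
#' @param resize_target `(height, width)` pair, or `NULL` to keep native size.
#' @param normalization list with `mean` and `sd` (length-3 each) used to
#'   standardise channels at model-forward time; defaults to ImageNet
#'   statistics.
#' @return an `alcfcn_manifest`: list of scenes plus preprocessing metadata.
#' @export
load_manifest <- function(root, resize_target = NULL,
                          normalization = list(mean = IMAGENET_MEAN, sd = IMAGENET_SD)) {
  scenes <- list()
  for (split in c("train", "val", "test")) {
    listing <- file.path(root, paste0(split, ".txt"))
    if (!file.exists(listing)) next
    ids <- readLines(listing, warn = FALSE)
    ids <- ids[nzchar(ids)]
    for (id in ids) {
      img_path <- resolve_file(file.path(root, "images", split, id), c(".png", ".jpg", ".jpeg"))
      img <- read_image_file(img_path)
      pts_path <- file.path(root, "points", split, paste0(id, ".png"))
      pm <- read_points_map(pts_path)
      mask_path <- file.path(root, "masks", split, paste0(id, ".png"))
      mask <- if (file.exists(mask_path)) read_mask_file(mask_path) else NULL
      pts <- pm$points
      if (!is.null(resize_target)) {
        H2 <- resize_target[1]; W2 <- resize_target[2]
        H1 <- dim(img)[1]; W1 <- dim(img)[2]
        img <- vapply(1:3, function(ch) resize_bilinear(img[, , ch], H2, W2),
                      matrix(0, H2, W2))
        if (!is.null(mask)) mask <- resize_nearest(mask, H2, W2)
        if (nrow(pts) > 0L) {
          pts <- cbind(row = scale_point_coord(pts[, 1], H1, H2),
                       col = scale_point_coord(pts[, 2], W1, W2))
          pts <- unique(pts)
        }
      }
      scenes[[length(scenes) + 1L]] <-
        scene(id, img, pts, mask, split)
    }
  }
  manifest(scenes,
           resize_target = resize_target,
           normalization = normalization)
}

resolve_file <- function(stem, exts) {
  for (e in exts) if (file.exists(paste0(stem, e))) return(paste0(stem, e))
  stop("image file not found: ", stem, " (tried ", paste(exts, collapse = ", "), ")")
}

#' Bundle scenes into a manifest
#' @param scenes list of [scene()] objects.
#' @param resize_target `(height, width)` applied uniformly, or `NULL`.
#' @param normalization per-channel `mean`/`sd` list.
#' @return an `alcfcn_manifest`.
#' @export
manifest <- function(scenes, resize_target = NULL,
                     normalization = list(mean = IMAGENET_MEAN, sd = IMAGENET_SD)) {
  structure(
    list(scenes = scenes, resize_target = resize_target, normalization = normalization),
    class = "alcfcn_manifest"
  )
}

#' @export
print.alcfcn_manifest <- function(x, ...) {
  sp <- vapply(x$scenes, function(s) s$split, character(1))
  cat(sprintf("<manifest> %d scenes (train %d / val %d / test %d)\n",
              length(x$scenes), sum(sp == "train"), sum(sp == "val"), sum(sp == "test")))
  invisible(x)
}

# Subset of scenes belonging to one split.
split_scenes <- function(man, split) {
  Filter(function(s) s$split == split, man$scenes)
}

#' Summarise a manifest as a tibble
#' @param x an `alcfcn_manifest`.
#' @param ... unused.
#' @return one row per scene: id, split, height, width, n points, mask flag.
#' @export
as_tibble.alcfcn_manifest <- function(x, ...) {
  tibble::tibble(
    id = vapply(x$scenes, function(s) s$id, character(1)),
    split = vapply(x$scenes, function(s) s$split, character(1)),
    height = vapply(x$scenes, function(s) dim(s$image)[1], numeric(1)),
    width = vapply(x$scenes, function(s) dim(s$image)[2], numeric(1)),
    n_points = vapply(x$scenes, function(s) nrow(s$points), numeric(1)),
    has_mask = vapply(x$scenes, function(s) !is.null(s$mask), logical(1))
  )
}
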