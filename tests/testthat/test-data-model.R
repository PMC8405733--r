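test_that("mask PNG round-trip is exact", {
  tmp <- withr::local_tempdir()
  set.seed(11)
  m <- matrix(sample(0:1, 16 * 16, replace = TRUE), 16, 16)
  path <- file.path(tmp, "m.png")
  write_mask(m, path)
  expect_identical(read_mask_file(path), alcfcn:::check_binary_mask(m))

  ones <- matrix(1L, 9, 7)
  write_mask(ones, path)
  expect_equal(sum(read_mask_file(path)), 9 * 7)

  checker <- outer(1:4, 1:4, function(r, c) (r + c) %% 2L)
  write_mask(checker, path)
  expect_equal(sum(read_mask_file(path)), 8)
})

test_that("point derivation follows the max-distance-transform rule", {
  expect_equal(nrow(derive_points_from_mask(matrix(0L, 12, 12))), 0)

  # filled disk: symmetry forces the centre
  disk <- outer(1:19, 1:19, function(r, c) ((r - 10)^2 + (c - 10)^2 <= 36) * 1L)
  expect_equal(derive_points_from_mask(disk), rbind(c(10L, 10L)),
               ignore_attr = TRUE)

  # filled 3x7 rectangle: interior row, distance transform value 1 at the
  # middle row, pixel must match the brute-force search exactly
  rect <- matrix(0L, 8, 10)
  rect[2:4, 2:8] <- 1L
  got <- derive_points_from_mask(rect)
  expect_equal(got, oracle_points_from_mask(rect), ignore_attr = TRUE)
  expect_equal(unname(got[1, 1]), 3L)  # middle row of the rectangle
})

test_that("one point per component, matching the brute-force oracle", {
  set.seed(202)
  for (i in 1:25) {
    m <- random_mask(32, 32)
    pts <- derive_points_from_mask(m)
    expect_equal(nrow(pts), max(oracle_label8(m)))
    expect_equal(unclass(pts), oracle_points_from_mask(m), ignore_attr = TRUE)
    # determinism
    expect_identical(pts, derive_points_from_mask(m))
  }
})

test_that("non-binary masks are rejected", {
  expect_error(derive_points_from_mask(matrix(c(0, 2), 2, 2)), "binary")
})

test_that("manifest round-trips through the on-disk layout", {
  tmp <- withr::local_tempdir()
  man <- generate_split(easy_scene_spec(height = 48, width = 48),
                        2, 1, 1, seed = 5, root = tmp)
  expect_equal(length(man$scenes), 4)
  re <- load_manifest(tmp)
  expect_equal(length(re$scenes), 4)
  for (i in seq_along(man$scenes)) {
    a <- man$scenes[[i]]
    b <- Filter(function(s) s$id == a$id, re$scenes)[[1]]
    expect_identical(b$mask, a$mask)
    expect_equal(b$points[order(b$points[, 1], b$points[, 2]), , drop = FALSE],
                 a$points[order(a$points[, 1], a$points[, 2]), , drop = FALSE])
    expect_equal(b$image, a$image, tolerance = 1 / 254)  # 8-bit quantisation
  }
})

test_that("empty root yields an empty manifest", {
  tmp <- withr::local_tempdir()
  expect_equal(length(load_manifest(tmp)$scenes), 0)
})

test_that("point maps preserve the click count", {
  tmp <- withr::local_tempdir()
  pts <- rbind(c(3L, 4L), c(10L, 2L), c(7L, 7L))
  alcfcn:::write_points_map(pts, 12, 12, file.path(tmp, "p.png"))
  got <- alcfcn:::read_points_map(file.path(tmp, "p.png"))
  expect_equal(nrow(got$points), 3)
})

test_that("resize maps coordinates by half-down rounding", {
  # 512x910 -> (256,455): 0-based point (510, 900) must land on (255, 450)
  expect_equal(alcfcn:::scale_point_coord(511L, 512, 256), 256L)  # 1-based
  expect_equal(alcfcn:::scale_point_coord(901L, 910, 455), 451L)
  # full pipeline: write a scene at 96x96, reload resized to 48x48
  tmp <- withr::local_tempdir()
  man <- generate_split(easy_scene_spec(height = 96, width = 96,
                                        n_fish_range = c(2, 2)),
                        1, 0, 0, seed = 3, root = tmp)
  re <- load_manifest(tmp, resize_target = c(48, 48))
  s <- re$scenes[[1]]
  expect_equal(dim(s$image), c(48, 48, 3))
  expect_equal(dim(s$mask), c(48, 48))
  orig <- man$scenes[[1]]$points
  want <- cbind(row = alcfcn:::scale_point_coord(orig[, 1], 96, 48),
                col = alcfcn:::scale_point_coord(orig[, 2], 96, 48))
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  got <- s$points[order(s$points[, 1], s$points[, 2]), , drop = FALSE]
  expect_equal(unclass(got), want, ignore_attr = TRUE)
})

test_that("a point off the mask foreground warns but is kept", {
  img <- array(0.5, c(8, 8, 3))
  m <- matrix(0L, 8, 8); m[2:3, 2:3] <- 1L
  expect_warning(s <- scene("x", img, rbind(c(6L, 6L)), m), "foreground")
  expect_equal(nrow(s$points), 1)
})

test_that("distance transform agrees with brute force", {
  set.seed(9)
  for (i in 1:5) {
    m <- random_mask(20, 20)
    if (!any(m == 0)) next
    expect_equal(alcfcn:::distance_transform(m), oracle_distance_transform(m),
                 tolerance = 1e-10)
  }
})
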