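probmap_from_fish <- function(pf) {
  probs <- array(0, c(nrow(pf), ncol(pf), 2))
  probs[, , 1] <- 1 - pf
  probs[, , 2] <- pf
  probs
}

test_that("blob extraction uses argmax foreground and 8-connectivity", {
  # all background
  probs <- probmap_from_fish(matrix(0.1, 5, 5))
  expect_equal(length(find_blobs(probs)$blobs), 0)

  # two disjoint squares, one click each
  pf <- matrix(0.1, 8, 8)
  pf[2:3, 2:3] <- 0.9
  pf[6:7, 6:7] <- 0.9
  b <- find_blobs(probmap_from_fish(pf), rbind(c(2L, 2L), c(6L, 7L)))
  expect_equal(length(b$blobs), 2)
  expect_equal(vapply(b$blobs, function(x) length(x$contained_points), integer(1)),
               c(1L, 1L))

  # anti-diagonal touching pixels merge under 8-connectivity
  pf <- matrix(0.1, 2, 2)
  pf[1, 2] <- 0.9; pf[2, 1] <- 0.9
  expect_equal(length(find_blobs(probmap_from_fish(pf))$blobs), 1)

  # a tie (0.5 / 0.5) is background
  expect_equal(length(find_blobs(probmap_from_fish(matrix(0.5, 3, 3)))$blobs), 0)
})

test_that("image-level loss covers the annotated and empty cases", {
  pf <- matrix(0.2, 4, 4); pf[2, 2] <- 1
  expect_equal(image_level_loss(probmap_from_fish(pf), rbind(c(1L, 1L))), 0)
  expect_equal(image_level_loss(probmap_from_fish(matrix(0, 4, 4)), NULL), 0)
  expect_equal(image_level_loss(probmap_from_fish(matrix(0.5, 4, 4)), NULL),
               -log(0.5), tolerance = 1e-12)
})

test_that("point-level loss sums click cross-entropies", {
  expect_equal(point_level_loss(probmap_from_fish(matrix(0.3, 4, 4)), NULL), 0)
  pf <- matrix(0.9, 4, 4); pf[1, 1] <- 1
  expect_equal(point_level_loss(probmap_from_fish(pf), rbind(c(1L, 1L))), 0)
  pf <- matrix(0.9, 4, 4); pf[2, 2] <- 0.5; pf[3, 3] <- 0.25
  expect_equal(point_level_loss(probmap_from_fish(pf), rbind(c(2L, 2L), c(3L, 3L))),
               -log(0.5) - log(0.25), tolerance = 1e-12)
})

test_that("split-level loss penalises the watershed dam", {
  # single-point blobs contribute nothing
  pf <- matrix(0.1, 6, 6); pf[2:3, 2:3] <- 0.9
  probs <- probmap_from_fish(pf)
  pts <- rbind(c(2L, 2L))
  expect_equal(split_level_loss(probs, find_blobs(probs, pts)), 0)

  # 1x5 strip, clicks at both ends, uniform fish prob 0.9:
  # dam at the middle pixel, loss = 2 * -log(0.1)
  pf <- matrix(0.9, 1, 5)
  probs <- probmap_from_fish(pf)
  pts <- rbind(c(1L, 1L), c(1L, 5L))
  expect_equal(split_level_loss(probs, find_blobs(probs, pts)),
               2 * -log(0.1), tolerance = 1e-9)

  # background prob 1 on the dam -> zero loss (clamped log(1))
  pf2 <- matrix(0.9, 1, 5); pf2[1, 3] <- 0  # dam pixel fully background
  # force the strip to stay one blob: use probs directly with a crafted mask
  probs2 <- probmap_from_fish(matrix(0.9, 1, 5))
  probs2[1, 3, 1] <- 1  # background prob 1 at the dam (inconsistent on purpose)
  b2 <- find_blobs(probmap_from_fish(matrix(0.9, 1, 5)), pts)
  expect_equal(split_level_loss(probs2, b2), 0, tolerance = 1e-9)
})

test_that("false-positive loss targets unannotated blobs only", {
  pf <- matrix(0.1, 5, 5)
  probs <- probmap_from_fish(pf)
  expect_equal(false_positive_loss(probs, find_blobs(probs)), 0)

  pf <- matrix(0.1, 5, 5); pf[2, 2:3] <- 0.9; pf[4, 4] <- 0.9
  probs <- probmap_from_fish(pf)
  b <- find_blobs(probs, rbind(c(2L, 2L), c(4L, 4L)))
  expect_equal(false_positive_loss(probs, b), 0)

  # one 3-pixel unannotated strip with background probs 0.5, 0.5, 0.25
  probs <- probmap_from_fish(matrix(0.1, 3, 5))
  probs[2, 2:4, 2] <- c(0.5, 0.5, 0.75) + 0.001  # fish wins at these pixels
  probs[2, 2:4, 1] <- c(0.5, 0.5, 0.25) - 0.001
  b <- find_blobs(probs)
  expect_equal(false_positive_loss(probs, b),
               -log(0.499) * 2 - log(0.249), tolerance = 1e-9)
})

test_that("the total is the sum of the four terms and all are non-negative", {
  set.seed(55)
  for (i in 1:10) {
    probs <- random_probmap(8, 8)
    n_pts <- sample(0:3, 1)
    pts <- if (n_pts > 0)
      cbind(sample(8, n_pts), sample(8, n_pts)) else NULL
    rep <- lcfcn_loss(probs, pts)
    blobs <- find_blobs(probs, alcfcn:::normalize_points(pts))
    expect_equal(rep$total, rep$image_level + rep$point_level +
                   rep$split_level + rep$false_positive)
    expect_equal(rep$image_level, image_level_loss(probs, pts))
    expect_equal(rep$point_level, point_level_loss(probs, pts))
    expect_equal(rep$split_level, split_level_loss(probs, blobs))
    expect_equal(rep$false_positive, false_positive_loss(probs, blobs))
    expect_true(all(unlist(rep) >= 0))
  }
})

test_that("each term matches an independent straight-line reimplementation", {
  set.seed(99)
  for (i in 1:20) {
    probs <- random_probmap(8, 8)
    n_pts <- sample(0:3, 1)
    pts <- if (n_pts > 0) {
      idx <- sample(64, n_pts)
      cbind((idx - 1) %% 8 + 1, (idx - 1) %/% 8 + 1)
    } else NULL
    want <- oracle_lcfcn(probs, pts)
    rep <- lcfcn_loss(probs, pts)
    expect_equal(rep$image_level, want$image)
    expect_equal(rep$point_level, want$point)
    expect_equal(rep$split_level, want$split)
    expect_equal(rep$false_positive, want$fp)
    expect_equal(rep$total, want$total)
  }
})

test_that("a confident all-background prediction on an empty image costs ~0", {
  probs <- probmap_from_fish(matrix(1e-9, 6, 6))
  expect_lt(lcfcn_loss(probs, NULL)$total, 1e-6)
})

test_that("loss gradients vanish off the structural pixel sets", {
  set.seed(13)
  probs <- random_probmap(6, 6)
  pts <- rbind(c(2L, 2L))
  rep <- lcfcn_loss(probs, pts, with_grad = TRUE)
  g <- attr(rep, "grad")
  expect_equal(dim(g), dim(probs))
  # point pixel always carries point-level gradient on the fish channel
  expect_true(g[2, 2, 2] != 0)
})
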