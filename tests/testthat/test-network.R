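test_that("backbone stride arithmetic and determinism hold", {
  set.seed(21)
  m <- init_model(model_config(backbone = "small"))
  img <- array(runif(96 * 96 * 3), c(96, 96, 3))
  bb <- backbone_forward(m, img)
  expect_equal(dim(bb$levels[[1]])[1:2], c(48, 48))
  expect_equal(dim(bb$levels[[2]])[1:2], c(24, 24))
  expect_equal(dim(bb$last)[1:2], c(12, 12))   # stride 8
  bb2 <- backbone_forward(m, img)
  expect_identical(bb$last, bb2$last)
  # stride-4 variant keeps the deepest grid at 24x24
  set.seed(21)
  m4 <- init_model(model_config(backbone = "small4"))
  expect_equal(dim(backbone_forward(m4, img)$last)[1:2], c(24, 24))
})

test_that("backbones are swappable behind the 3-level contract", {
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  set.seed(5)
  small <- init_model(model_config(backbone = "small"))
  set.seed(5)
  big <- init_model(model_config(backbone = "resnet38_style",
                                 affinity_channels = c(8, 16, 24)))
  f1 <- model_forward(small, img)
  f2 <- model_forward(big, img)
  expect_equal(dim(f1$prob), dim(f2$prob))
  expect_false(isTRUE(all.equal(f1$prob, f2$prob)))
})

test_that("activation branch is an exact 1x1 convolution", {
  set.seed(33)
  m <- init_model(model_config(backbone = "tiny"))
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  bb <- backbone_forward(m, img)
  A <- activation_branch(m, bb)
  expect_equal(dim(A), c(dim(bb$last)[1:2], 2))
  # brute-force per-pixel dot product
  L3 <- bb$last
  for (r in c(1, 3)) for (c in c(2, 5)) for (k in 1:2) {
    want <- sum(L3[r, c, ] * m$params$act$W[, k]) + m$params$act$b[k]
    expect_equal(A[r, c, k], want, tolerance = 1e-12)
  }
  # zero weights -> zero scores
  m0 <- m
  m0$params$act$W[] <- 0; m0$params$act$b[] <- 0
  expect_true(all(activation_branch(m0, bb) == 0))
})

test_that("affinity branch obeys the channel and merge contracts", {
  cfg <- model_config(backbone = "resnet38_style")
  expect_equal(cfg$affinity_channels, c(64L, 128L, 256L))
  expect_equal(cfg$merged_channels, 448L)

  set.seed(44)
  m <- init_model(model_config(backbone = "tiny"))
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  bb <- backbone_forward(m, img)
  af <- affinity_branch(m, bb)
  expect_equal(dim(af$features),
               c(dim(bb$last)[1:2], m$config$merged_channels))

  # zeroed level convolutions make features constant -> all affinities 1
  mz <- m
  for (l in 1:3) {
    mz$params$aff$levels[[l]]$W[] <- 0
    mz$params$aff$levels[[l]]$b[] <- 0
  }
  afz <- affinity_branch(mz, backbone_forward(mz, img))
  g <- build_affinity_graph(afz$features, radius = 2)
  expect_true(all(abs(g$weight - 1) < 1e-12))
})

test_that("full forward output is a probability map", {
  set.seed(7)
  m <- init_model(model_config(backbone = "small"))
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  fwd <- model_forward(m, img)
  expect_equal(dim(fwd$prob), c(48, 48, 2))
  sums <- fwd$prob[, , 1] + fwd$prob[, , 2]
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("disabling affinity bypasses refinement exactly", {
  set.seed(70)
  cfg_off <- model_config(backbone = "tiny", affinity_enabled = FALSE)
  m <- init_model(cfg_off)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  fwd <- model_forward(m, img)
  bb <- backbone_forward(m, img)
  A <- activation_branch(m, bb)
  h <- dim(A)[1]; w <- dim(A)[2]
  U <- alcfcn:::bilinear_operator(h, w, 8, 8)
  S <- as.matrix(U %*% matrix(A, h * w, 2))
  expect_equal(matrix(fwd$prob, 64, 2), alcfcn:::softmax2(S), tolerance = 1e-12)
  expect_null(fwd$graph)
})

test_that("constant affinities with one step average over the neighbourhood", {
  set.seed(70)
  m <- init_model(model_config(backbone = "tiny", iterations = 1, radius = 1.5))
  for (l in 1:3) {
    m$params$aff$levels[[l]]$W[] <- 0
    m$params$aff$levels[[l]]$b[] <- 0
  }
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  bb <- backbone_forward(m, img)
  A <- activation_branch(m, bb)
  fwd <- model_forward(m, img)
  h <- dim(A)[1]; w <- dim(A)[2]
  # hand-rolled box average (radius-1.5 disc = 8-neighbourhood + self)
  want <- A
  for (r in seq_len(h)) for (c in seq_len(w)) for (k in 1:2) {
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) nb <- c(nb, A[rr, cc, k])
    }
    want[r, c, k] <- mean(nb)
  }
  expect_equal(fwd$refined, want, tolerance = 1e-9)
})

test_that("analytic gradients match finite differences end-to-end", {
  set.seed(42)
  cfg <- model_config(backbone = "tiny", beta = 2, iterations = 2, radius = 1.5)
  m <- init_model(cfg)
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  pts <- rbind(c(2L, 2L), c(3L, 4L))
  chk <- gradient_check(m, img, pts, n_sample = 120)
  expect_lt(max(chk$rel_error), 1e-3)
  # both branches and the shared backbone receive gradient
  expect_true(any(chk$analytic[grepl("^backbone", chk$path)] != 0))
})

test_that("checkpoints round-trip through disk", {
  tmp <- withr::local_tempdir()
  set.seed(3)
  m <- init_model(model_config(backbone = "tiny"))
  p <- file.path(tmp, "ckpt.rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  expect_equal(model_forward(m2, img)$prob, model_forward(m, img)$prob)
})
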