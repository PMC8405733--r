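test_that("pseudo masks are the per-pixel argmax with ties to background", {
  set.seed(61)
  sp <- easy_scene_spec(height = 32, width = 32)
  scenes <- lapply(1:2, function(i) generate_scene(sp, id = paste0("s", i), seed = i))
  m <- init_model(model_config(backbone = "tiny"))
  pm <- generate_pseudo_masks(m, scenes)
  expect_named(pm, c("s1", "s2"))
  for (i in 1:2) {
    p <- model_forward(m, scenes[[i]]$image)$prob
    expect_identical(pm[[i]]$mask, (p[, , 2] > p[, , 1]) * 1L)
    expect_equal(dim(pm[[i]]$mask), dim(scenes[[i]]$image)[1:2])
  }
  # equal scores everywhere (zeroed model scores) -> all background
  m0 <- m
  m0$params$act$W[] <- 0; m0$params$act$b[] <- 0
  m0$config$affinity_enabled <- FALSE
  pm0 <- generate_pseudo_masks(m0, scenes[1])
  expect_equal(sum(pm0[[1]]$mask), 0)
})

test_that("weighted cross-entropy matches direct evaluation", {
  # 2-pixel case: probs on target (0.5, 1), weights (2, 1)
  pred <- array(0, c(1, 2, 2))
  pred[1, 1, 2] <- 0.5; pred[1, 1, 1] <- 0.5
  pred[1, 2, 2] <- 1
  target <- matrix(1, 1, 2)
  w <- matrix(c(2, 1), 1, 2)
  expect_equal(weighted_ce_loss(pred, target, w), 2 * -log(0.5) / 3,
               tolerance = 1e-12)
  # perfect prediction -> 0
  perfect <- array(0, c(2, 2, 2)); perfect[, , 1] <- 1
  expect_equal(weighted_ce_loss(perfect, matrix(0, 2, 2), matrix(1, 2, 2)), 0)
  # uniform weights reduce to the mean cross-entropy
  set.seed(3)
  p <- random_probmap(4, 4)
  g <- matrix(sample(0:1, 16, TRUE), 4, 4)
  pt <- ifelse(g == 1, p[, , 2], p[, , 1])
  expect_equal(weighted_ce_loss(p, g, matrix(7, 4, 4)), mean(-log(pt)),
               tolerance = 1e-12)
  expect_error(weighted_ce_loss(p, g, matrix(0, 4, 4)), "weight")
})

test_that("weighted IoU loss matches direct evaluation", {
  # hard perfect prediction -> 0
  pred <- array(0, c(2, 2, 2))
  g <- matrix(c(1, 0, 0, 1), 2, 2)
  pred[, , 2] <- g; pred[, , 1] <- 1 - g
  expect_equal(weighted_iou_loss(pred, g, matrix(1, 2, 2)), 0)
  # all-background prediction on all-background target -> 0
  pred0 <- array(0, c(2, 2, 2)); pred0[, , 1] <- 1
  expect_equal(weighted_iou_loss(pred0, matrix(0, 2, 2), matrix(1, 2, 2)), 0)
  # p = g = 0.5 on 4 pixels, unit weights -> 0.5
  ph <- array(0.5, c(2, 2, 2))
  expect_equal(weighted_iou_loss(ph, matrix(0.5, 2, 2), matrix(1, 2, 2)), 0.5)
})

test_that("boundary weights emphasise label edges only", {
  g <- matrix(0, 24, 24); g[8:16, 8:16] <- 1
  w <- boundary_weights(g, lambda = 5, window = 31)
  expect_true(all(w >= 1))
  expect_gt(w[8, 8], w[12, 12])   # corner pixel sits on the boundary
  expect_equal(w[1, 1], 1)        # far corner untouched
  expect_equal(w[12, 12], 1, tolerance = 0.5)  # deep interior near 1
})

test_that("the weighted losses backpropagate correctly through the student", {
  set.seed(15)
  st <- init_student(backbone = "tiny")
  img <- array(runif(6 * 6 * 3), c(6, 6, 3))
  tgt <- matrix(sample(0:1, 36, TRUE), 6, 6)
  wts <- boundary_weights(tgt)
  loss_at <- function(params) {
    s <- st; s$params <- params
    fwd <- alcfcn:::student_forward(s, img)
    weighted_ce_loss(fwd$prob, tgt, wts) + weighted_iou_loss(fwd$prob, tgt, wts)
  }
  fwd <- alcfcn:::student_forward(st, img, keep_cache = TRUE)
  ce <- alcfcn:::weighted_ce_term(fwd$prob, tgt, wts)
  io <- alcfcn:::weighted_iou_term(fwd$prob, tgt, wts)
  grads <- alcfcn:::student_backward(st, fwd, ce$grad + io$grad)
  slots <- alcfcn:::param_paths(st$params)
  set.seed(16)
  slots <- slots[sample(length(slots), 40)]
  for (sl in slots) {
    v0 <- alcfcn:::get_param(st$params, sl$path, sl$index)
    lp <- loss_at(alcfcn:::set_param(st$params, sl$path, sl$index, v0 + 1e-6))
    lm <- loss_at(alcfcn:::set_param(st$params, sl$path, sl$index, v0 - 1e-6))
    num <- (lp - lm) / 2e-6
    a <- alcfcn:::get_param(grads, sl$path, sl$index)
    expect_lt(abs(a - num) / max(abs(a) + abs(num), 1e-6), 1e-3)
  }
})

test_that("student predictions keep the binary label space and image shape", {
  set.seed(29)
  st <- init_student(backbone = "small")
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  m <- alcfcn:::student_predict(st, img)
  expect_equal(dim(m), c(48, 48))
  expect_true(all(m %in% c(0L, 1L)))
})
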