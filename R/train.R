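# Training and evaluation orchestration: the five method modes, the
# learning-rate sweep with early stopping, per-epoch validation, and metric
# evaluation of fitted models.

#' Training configuration
#'
#' Defaults follow the standard protocol for this model family: ADAM with a
#' batch size of 1, a learning-rate sweep, early stopping on the validation
#' metric with patience 10, and the model of the best-validating learning
#' rate reported. `max_epochs` defaults to a desk-scale 100 (the full-scale
#' protocol uses 1000).
#'
#' @param method one of `"a_lcfcn"` (affinity-refined, LCFCN loss),
#'   `"lcfcn"` (identical but refinement disabled), `"pl_fcn"` (point-level
#'   cross-entropy baseline), `"fs_fcn"` (fully supervised student on true
#'   masks), `"a_lcfcn_pm"` (train A-LCFCN, distill into a student via pseudo
#'   masks).
#' @param learning_rates numeric vector swept over; best validation wins.
#' @param batch_size only 1 is supported.
#' @param max_epochs maximum epochs per learning rate.
#' @param patience epochs without validation improvement before stopping.
#' @param seed master seed covering weight init and data order.
#' @param val_metric `"auto"` (mIoU when validation masks exist, else
#'   GAME(4)), `"miou"`, `"game"`, or `"mae"`.
#' @param backbone,beta,iterations,radius,affinity_channels model settings,
#'   see [model_config()].
#' @param student_epochs,student_lr distillation-stage settings.
#' @return an `alcfcn_train_config`.
#' @export
train_config <- function(method = "a_lcfcn",
                         learning_rates = c(1e-4, 1e-5, 1e-6),
                         batch_size = 1L, max_epochs = 100L, patience = 10L,
                         seed = 1L, val_metric = "auto",
                         backbone = "small4", beta = 8, iterations = 8,
                         radius = 5, affinity_channels = NULL,
                         student_epochs = 20L, student_lr = 1e-3) {
  method <- match.arg(method, c("a_lcfcn", "lcfcn", "pl_fcn", "fs_fcn", "a_lcfcn_pm"))
  val_metric <- match.arg(val_metric, c("auto", "miou", "game", "mae"))
  if (batch_size != 1L) stop("only batch size 1 is supported")
  stopifnot(length(learning_rates) >= 1L, patience <= max_epochs)
  structure(
    list(method = method, learning_rates = learning_rates,
         batch_size = 1L, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), seed = as.integer(seed),
         val_metric = val_metric, backbone = backbone, beta = beta,
         iterations = iterations, radius = radius,
         affinity_channels = affinity_channels,
         student_epochs = as.integer(student_epochs), student_lr = student_lr),
    class = "alcfcn_train_config"
  )
}

#' Point-level FCN baseline loss
#'
#' Cross-entropy at the annotated pixels; for images without any point, the
#' mean background cross-entropy over all pixels (every prediction should be
#' background).
#'
#' @inheritParams find_blobs
#' @param with_grad also return the gradient w.r.t. `probs` as an attribute.
#' @return scalar loss (with `grad` attribute when requested).
#' @export
baseline_pl_fcn_loss <- function(probs, points = NULL, with_grad = FALSE) {
  points <- normalize_points(points)
  if (nrow(points) > 0L) {
    term <- point_level_term(probs, points)
  } else {
    pb <- prob_channel(probs, 1L)
    n <- length(pb)
    grad <- array(0, dim(probs))
    grad[, , 1L] <- neg_log_grad(pb) / n
    term <- list(value = mean(neg_log(pb)), grad = grad)
  }
  out <- term$value
  if (with_grad) attr(out, "grad") <- term$grad
  out
}

weak_loss_term <- function(method, probs, points) {
  if (method == "pl_fcn") {
    v <- baseline_pl_fcn_loss(probs, points, with_grad = TRUE)
    list(report = list(total = as.numeric(v)), grad = attr(v, "grad"))
  } else {
    rep <- lcfcn_loss(probs, points, with_grad = TRUE)
    list(report = rep, grad = attr(rep, "grad"))
  }
}

predict_scene_mask <- function(model, s) {
  if (inherits(model, "alcfcn_student")) return(student_predict(model, s$image))
  p <- model_forward(model, s$image)$prob
  (prob_channel(p, 2L) > prob_channel(p, 1L)) * 1L
}

# Validation score: larger is better (error metrics negated).
val_score <- function(model, scenes, metric) {
  preds <- lapply(scenes, function(s) predict_scene_mask(model, s))
  have_masks <- all(vapply(scenes, function(s) !is.null(s$mask), logical(1)))
  if (metric == "auto") metric <- if (have_masks) "miou" else "game"
  pts <- lapply(scenes, function(s) s$points)
  score <- switch(metric,
    miou = {
      if (!have_masks) stop("val_metric 'miou' needs validation masks")
      iou_accumulate(preds, lapply(scenes, function(s) s$mask))$miou
    },
    game = -game(preds, pts, L = 4),
    mae = -count_mae(vapply(preds, count_predictions, integer(1)),
                     vapply(pts, function(p) nrow(p), integer(1)))
  )
  list(score = score, metric = metric)
}

#' Train a model
#'
#' Runs the configured method over the manifest's train split, validating
#' each epoch on the val split, early-stopping with the configured patience,
#' sweeping the learning rates, and returning the best-validating model.
#' Deterministic given `config$seed`.
#'
#' @param man an `alcfcn_manifest` with non-empty train and val splits.
#' @param config an [train_config()].
#' @return an `alcfcn_fit`: `model` (or `student` for distilled methods),
#'   `log` (per-epoch tibble), `best` (lr/epoch/score), `config`. For
#'   `a_lcfcn_pm` the teacher fit is kept in `$teacher`.
#' @export
train <- function(man, config = train_config()) {
  stopifnot(inherits(man, "alcfcn_manifest"), inherits(config, "alcfcn_train_config"))
  train_sc <- split_scenes(man, "train")
  val_sc <- split_scenes(man, "val")
  if (length(train_sc) == 0L || length(val_sc) == 0L)
    stop("train and val splits must be non-empty")
  if (config$method == "a_lcfcn_pm") {
    teacher_cfg <- config; teacher_cfg$method <- "a_lcfcn"
    class(teacher_cfg) <- class(config)
    teacher <- train(man, teacher_cfg)
    fit <- distill_fit(teacher, man, config)
    fit$teacher <- teacher
    return(fit)
  }
  if (config$method == "fs_fcn") {
    masks <- lapply(train_sc, function(s) {
      if (is.null(s$mask)) stop("fs_fcn needs ground-truth masks on the train split")
      structure(list(mask = s$mask, source_id = s$id), class = "alcfcn_pseudo_mask")
    })
    names(masks) <- vapply(train_sc, function(s) s$id, character(1))
    return(train_student_fit(man, masks, config))
  }
  weak_train(man, config)
}

weak_train <- function(man, config) {
  train_sc <- split_scenes(man, "train")
  val_sc <- split_scenes(man, "val")
  mcfg <- model_config(
    backbone = config$backbone,
    affinity_enabled = config$method == "a_lcfcn",
    affinity_channels = config$affinity_channels,
    beta = config$beta, iterations = config$iterations, radius = config$radius
  )
  log_rows <- list()
  best <- list(score = -Inf, model = NULL, lr = NA_real_, epoch = NA_integer_)
  for (li in seq_along(config$learning_rates)) {
    lr <- config$learning_rates[li]
    set.seed(config$seed)               # same init for every lr and method
    model <- init_model(mcfg)
    opt <- adam_init(model$params)
    set.seed(config$seed + 10000L * li) # per-lr data-order stream
    best_lr <- list(score = -Inf, epoch = NA_integer_, params = NULL)
    stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(train_sc))
      comp <- c(total = 0, image_level = 0, point_level = 0,
                split_level = 0, false_positive = 0)
      for (i in ord) {
        s <- train_sc[[i]]
        fwd <- model_forward(model, s$image, keep_cache = TRUE)
        lt <- weak_loss_term(config$method, fwd$prob, s$points)
        if (!is.finite(lt$report$total))
          stop(sprintf("non-finite loss at epoch %d on scene '%s'", epoch, s$id))
        for (nm in names(comp))
          comp[nm] <- comp[nm] + (lt$report[[nm]] %||% 0)
        grads <- model_backward(model, fwd, lt$grad)
        st <- adam_step(model$params, grads, opt, lr)
        model$params <- st$params; opt <- st$state
      }
      vs <- val_score(model, val_sc, config$val_metric)
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        method = config$method, lr = lr, epoch = epoch,
        loss_total = comp["total"] / length(train_sc),
        loss_image = comp["image_level"] / length(train_sc),
        loss_point = comp["point_level"] / length(train_sc),
        loss_split = comp["split_level"] / length(train_sc),
        loss_fp = comp["false_positive"] / length(train_sc),
        val_metric = vs$metric, val_score = vs$score
      )
      if (vs$score > best_lr$score) {
        best_lr <- list(score = vs$score, epoch = epoch, params = model$params)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    if (best_lr$score > best$score) {
      m <- model; m$params <- best_lr$params
      best <- list(score = best_lr$score, model = m, lr = lr, epoch = best_lr$epoch)
    }
  }
  structure(
    list(model = best$model, method = config$method,
         log = do.call(rbind, log_rows),
         best = list(lr = best$lr, epoch = best$epoch, val_score = best$score),
         config = config),
    class = "alcfcn_fit"
  )
}

# Distillation stage of a_lcfcn_pm: pseudo-label train+val scenes with the
# teacher, then fit the student.
distill_fit <- function(teacher, man, config) {
  scenes <- c(split_scenes(man, "train"), split_scenes(man, "val"))
  pm <- generate_pseudo_masks(teacher$model, scenes)
  train_student_fit(man, pm, config)
}

# Train the fully supervised student against per-id target masks (pseudo or
# true), selecting the best epoch on validation mIoU (true masks when
# available, else the pseudo masks).
train_student_fit <- function(man, target_masks, config) {
  train_sc <- split_scenes(man, "train")
  val_sc <- split_scenes(man, "val")
  if (length(train_sc) == 0L) stop("empty train split")
  set.seed(config$seed)
  student <- init_student(backbone = config$backbone)
  opt <- adam_init(student$params)
  set.seed(config$seed + 77L)
  wts <- lapply(train_sc, function(s) boundary_weights(target_masks[[s$id]]$mask))
  val_targets <- lapply(val_sc, function(s) {
    if (!is.null(s$mask)) s$mask else target_masks[[s$id]]$mask
  })
  have_val <- !any(vapply(val_targets, is.null, logical(1))) && length(val_sc) > 0L
  best <- list(score = -Inf, epoch = NA_integer_, params = NULL)
  stall <- 0L
  log_rows <- list()
  for (epoch in seq_len(config$student_epochs)) {
    ord <- sample(length(train_sc))
    tot <- 0
    for (i in ord) {
      s <- train_sc[[i]]
      tgt <- target_masks[[s$id]]$mask
      fwd <- student_forward(student, s$image, keep_cache = TRUE)
      ce <- weighted_ce_term(fwd$prob, tgt, wts[[i]])
      io <- weighted_iou_term(fwd$prob, tgt, wts[[i]])
      if (!is.finite(ce$value + io$value))
        stop(sprintf("non-finite student loss at epoch %d on scene '%s'", epoch, s$id))
      tot <- tot + ce$value + io$value
      grads <- student_backward(student, fwd, ce$grad + io$grad)
      st <- adam_step(student$params, grads, opt, config$student_lr)
      student$params <- st$params; opt <- st$state
    }
    score <- if (have_val) {
      preds <- lapply(val_sc, function(s) student_predict(student, s$image))
      iou_accumulate(preds, val_targets)$miou
    } else -tot
    log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
      method = config$method, lr = config$student_lr, epoch = epoch,
      loss_total = tot / length(train_sc), loss_image = NA_real_,
      loss_point = NA_real_, loss_split = NA_real_, loss_fp = NA_real_,
      val_metric = "miou", val_score = score
    )
    if (score > best$score) {
      best <- list(score = score, epoch = epoch, params = student$params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  student$params <- best$params
  structure(
    list(model = student, method = config$method,
         log = do.call(rbind, log_rows),
         best = list(lr = config$student_lr, epoch = best$epoch, val_score = best$score),
         config = config),
    class = "alcfcn_fit"
  )
}

#' Evaluate a fitted model on one split
#'
#' Predicts a binary mask per scene (per-pixel argmax) and pools the metrics.
#' IoU is reported only when every scene in the split has a ground-truth
#' mask; counting metrics are always reported.
#'
#' @param fit an `alcfcn_fit` (or a bare model / student).
#' @param man an `alcfcn_manifest`.
#' @param split which split to evaluate.
#' @return an `alcfcn_metrics` report.
#' @export
evaluate <- function(fit, man, split = "test") {
  model <- if (inherits(fit, "alcfcn_fit")) fit$model else fit
  scenes <- split_scenes(man, split)
  if (length(scenes) == 0L) stop("split '", split, "' is empty")
  preds <- lapply(scenes, function(s) predict_scene_mask(model, s))
  have_masks <- all(vapply(scenes, function(s) !is.null(s$mask), logical(1)))
  metric_report(
    preds,
    true_masks = if (have_masks) lapply(scenes, function(s) s$mask) else NULL,
    true_points = lapply(scenes, function(s) s$points)
  )
}

#' @export
print.alcfcn_fit <- function(x, ...) {
  cat(sprintf("<%s fit> best lr %.1e, epoch %d, val score %.4f\n",
              x$method, x$best$lr, x$best$epoch, x$best$val_score))
  invisible(x)
}

#' Per-epoch training log of a fit
#' @param x an `alcfcn_fit`.
#' @param ... unused.
#' @return tibble with one row per (lr, epoch): loss components and the
#'   validation score.
#' @export
tidy.alcfcn_fit <- function(x, ...) tibble::as_tibble(x$log)

#' One-row summary of a fit
#' @param x an `alcfcn_fit`.
#' @param ... unused.
#' @return tibble with the method, best learning rate/epoch/validation score
#'   and total epochs trained.
#' @export
glance.alcfcn_fit <- function(x, ...) {
  tibble::tibble(method = x$method, best_lr = x$best$lr,
                 best_epoch = x$best$epoch, val_score = x$best$val_score,
                 epochs_trained = nrow(x$log))
}
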