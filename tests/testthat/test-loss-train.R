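# Loss closed forms, gradient correctness, and short optimization runs.

tiny_cfg <- function(nc = 2) {
  model_config(num_classes = nc, input_size = 32, scale = "n",
               repeats_profile = "unit",
               anchors = list(matrix(c(8, 8, 12, 12, 16, 16), 3, 2,
                                     byrow = TRUE),
                              matrix(c(16, 16, 24, 24, 32, 32), 3, 2,
                                     byrow = TRUE),
                              matrix(c(24, 24, 32, 32, 48, 48), 3, 2,
                                     byrow = TRUE)))
}

zero_preds <- function(cfg) {
  no <- 3 * (5 + cfg$num_classes)
  lapply(c(8, 16, 32), function(s) {
    array(0, dim = c(cfg$input_size / s, cfg$input_size / s, no))
  })
}

test_that("ciou is 1 for identical boxes and below for shifted ones", {
  expect_equal(ciou(c(10, 10, 8, 8), c(10, 10, 8, 8)), 1)
  expect_lt(ciou(c(10, 10, 8, 8), c(12, 10, 8, 8)), 1)
  expect_lt(ciou(c(10, 10, 8, 4), c(10, 10, 4, 8)),
            iou(c(6, 8, 14, 12), c(8, 6, 12, 14)))  # aspect penalty bites
})

test_that("predictions equal to assigned targets zero the box term", {
  cfg <- tiny_cfg()
  hyp <- hyper_params()
  labels <- data.frame(class_id = 1L, cx = 0.55, cy = 0.45, w = 0.4, h = 0.4)
  preds <- zero_preds(cfg)
  dims <- lapply(preds, dim)
  targets <- uwdet:::build_targets(labels, cfg, dims, hyp)
  # solve the decode for each assigned slot so every slot emits the gt box
  qlogis_ <- stats::qlogis
  for (k in 1:3) {
    tg <- targets[[k]]
    if (nrow(tg) == 0) next
    no5 <- 5 + cfg$num_classes
    pa <- array(preds[[k]], dim = c(dims[[k]][1], dims[[k]][2], no5, 3))
    for (t in seq_len(nrow(tg))) {
      a <- tg$anchor[t]
      anch <- cfg$anchors[[k]][a, ]
      sx <- (tg$gx[t] - tg$gj[t] + 0.5) / 2
      sy <- (tg$gy[t] - tg$gi[t] + 0.5) / 2
      sw <- sqrt(tg$gw[t] / anch[1]) / 2
      sh <- sqrt(tg$gh[t] / anch[2]) / 2
      pa[tg$gi[t] + 1, tg$gj[t] + 1, 1:4, a] <-
        qlogis_(c(sx, sy, sw, sh))
    }
    preds[[k]] <- array(pa, dim = dim(preds[[k]]))
  }
  ls <- yolo_loss(preds, labels, cfg, hyp)
  expect_lt(ls$box, 1e-8)
})

test_that("empty target set: cls and box vanish, obj matches closed-form BCE", {
  cfg <- tiny_cfg()
  hyp <- hyper_params()
  preds <- zero_preds(cfg)
  # craft a 2x2-cell logit map at the coarsest scale
  preds[[3]][, , ] <- -2
  none <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                     w = numeric(0), h = numeric(0))
  ls <- yolo_loss(preds, none, cfg, hyp)
  expect_equal(ls$cls, 0)
  expect_equal(ls$box, 0)
  # closed form: all-negative BCE of constant logits per scale
  bce_neg <- function(z) -log(1 - stats::plogis(z))
  want <- hyp$obj * (hyp$obj_balance[1] * bce_neg(0) +
                       hyp$obj_balance[2] * bce_neg(0) +
                       hyp$obj_balance[3] * bce_neg(-2))
  expect_equal(ls$obj, want, tolerance = 1e-9)
})

test_that("loss gradients match numeric differentiation", {
  cfg <- tiny_cfg()
  # constant objectness target: the CIoU-valued target is defined as
  # detached (a stop-gradient), which finite differences cannot represent
  hyp <- hyper_params(obj_pos = "one")
  set.seed(5)
  preds <- lapply(zero_preds(cfg), function(p) {
    array(rnorm(length(p), sd = 0.5), dim = dim(p))
  })
  labels <- data.frame(class_id = c(0L, 1L), cx = c(0.3, 0.7),
                       cy = c(0.4, 0.6), w = c(0.35, 0.3), h = c(0.3, 0.4))
  ls <- yolo_loss(preds, labels, cfg, hyp, grad = TRUE)
  eps <- 1e-5
  for (k in c(1, 3)) {
    for (ix in sample(length(preds[[k]]), 6)) {
      pp <- preds
      pp[[k]][ix] <- pp[[k]][ix] + eps
      lp <- yolo_loss(pp, labels, cfg, hyp)$total
      pm <- preds
      pm[[k]][ix] <- pm[[k]][ix] - eps
      lm <- yolo_loss(pm, labels, cfg, hyp)$total
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - ls$dpreds[[k]][ix]), 5e-4)
    }
  }
})

test_that("anchor matching respects the ratio test and neighbor cells", {
  cfg <- tiny_cfg()
  # a 3.2 px box is >= 7x smaller than every stride-32 anchor: excluded
  tiny <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.1, h = 0.1)
  dims <- lapply(zero_preds(cfg), dim)
  tg <- uwdet:::build_targets(tiny, cfg, dims)
  expect_equal(nrow(tg[[3]]), 0)
  expect_gt(nrow(tg[[1]]), 0)      # 3.2 px vs an 8 px anchor: ratio 2.5 < 4
  # center cell plus up to two neighbors per (scale, anchor)
  small <- data.frame(class_id = 0L, cx = 0.55, cy = 0.55, w = 0.25, h = 0.25)
  tg2 <- uwdet:::build_targets(small, cfg, dims)
  per_anchor <- table(tg2[[1]]$anchor)
  expect_true(all(per_anchor >= 1 & per_anchor <= 3))
})

test_that("a few SGD steps reduce the loss on one image", {
  set.seed(31)
  cfg <- model_config(num_classes = 3, input_size = 64, scale = "n",
                      repeats_profile = "unit")
  model <- init_model(build_model(cfg))
  img <- rand_fmap(64, 64, 3, seed = 32)
  img[] <- pmin(pmax(img * 0.2 + 0.5, 0), 1)
  labels <- data.frame(class_id = 1L, cx = 0.5, cy = 0.5, w = 0.5, h = 0.5)
  res <- train_model(model, list(list(image = img, labels = labels)),
                     steps = 12, batch = 1, seed = 3,
                     hyp = hyper_params(lr = 0.05))
  expect_lt(tail(res$history$total, 1), res$history$total[1])
  expect_true(all(is.finite(res$history$total)))
})

test_that("training is bit-stable under a fixed seed", {
  run <- function() {
    set.seed(77)
    cfg <- model_config(num_classes = 2, input_size = 32, scale = "n",
                        repeats_profile = "unit")
    model <- init_model(build_model(cfg))
    img <- rand_fmap(32, 32, 3, seed = 7)
    img[] <- pmin(pmax(img, 0), 1)
    labels <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.6, h = 0.6)
    train_model(model, list(list(image = img, labels = labels)),
                steps = 4, batch = 1, seed = 9)$history
  }
  expect_identical(run(), run())
})

test_that("hyperparameter defaults mirror the training settings", {
  hyp <- hyper_params()
  expect_equal(hyp$lr, 0.01)
  expect_equal(hyp$momentum, 0.937)
  expect_equal(hyp$weight_decay, 5e-4)
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(lr = 0.02, momentum = 0.9), p)
  h2 <- read_hyper_params(p)
  expect_equal(h2$lr, 0.02)
  expect_equal(h2$momentum, 0.9)
  expect_equal(h2$weight_decay, 5e-4)
  expect_error(hyper_params(bogus = 1), "unknown hyperparameter")
})

test_that("decode/NMS pipeline emits well-formed detections", {
  set.seed(41)
  cfg <- tiny_cfg()
  preds <- lapply(zero_preds(cfg), function(p) {
    array(rnorm(length(p)), dim = dim(p))
  })
  dets <- decode_predictions(preds, cfg, conf_thresh = 0.1, iou_thresh = 0.5)
  if (nrow(dets) > 0) {
    expect_true(all(dets$x2 > dets$x1 & dets$y2 > dets$y1))
    expect_true(all(dets$conf >= 0.1 & dets$conf <= 1))
    expect_true(all(dets$class_id %in% 0:1))
    expect_false(is.unsorted(rev(dets$conf)))
  }
  expect_equal(nrow(decode_predictions(zero_preds(cfg), cfg,
                                       conf_thresh = 0.9)), 0)
})
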