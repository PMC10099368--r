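# SGD training loop, inference and dataset-level evaluation.

# one optimizer step over every module: momentum SGD or Adam. Weight decay
# applies to conv and projection weights only (not biases or batch-norm
# affine terms).
optimizer_step <- function(model, hyp, step) {
  adam <- identical(hyp$optimizer, "adam")
  for (mod in model_modules(model)) {
    module_walk(mod, function(m) {
      if (is.null(m$params) || is.null(m$grads)) return(invisible(NULL))
      if (is.null(m$state$opt)) m$state$opt <- list()
      for (nm in names(m$params)) {
        g <- m$grads[[nm]]
        if (is.null(g)) next
        if (hyp$weight_decay > 0 && nm %in% c("w", "wq", "wk", "wv")) {
          g <- g + hyp$weight_decay * m$params[[nm]]
        }
        o <- m$state$opt[[nm]]
        if (is.null(o)) {
          zero <- array(0, dim = dim(as.array(m$params[[nm]])))
          o <- list(v = zero, s = zero)
        }
        if (adam) {
          b1 <- 0.9
          b2 <- 0.999
          o$v <- b1 * o$v + (1 - b1) * g
          o$s <- b2 * o$s + (1 - b2) * g^2
          vhat <- o$v / (1 - b1^step)
          shat <- o$s / (1 - b2^step)
          m$params[[nm]] <- m$params[[nm]] -
            hyp$lr * vhat / (sqrt(shat) + 1e-8)
        } else {
          o$v <- hyp$momentum * o$v + g
          m$params[[nm]] <- m$params[[nm]] - hyp$lr * o$v
        }
        m$state$opt[[nm]] <- o
      }
    })
  }
  invisible(model)
}

model_zero_grads <- function(model) {
  for (mod in model_modules(model)) zero_grads(mod)
  invisible(model)
}

#' Snapshot / restore model weights
#'
#' `model_state` deep-copies every parameter array and batch-norm running
#' moment into a plain list (a checkpoint); `load_state` writes one back.
#'
#' @param model a `uw_model`.
#' @param state a checkpoint from `model_state`.
#' @return `model_state`: the checkpoint; `load_state`: the model.
#' @export
model_state <- function(model) {
  st <- list()
  idx <- 0
  for (mod in model_modules(model)) {
    module_walk(mod, function(m) {
      idx <<- idx + 1
      st[[idx]] <<- list(params = m$params,
                         running_mean = m$state$running_mean,
                         running_var = m$state$running_var)
    })
  }
  st
}

#' @rdname model_state
#' @export
load_state <- function(model, state) {
  idx <- 0
  for (mod in model_modules(model)) {
    module_walk(mod, function(m) {
      idx <<- idx + 1
      m$params <- state[[idx]]$params
      if (!is.null(state[[idx]]$running_mean)) {
        m$state$running_mean <- state[[idx]]$running_mean
        m$state$running_var <- state[[idx]]$running_var
      }
    })
  }
  invisible(model)
}

#' Recalibrate batch-norm running statistics
#'
#' Replaces every batch-norm layer's running moments with the exact average
#' of the per-sample batch statistics over the given samples. Useful after
#' short, high-learning-rate training runs, where the exponentially-updated
#' running moments lag the final weights; [train_model()] calls this
#' automatically.
#'
#' @param model an initialized `uw_model`.
#' @param samples list of samples with an `image` entry (network-input size).
#' @return the model, invisibly.
#' @export
recalibrate_bn <- function(model, samples) {
  for (mod in model_modules(model)) {
    module_walk(mod, function(m) {
      if (inherits(m, "uw_batchnorm")) {
        m$state$accumulate <- TRUE
        m$state$acc_mean <- 0
        m$state$acc_var <- 0
        m$state$acc_n <- 0
      }
    })
  }
  for (smp in samples) forward_model(model, smp$image, train = FALSE)
  for (mod in model_modules(model)) {
    module_walk(mod, function(m) {
      if (inherits(m, "uw_batchnorm")) {
        if (m$state$acc_n > 0) {
          m$state$running_mean <- m$state$acc_mean / m$state$acc_n
          m$state$running_var <- m$state$acc_var / m$state$acc_n
        }
        m$state$accumulate <- FALSE
      }
    })
  }
  invisible(model)
}

# switch every batch-norm layer between per-sample and frozen statistics
set_bn_frozen <- function(model, frozen) {
  for (mod in model_modules(model)) {
    module_walk(mod, function(m) {
      if (inherits(m, "uw_batchnorm")) m$state$frozen <- frozen
    })
  }
  invisible(model)
}
load_samples <- function(manifest, size) {
  lapply(manifest$items, function(it) {
    lb <- letterbox(load_image(it$image), read_label_file(it$label), size)
    list(image = lb$image, labels = lb$labels, name = basename(it$image),
         meta = lb$meta)
  })
}

#' Train a detector by SGD
#'
#' Plain momentum-SGD over a fixed number of optimizer steps; each step
#' accumulates gradients over `batch` images cycled from the training set,
#' letterboxed to the configured input size. Deterministic given `seed`
#' (single-threaded). If a loss turns non-finite the loop aborts and the
#' last snapshot is restored.
#'
#' @param model an initialized `uw_model`.
#' @param train_manifest a `uw_manifest` (or a list of in-memory samples
#'   with `image`/`labels` entries).
#' @param steps optimizer steps.
#' @param hyp hyperparameters from [hyper_params()].
#' @param batch images per step.
#' @param seed RNG seed controlling sample order.
#' @param verbose print progress every 10 steps.
#' @return list with `model`, `history` (per-step data.frame of loss terms).
#' @export
train_model <- function(model, train_manifest, steps = 150,
                        hyp = hyper_params(), batch = 4, seed = 0,
                        verbose = FALSE) {
  samples <- if (inherits(train_manifest, "uw_manifest")) {
    load_samples(train_manifest, model$cfg$input_size)
  } else {
    train_manifest
  }
  n <- length(samples)
  hist <- data.frame(step = integer(0), box = numeric(0), obj = numeric(0),
                     cls = numeric(0), total = numeric(0))
  frozen_bn <- identical(hyp$bn_mode, "frozen")
  if (frozen_bn) {
    recalibrate_bn(model, samples)
    set_bn_frozen(model, TRUE)
  }
  snapshot <- model_state(model)
  with_seed(seed, {
    order_pool <- integer(0)
    for (st in seq_len(steps)) {
      if (length(order_pool) < batch) {
        order_pool <- c(order_pool, sample.int(n))
      }
      take <- order_pool[seq_len(batch)]
      order_pool <- order_pool[-seq_len(batch)]
      model_zero_grads(model)
      acc <- c(box = 0, obj = 0, cls = 0, total = 0)
      ok <- TRUE
      for (ix in take) {
        smp <- samples[[ix]]
        preds <- forward_model(model, smp$image, train = TRUE)
        ls <- tryCatch(yolo_loss(preds, smp$labels, model$cfg, hyp,
                                 grad = TRUE),
                       error = function(e) e)
        if (inherits(ls, "error")) {
          ok <- FALSE
          break
        }
        backward_model(model, lapply(ls$dpreds, function(g) g / batch))
        acc <- acc + c(ls$box, ls$obj, ls$cls, ls$total) / batch
      }
      if (!ok || !all(is.finite(acc))) {
        warning("training diverged at step ", st,
                "; restoring last snapshot", call. = FALSE)
        load_state(model, snapshot)
        break
      }
      optimizer_step(model, hyp, st)
      hist <- rbind(hist, data.frame(step = st, box = acc["box"],
                                     obj = acc["obj"], cls = acc["cls"],
                                     total = acc["total"]))
      if (st %% 10 == 0) {
        if (frozen_bn) {
          set_bn_frozen(model, FALSE)
          recalibrate_bn(model, samples)
          set_bn_frozen(model, TRUE)
        }
        snapshot <- model_state(model)
        if (verbose) {
          message(sprintf("step %3d  box %.4f  obj %.4f  cls %.4f", st,
                          acc["box"], acc["obj"], acc["cls"]))
        }
      }
    }
  })
  rownames(hist) <- NULL
  if (frozen_bn) set_bn_frozen(model, FALSE)
  recalibrate_bn(model, samples)
  list(model = model, history = hist)
}

#' Train with per-epoch validation and best-checkpoint selection
#'
#' Runs [train_model()] one epoch at a time (an epoch covers the training
#' set once), evaluates mAP\@0.5 on the validation split after each epoch,
#' and restores the best checkpoint at the end.
#'
#' @param model an initialized `uw_model`.
#' @param train_manifest,val_manifest dataset manifests.
#' @param hyp hyperparameters.
#' @param epochs number of epochs.
#' @param batch images per optimizer step.
#' @param seed RNG seed.
#' @param verbose print per-epoch metrics.
#' @return list with `model` (best weights), `log` (per-epoch data.frame),
#'   `best` (epoch index).
#' @export
train <- function(model, train_manifest, val_manifest, hyp = hyper_params(),
                  epochs = 3, batch = 4, seed = 0, verbose = FALSE) {
  samples <- load_samples(train_manifest, model$cfg$input_size)
  steps_per_epoch <- max(1L, ceiling(length(samples) / batch))
  log <- data.frame(epoch = integer(0), loss = numeric(0), map50 = numeric(0))
  best <- list(map = -Inf, state = model_state(model), epoch = 0L)
  for (ep in seq_len(epochs)) {
    res <- train_model(model, samples, steps = steps_per_epoch, hyp = hyp,
                       batch = batch, seed = seed + ep)
    rep <- evaluate_model(model, val_manifest)
    loss_ep <- mean(res$history$total)
    log <- rbind(log, data.frame(epoch = ep, loss = loss_ep,
                                 map50 = rep$map50))
    if (rep$map50 > best$map) {
      best <- list(map = rep$map50, state = model_state(model), epoch = ep)
    }
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  mAP@0.5 %.4f", ep, loss_ep,
                      rep$map50))
    }
  }
  load_state(model, best$state)
  list(model = model, log = log, best = best$epoch)
}

#' Detect objects in an image
#'
#' Letterboxes the image to the network input size, runs the model in
#' inference mode, decodes and NMS-filters the predictions, and maps boxes
#' back to original-image pixel coordinates.
#'
#' @param model an initialized `uw_model`.
#' @param img `H x W x 3` array.
#' @param conf_thresh,iou_thresh post-processing thresholds.
#' @return detection data.frame in original pixels.
#' @export
detect_objects <- function(model, img, conf_thresh = 0.25, iou_thresh = 0.45) {
  lb <- letterbox(img, size = model$cfg$input_size)
  preds <- forward_model(model, lb$image, train = FALSE)
  dets <- decode_predictions(preds, model$cfg, conf_thresh, iou_thresh)
  if (nrow(dets) > 0) {
    dets[, c("x1", "y1", "x2", "y2")] <-
      unletterbox_boxes(dets, lb$meta)[, c("x1", "y1", "x2", "y2")]
  }
  dets
}

#' Evaluate a model over a dataset split
#'
#' Runs inference on every image of the manifest (raw images; no
#' enhancement is ever applied here) and scores the detections with
#' [evaluate_detections()].
#'
#' @param model an initialized `uw_model`.
#' @param manifest a `uw_manifest`.
#' @param conf_thresh low confidence floor used for PR-curve fidelity.
#' @param iou_thresh NMS IoU threshold.
#' @param num_classes class count (default from the model config).
#' @return an `uw_eval_report`.
#' @export
evaluate_model <- function(model, manifest, conf_thresh = 0.05,
                           iou_thresh = 0.45, num_classes = NULL) {
  if (is.null(num_classes)) num_classes <- model$cfg$num_classes
  all_dets <- list()
  all_truths <- list()
  for (nm in names(manifest$items)) {
    it <- manifest$items[[nm]]
    img <- load_image(it$image)
    d <- dim(img)
    dets <- detect_objects(model, img, conf_thresh, iou_thresh)
    if (nrow(dets) > 0) {
      dets$image <- nm
      all_dets[[nm]] <- dets
    }
    lb <- read_label_file(it$label)
    if (nrow(lb) > 0) {
      tb <- labels_to_xyxy(lb, d[1], d[2])
      tb$image <- nm
      all_truths[[nm]] <- tb
    }
  }
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), conf = numeric(0),
                      class_id = integer(0), image = character(0))
  dets <- if (length(all_dets)) do.call(rbind, all_dets) else empty
  truths <- if (length(all_truths)) {
    do.call(rbind, all_truths)
  } else {
    empty[, c("x1", "y1", "x2", "y2", "class_id", "image")]
  }
  evaluate_detections(dets, truths, num_classes)
}
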