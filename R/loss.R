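# Training loss: CIoU box regression, binary cross-entropy objectness and
# classification with anchor-matched target assignment (ratio test < 4,
# center cell plus the two nearest neighbor cells).

sigmoid <- function(x) stats::plogis(x)

#' Complete IoU between two boxes
#'
#' IoU minus the normalized center distance and an aspect-ratio consistency
#' penalty; 1 for identical boxes.
#'
#' @param b1,b2 boxes as `(cx, cy, w, h)` in pixels.
#' @return CIoU in `(-1, 1]`.
#' @export
ciou <- function(b1, b2) {
  eps <- 1e-9
  a1 <- c(b1[1] - b1[3] / 2, b1[2] - b1[4] / 2,
          b1[1] + b1[3] / 2, b1[2] + b1[4] / 2)
  a2 <- c(b2[1] - b2[3] / 2, b2[2] - b2[4] / 2,
          b2[1] + b2[3] / 2, b2[2] + b2[4] / 2)
  i <- iou(a1, a2)
  cw <- max(a1[3], a2[3]) - min(a1[1], a2[1])
  chh <- max(a1[4], a2[4]) - min(a1[2], a2[2])
  c2 <- cw^2 + chh^2 + eps
  rho2 <- (b1[1] - b2[1])^2 + (b1[2] - b2[2])^2
  v <- 4 / pi^2 * (atan(b2[3] / (b2[4] + eps)) - atan(b1[3] / (b1[4] + eps)))^2
  alpha <- v / (1 - i + v + eps)
  i - rho2 / c2 - alpha * v
}

default_hyp <- function() {
  list(lr = 0.01, momentum = 0.937, weight_decay = 5e-4,
       box = 0.05, obj = 1.0, cls = 0.5,
       anchor_t = 4.0, obj_balance = c(4.0, 1.0, 0.4),
       obj_pos = "iou", obj_pw = 1.0, neighbor_cells = TRUE,
       optimizer = "sgd", bn_mode = "batch")
}

#' Training hyperparameters
#'
#' Defaults mirror the usual single-stage detector settings: SGD learning
#' rate 0.01, momentum 0.937, weight decay 0.0005; loss gains box 0.05,
#' objectness 1.0, classification 0.5; anchor-match aspect threshold 4.
#'
#' @param ... overrides of the defaults.
#' @return named list of hyperparameters.
#' @export
hyper_params <- function(...) {
  hyp <- default_hyp()
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(hyp)) stop("unknown hyperparameter: ", nm, call. = FALSE)
    hyp[[nm]] <- over[[nm]]
  }
  hyp
}

#' Hyperparameters for the short-horizon overfit smoke test
#'
#' A setting for memorizing a handful of images in ~150 optimizer steps
#' rather than converging over a 100-epoch schedule: Adam (per-parameter
#' gradient normalization converges in tens of steps on memorization),
#' stronger box/class gains, an objectness positive weight that undoes the
#' dilution of the few positive cells in the mean BCE, a tight anchor-match
#' threshold, and center-cell-only target assignment (neighbor-cell
#' densification places offset targets near the sigmoid saturation
#' boundary, which a short overfit cannot fit exactly). Frozen after a
#' baseline run of the training loop.
#'
#' @return named list of hyperparameters.
#' @export
smoke_hyper_params <- function() {
  hyper_params(optimizer = "adam", lr = 0.01, weight_decay = 0,
               box = 1.0, cls = 1.0, obj_pw = 30, anchor_t = 2.0,
               neighbor_cells = FALSE, bn_mode = "frozen")
}

#' Anchors matched to the synthetic smoke scenes
#'
#' Three (w, h) pairs per stride sized for objects spanning roughly a
#' quarter to half of the input side, so every pyramid level receives
#' positive targets on the generated scenes.
#'
#' @param input_size network input in pixels.
#' @return list of three 3x2 anchor matrices.
#' @export
smoke_anchors <- function(input_size) {
  s <- input_size / 128
  lapply(list(matrix(c(10, 10, 16, 16, 24, 24), 3, 2, byrow = TRUE),
              matrix(c(24, 24, 34, 34, 44, 44), 3, 2, byrow = TRUE),
              matrix(c(48, 48, 64, 64, 88, 88), 3, 2, byrow = TRUE)),
         function(a) a * s)
}

#' Read a hyperparameter file (YAML)
#' @param path YAML file with any subset of the [hyper_params()] names.
#' @return named list of hyperparameters.
#' @export
read_hyper_params <- function(path) {
  do.call(hyper_params, yaml::read_yaml(path))
}

# assign ground-truth boxes to (scale, anchor, cell) slots.
# labels: normalized center-format data.frame; dims: list of 3 map dims.
# Returns per-scale data.frames with grid coords and pixel-space targets.
build_targets <- function(labels, cfg, dims, hyp = default_hyp()) {
  img <- cfg$input_size
  lapply(1:3, function(k) {
    Hs <- dims[[k]][1]
    Ws <- dims[[k]][2]
    anch <- cfg$anchors[[k]]
    rows <- list()
    if (nrow(labels) > 0) {
      for (t in seq_len(nrow(labels))) {
        gw <- labels$w[t] * img
        gh <- labels$h[t] * img
        gx <- labels$cx[t] * Ws
        gy <- labels$cy[t] * Hs
        for (a in 1:3) {
          r <- max(gw / anch[a, 1], anch[a, 1] / gw,
                   gh / anch[a, 2], anch[a, 2] / gh)
          if (r >= hyp$anchor_t) next
          j0 <- floor(gx)
          i0 <- floor(gy)
          cells <- list(c(i0, j0))
          if (isTRUE(hyp$neighbor_cells)) {
            fx <- gx - j0
            fy <- gy - i0
            if (fx < 0.5 && j0 >= 1) cells <- c(cells, list(c(i0, j0 - 1)))
            if (fx >= 0.5 && j0 < Ws - 1) cells <- c(cells, list(c(i0, j0 + 1)))
            if (fy < 0.5 && i0 >= 1) cells <- c(cells, list(c(i0 - 1, j0)))
            if (fy >= 0.5 && i0 < Hs - 1) cells <- c(cells, list(c(i0 + 1, j0)))
          }
          for (cl in cells) {
            if (cl[1] < 0 || cl[1] >= Hs || cl[2] < 0 || cl[2] >= Ws) next
            rows[[length(rows) + 1]] <- data.frame(
              anchor = a, gi = cl[1], gj = cl[2],
              class_id = labels$class_id[t],
              gx = gx, gy = gy, gw = gw, gh = gh)
          }
        }
      }
    }
    if (length(rows) == 0) {
      data.frame(anchor = integer(0), gi = integer(0), gj = integer(0),
                 class_id = integer(0), gx = numeric(0), gy = numeric(0),
                 gw = numeric(0), gh = numeric(0))
    } else {
      do.call(rbind, rows)
    }
  })
}

# decode one (anchor, cell) slot's box from raw values
decode_box <- function(raw4, gi, gj, stride, anchor) {
  s <- sigmoid(raw4)
  c((2 * s[1] - 0.5 + gj) * stride,
    (2 * s[2] - 0.5 + gi) * stride,
    (2 * s[3])^2 * anchor[1],
    (2 * s[4])^2 * anchor[2])
}

#' Detection training loss
#'
#' Computes the three loss components and (optionally) the gradient with
#' respect to the raw prediction maps. Box: mean `1 - CIoU` over assigned
#' targets. Objectness: per-scale balanced BCE over all cells, target equal
#' to the (detached, clamped) CIoU at assigned cells. Class: BCE over class
#' logits at assigned cells. Total = weighted sum with the configured gains.
#'
#' @param preds list of three raw maps from [forward_model()].
#' @param labels normalized center-format ground truth for the image.
#' @param cfg the `uw_model_config` of the model.
#' @param hyp hyperparameters, see [hyper_params()].
#' @param grad logical; also return `dpreds`.
#' @return list with `box`, `obj`, `cls`, `total` and optionally `dpreds`.
#' @export
yolo_loss <- function(preds, labels, cfg, hyp = hyper_params(), grad = FALSE) {
  nc <- cfg$num_classes
  no5 <- 5 + nc
  dims <- lapply(preds, dim)
  targets <- build_targets(labels, cfg, dims, hyp)
  box_terms <- numeric(0)
  cls_loss_sum <- 0
  cls_count <- 0
  obj_loss <- 0
  dpreds <- if (grad) lapply(preds, function(p) array(0, dim = dim(p)))
  for (k in 1:3) {
    p <- preds[[k]]
    Hs <- dims[[k]][1]
    Ws <- dims[[k]][2]
    stride <- cfg$strides[k]
    pa <- array(p, dim = c(Hs, Ws, no5, 3))
    tobj <- array(0, dim = c(Hs, Ws, 1, 3))
    tg <- targets[[k]]
    dboxraw <- if (grad) array(0, dim = c(Hs, Ws, no5, 3))
    if (nrow(tg) > 0) {
      for (t in seq_len(nrow(tg))) {
        a <- tg$anchor[t]
        i <- tg$gi[t] + 1
        j <- tg$gj[t] + 1
        raw4 <- pa[i, j, 1:4, a]
        bx <- decode_box(raw4, tg$gi[t], tg$gj[t], stride, cfg$anchors[[k]][a, ])
        gt <- c(tg$gx[t] * stride, tg$gy[t] * stride, tg$gw[t], tg$gh[t])
        cv <- ciou(bx, gt)
        box_terms <- c(box_terms, 1 - cv)
        pos <- if (identical(hyp$obj_pos, "one")) 1 else min(max(cv, 0), 1)
        tobj[i, j, 1, a] <- max(tobj[i, j, 1, a], pos)
        # class BCE at this slot
        zc <- pa[i, j, 5 + seq_len(nc), a]
        tc <- as.numeric(seq_len(nc) - 1 == tg$class_id[t])
        sc <- sigmoid(zc)
        cls_loss_sum <- cls_loss_sum +
          sum(-(tc * log(sc + 1e-12) + (1 - tc) * log(1 - sc + 1e-12)))
        cls_count <- cls_count + nc
        if (grad) {
          # d(1 - ciou)/draw4 by central differences through the decode
          eps <- 1e-4
          g4 <- numeric(4)
          for (q in 1:4) {
            rp <- raw4; rp[q] <- rp[q] + eps
            rm <- raw4; rm[q] <- rm[q] - eps
            cp <- ciou(decode_box(rp, tg$gi[t], tg$gj[t], stride,
                                  cfg$anchors[[k]][a, ]), gt)
            cm <- ciou(decode_box(rm, tg$gi[t], tg$gj[t], stride,
                                  cfg$anchors[[k]][a, ]), gt)
            g4[q] <- -(cp - cm) / (2 * eps)
          }
          dboxraw[i, j, 1:4, a] <- dboxraw[i, j, 1:4, a] + g4
          dboxraw[i, j, 5 + seq_len(nc), a] <-
            dboxraw[i, j, 5 + seq_len(nc), a] + (sc - tc)  # d cls-sum/dz
        }
      }
    }
    # objectness BCE over every slot, with a positive-class weight
    zo <- pa[, , 5, , drop = FALSE]
    so <- sigmoid(zo)
    nel <- length(zo)
    pw <- hyp$obj_pw
    obj_k <- mean(-(pw * tobj * log(so + 1e-12) +
                      (1 - tobj) * log(1 - so + 1e-12)))
    obj_loss <- obj_loss + hyp$obj_balance[k] * obj_k
    if (grad) {
      dz <- array(0, dim = c(Hs, Ws, no5, 3))
      dz[, , 5, ] <- hyp$obj * hyp$obj_balance[k] *
        (-pw * tobj * (1 - so) + (1 - tobj) * so)[, , 1, ] / nel
      n_box <- max(length(box_terms), 1)  # filled after loop; rescaled below
      dz[, , 1:4, ] <- dboxraw[, , 1:4, , drop = FALSE]
      dz[, , 5 + seq_len(nc), ] <- dboxraw[, , 5 + seq_len(nc), , drop = FALSE]
      dpreds[[k]] <- array(dz, dim = dim(p))
    }
  }
  n_box <- length(box_terms)
  box_loss <- if (n_box > 0) mean(box_terms) else 0
  cls_loss <- if (cls_count > 0) cls_loss_sum / cls_count else 0
  out <- list(box = hyp$box * box_loss, obj = hyp$obj * obj_loss,
              cls = hyp$cls * cls_loss)
  out$total <- out$box + out$obj + out$cls
  if (!all(vapply(out, is.finite, logical(1)))) {
    bad <- names(out)[!vapply(out, is.finite, logical(1))][1]
    stop("non-finite loss term: ", bad, call. = FALSE)
  }
  if (grad) {
    # rescale the per-target box/cls contributions by their means' denominators
    for (k in 1:3) {
      Hs <- dims[[k]][1]
      Ws <- dims[[k]][2]
      dz <- array(dpreds[[k]], dim = c(Hs, Ws, no5, 3))
      if (n_box > 0) dz[, , 1:4, ] <- dz[, , 1:4, ] * hyp$box / n_box
      if (cls_count > 0) {
        dz[, , 5 + seq_len(nc), ] <- dz[, , 5 + seq_len(nc), ] *
          hyp$cls / cls_count
      }
      dpreds[[k]] <- array(dz, dim = dim(preds[[k]]))
    }
    out$dpreds <- dpreds
  }
  out
}

#' Decode raw prediction maps into detections
#'
#' Applies the anchor decode to every cell, forms per-box confidence
#' `sigmoid(obj) * max_c sigmoid(cls_c)`, thresholds, and runs [nms()].
#' Boxes are pixel xyxy in the network input frame.
#'
#' @param preds list of three raw maps.
#' @param cfg the model's `uw_model_config`.
#' @param conf_thresh,iou_thresh post-processing thresholds.
#' @return detection data.frame.
#' @export
decode_predictions <- function(preds, cfg, conf_thresh = 0.25,
                               iou_thresh = 0.45) {
  nc <- cfg$num_classes
  no5 <- 5 + nc
  rows <- list()
  for (k in 1:3) {
    p <- preds[[k]]
    Hs <- dim(p)[1]
    Ws <- dim(p)[2]
    stride <- cfg$strides[k]
    pa <- array(p, dim = c(Hs, Ws, no5, 3))
    for (a in 1:3) {
      obj <- sigmoid(pa[, , 5, a])
      clsz <- sigmoid(pa[, , 5 + seq_len(nc), a, drop = FALSE])
      dim(clsz) <- c(Hs, Ws, nc)
      best_c <- apply(clsz, c(1, 2), which.max)
      best_p <- apply(clsz, c(1, 2), max)
      conf <- obj * best_p
      hits <- which(conf >= conf_thresh, arr.ind = TRUE)
      if (nrow(hits) == 0) next
      for (r in seq_len(nrow(hits))) {
        i <- hits[r, 1]
        j <- hits[r, 2]
        b <- decode_box(pa[i, j, 1:4, a], i - 1, j - 1, stride,
                        cfg$anchors[[k]][a, ])
        rows[[length(rows) + 1]] <- data.frame(
          x1 = b[1] - b[3] / 2, y1 = b[2] - b[4] / 2,
          x2 = b[1] + b[3] / 2, y2 = b[2] + b[4] / 2,
          conf = conf[i, j], class_id = best_c[i, j] - 1L)
      }
    }
  }
  dets <- if (length(rows) == 0) {
    data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
               y2 = numeric(0), conf = numeric(0), class_id = integer(0))
  } else {
    do.call(rbind, rows)
  }
  nms(dets, iou_thresh = iou_thresh, conf_thresh = conf_thresh)
}
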