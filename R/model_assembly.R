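# Assembly of the full detector: backbone (stem + 4 stages), FPN/PAN neck
# with the bottleneck-transformer block on the stride-16 branch, anchor-based
# prediction heads, plus analytic parameter/FLOP accounting.

scale_table <- list(
  n = c(depth = 0.33, width = 0.25),
  s = c(depth = 0.33, width = 0.50),
  m = c(depth = 0.67, width = 0.75),
  l = c(depth = 1.00, width = 1.00),
  x = c(depth = 1.33, width = 1.25)
)

# default anchors (pixels at 640 input), three (w, h) pairs per stride
default_anchors_640 <- list(
  matrix(c(10, 13, 16, 30, 33, 23), ncol = 2, byrow = TRUE),    # stride 8
  matrix(c(30, 61, 62, 45, 59, 119), ncol = 2, byrow = TRUE),   # stride 16
  matrix(c(116, 90, 156, 198, 373, 326), ncol = 2, byrow = TRUE) # stride 32
)

make_divisible <- function(x, d = 8) max(d, ceiling(x / d) * d)

#' Detector model configuration
#'
#' Declarative description of an assembled detector. `scale` maps to the
#' usual (depth_multiple, width_multiple) pairs; the `x` scale is
#' (1.33, 1.25). `repeats_profile` selects the per-stage CSPNeXt repeats of
#' the improved backbone: `"unit"` is one block per stage; `"footprint"` is
#' the calibrated x-scale plan `(3, 8, 10, 8)` whose assembled parameter and
#' FLOP totals reproduce the reported footprint of the improved x model (see
#' the methods vignette). Detection always happens at three scales with
#' strides 8/16/32.
#'
#' @param num_classes number of object classes.
#' @param input_size square network input in pixels; divisible by 32.
#' @param scale one of `"n","s","m","l","x"`.
#' @param variant `"improved"` (CSPNeXt backbone + BoT3 neck) or `"baseline"`.
#' @param repeats_profile `"unit"`, `"footprint"`, or an integer vector of 4.
#' @param mhsa_heads attention heads in the BoT3 block.
#' @param anchors list of three 3x2 matrices of (w, h) anchor pixels at
#'   `input_size` scale; default anchors are scaled from the 640-pixel set.
#' @param depthwise use depth-wise 5x5 convolutions in CSPNeXt blocks.
#' @param use_bot3 keep the BoT3 block on the stride-16 branch (ablation
#'   switch; `FALSE` restores the classic C3 fuse there).
#' @return an object of class `uw_model_config`.
#' @export
model_config <- function(num_classes = 80, input_size = 640, scale = "x",
                         variant = c("improved", "baseline"),
                         repeats_profile = NULL, mhsa_heads = 4,
                         anchors = NULL, depthwise = FALSE, use_bot3 = TRUE) {
  variant <- match.arg(variant)
  stopifnot(scale %in% names(scale_table))
  if (input_size %% 32 != 0) {
    stop("input_size must be divisible by 32", call. = FALSE)
  }
  if (is.null(repeats_profile)) {
    repeats_profile <- if (identical(scale, "x")) "footprint" else "unit"
  }
  repeats <- if (is.numeric(repeats_profile)) {
    stopifnot(length(repeats_profile) == 4)
    as.integer(repeats_profile)
  } else {
    switch(match.arg(repeats_profile, c("unit", "footprint")),
           unit = c(1L, 1L, 1L, 1L),
           footprint = c(3L, 8L, 10L, 8L))
  }
  if (is.null(anchors)) {
    anchors <- lapply(default_anchors_640, function(a) a * input_size / 640)
  }
  stopifnot(length(anchors) == 3,
            all(vapply(anchors, function(a) all(dim(a) == c(3, 2)), logical(1))))
  structure(list(num_classes = num_classes, input_size = input_size,
                 scale = scale, variant = variant, repeats = repeats,
                 mhsa_heads = mhsa_heads, anchors = anchors,
                 depthwise = depthwise, use_bot3 = use_bot3,
                 depth_multiple = scale_table[[scale]]["depth"],
                 width_multiple = scale_table[[scale]]["width"],
                 strides = c(8L, 16L, 32L)),
            class = "uw_model_config")
}

cfg_width <- function(cfg, c) make_divisible(c * cfg$width_multiple, 8)
cfg_depth <- function(cfg, n) max(round(n * cfg$depth_multiple), 1)

node <- function(name, op, from, module = NULL) {
  list(name = name, op = op, from = from, module = module)
}

#' Build the backbone graph fragment
#'
#' Improved variant: a stem of three 3x3 CBS units (strides 2, 1, 1, half
#' width then full width) and four stages, each a stride-2 CBS unit plus a
#' [csplayer()]; stage 4 inserts [sppf()] before its CSP layer. Emits the
#' stride-8/16/32 pyramid from stages 2-4. Baseline variant: the classic
#' CSP backbone with C3 blocks and a trailing SPPF.
#'
#' @param cfg a [model_config()].
#' @return list with `nodes` and pyramid node indices `p3`, `p4`, `p5`.
#' @export
build_backbone <- function(cfg) {
  w <- function(c) cfg_width(cfg, c)
  if (cfg$variant == "improved") {
    half <- max(w(64) %/% 2, 8)
    n <- cfg$repeats
    dw <- cfg$depthwise
    nodes <- list(
      node("stem1", "module", 0L, conv_bn_act(3, half, 3, 2)),
      node("stem2", "module", 1L, conv_bn_act(half, half, 3, 1)),
      node("stem3", "module", 2L, conv_bn_act(half, w(64), 3, 1)),
      node("stage1_conv", "module", 3L, conv_bn_act(w(64), w(128), 3, 2)),
      node("stage1_csp", "module", 4L, csplayer(w(128), w(128), n[1], dw)),
      node("stage2_conv", "module", 5L, conv_bn_act(w(128), w(256), 3, 2)),
      node("stage2_csp", "module", 6L, csplayer(w(256), w(256), n[2], dw)),
      node("stage3_conv", "module", 7L, conv_bn_act(w(256), w(512), 3, 2)),
      node("stage3_csp", "module", 8L, csplayer(w(512), w(512), n[3], dw)),
      node("stage4_conv", "module", 9L, conv_bn_act(w(512), w(1024), 3, 2)),
      node("stage4_sppf", "module", 10L, sppf(w(1024), w(1024))),
      node("stage4_csp", "module", 11L, csplayer(w(1024), w(1024), n[4], dw))
    )
    list(nodes = nodes, p3 = 7L, p4 = 9L, p5 = 12L)
  } else {
    d <- function(nn) cfg_depth(cfg, nn)
    nodes <- list(
      node("stem", "module", 0L, conv_bn_act(3, w(64), 6, 2, pad = 2)),
      node("conv1", "module", 1L, conv_bn_act(w(64), w(128), 3, 2)),
      node("c3_1", "module", 2L, c3_layer(w(128), w(128), d(3))),
      node("conv2", "module", 3L, conv_bn_act(w(128), w(256), 3, 2)),
      node("c3_2", "module", 4L, c3_layer(w(256), w(256), d(6))),
      node("conv3", "module", 5L, conv_bn_act(w(256), w(512), 3, 2)),
      node("c3_3", "module", 6L, c3_layer(w(512), w(512), d(9))),
      node("conv4", "module", 7L, conv_bn_act(w(512), w(1024), 3, 2)),
      node("c3_4", "module", 8L, c3_layer(w(1024), w(1024), d(3))),
      node("sppf", "module", 9L, sppf(w(1024), w(1024)))
    )
    list(nodes = nodes, p3 = 5L, p4 = 7L, p5 = 10L)
  }
}

#' Build the FPN/PAN neck graph fragment
#'
#' Top-down (upsample + concat + fuse) then bottom-up (stride-2 conv +
#' concat + fuse) paths over the backbone pyramid. In the improved variant
#' exactly one [bot3()] block sits on the stride-16 branch feeding the
#' medium detection head; with `use_bot3 = FALSE` (or in the baseline) that
#' site is the classic C3 fuse.
#'
#' @param cfg a [model_config()].
#' @param backbone result of [build_backbone()].
#' @return list with combined `nodes` and head node indices
#'   `head_s`, `head_m`, `head_l`.
#' @export
build_neck <- function(cfg, backbone) {
  w <- function(c) cfg_width(cfg, c)
  d <- function(nn) cfg_depth(cfg, nn)
  nodes <- backbone$nodes
  i <- length(nodes)
  add <- function(nd) {
    nodes[[length(nodes) + 1]] <<- nd
    length(nodes)
  }
  lat5 <- add(node("lat_p5", "module", backbone$p5,
                   conv_bn_act(w(1024), w(512), 1)))
  up1 <- add(node("up1", "module", lat5, mod_upsample(2)))
  cat1 <- add(node("cat_p4", "concat", c(up1, backbone$p4)))
  fuse1 <- add(node("fuse_td_p4", "module", cat1,
                    c3_layer(2 * w(512), w(512), d(3), shortcut = FALSE)))
  lat4 <- add(node("lat_p4", "module", fuse1, conv_bn_act(w(512), w(256), 1)))
  up2 <- add(node("up2", "module", lat4, mod_upsample(2)))
  cat2 <- add(node("cat_p3", "concat", c(up2, backbone$p3)))
  head_s <- add(node("fuse_td_p3", "module", cat2,
                     c3_layer(2 * w(256), w(256), d(3), shortcut = FALSE)))
  down1 <- add(node("down_p3", "module", head_s,
                    conv_bn_act(w(256), w(256), 3, 2)))
  cat3 <- add(node("cat_pan_p4", "concat", c(down1, lat4)))
  medium_fuse <- if (cfg$variant == "improved" && cfg$use_bot3) {
    bot3(2 * w(256), w(512), heads = cfg$mhsa_heads)
  } else {
    c3_layer(2 * w(256), w(512), d(3), shortcut = FALSE)
  }
  head_m <- add(node("fuse_bu_p4", "module", cat3, medium_fuse))
  down2 <- add(node("down_p4", "module", head_m,
                    conv_bn_act(w(512), w(512), 3, 2)))
  cat4 <- add(node("cat_pan_p5", "concat", c(down2, lat5)))
  head_l <- add(node("fuse_bu_p5", "module", cat4,
                     c3_layer(2 * w(512), w(1024), d(3), shortcut = FALSE)))
  list(nodes = nodes, head_s = head_s, head_m = head_m, head_l = head_l)
}

# prediction head: one 1x1 conv (with bias) per scale, 3*(5+nc) outputs/cell
mod_detect <- function(cins, num_classes, anchors) {
  no <- 3 * (5 + num_classes)
  new_module("detect",
             cfg = list(cins = cins, num_classes = num_classes, no = no,
                        anchors = anchors),
             children = list(
               cv_s = mod_conv2d(cins[1], no, 1, bias = TRUE),
               cv_m = mod_conv2d(cins[2], no, 1, bias = TRUE),
               cv_l = mod_conv2d(cins[3], no, 1, bias = TRUE)))
}

#' Build the prediction head graph fragment
#'
#' One 1x1 convolution per pyramid scale emitting, per anchor and cell,
#' `5 + num_classes` raw outputs (box offsets, objectness, class logits).
#'
#' @param cfg a [model_config()].
#' @param neck result of [build_neck()].
#' @return list with combined `nodes` and the `detect` node index.
#' @export
build_head <- function(cfg, neck) {
  w <- function(c) cfg_width(cfg, c)
  nodes <- neck$nodes
  det <- mod_detect(c(w(256), w(512), w(1024)), cfg$num_classes, cfg$anchors)
  nodes[[length(nodes) + 1]] <-
    node("detect", "detect", c(neck$head_s, neck$head_m, neck$head_l), det)
  list(nodes = nodes, detect = length(nodes))
}

#' Assemble a full detection model
#'
#' Composes [build_backbone()], [build_neck()] and [build_head()] into one
#' graph. Weights are not allocated; call [uw_init_params()] (after seeding
#' the RNG) before running [forward_model()]. Parameter and FLOP accounting
#' ([count_parameters()], [count_flops()]) works on the unallocated graph.
#'
#' @param cfg a [model_config()].
#' @return an object of class `uw_model`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "uw_model_config"))
  bb <- build_backbone(cfg)
  nk <- build_neck(cfg, bb)
  hd <- build_head(cfg, nk)
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$nodes <- hd$nodes
  m$pyramid <- c(p3 = bb$p3, p4 = bb$p4, p5 = bb$p5)
  m$heads <- c(s = nk$head_s, m = nk$head_m, l = nk$head_l)
  m$detect_idx <- hd$detect
  class(m) <- "uw_model"
  m
}

model_modules <- function(model) {
  Filter(Negate(is.null), lapply(model$nodes, `[[`, "module"))
}

#' Initialize model weights
#'
#' Allocates every module's weights from the current RNG stream and applies
#' the detection-head bias prior (objectness biased towards the expected
#' object count per cell, class logits towards a small uniform prior), which
#' stabilizes early training.
#'
#' @param model a `uw_model`.
#' @return the model, invisibly.
#' @export
init_model <- function(model) {
  for (mod in model_modules(model)) uw_init_params(mod)
  det <- model$nodes[[model$detect_idx]]$module
  nc <- det$cfg$num_classes
  img <- model$cfg$input_size
  for (i in 1:3) {
    cv <- det$children[[c("cv_s", "cv_m", "cv_l")[i]]]
    stride <- model$cfg$strides[i]
    b <- array(cv$params$b, dim = c(5 + nc, 3))
    b[5, ] <- log(8 / (img / stride)^2)
    b[5 + seq_len(nc), ] <- log(0.6 / (nc - 0.99 + 1e-12))
    cv$params$b <- as.numeric(b)
  }
  invisible(model)
}

#' Run the model forward
#'
#' @param model an initialized `uw_model`.
#' @param x input image as `H x W x 3` array (letterboxed to
#'   `cfg$input_size`).
#' @param train logical; training mode (enables backward).
#' @return list of three raw prediction maps, strides 8/16/32, each
#'   `H/s x W/s x 3*(5+num_classes)`.
#' @export
forward_model <- function(model, x, train = FALSE) {
  outs <- vector("list", length(model$nodes))
  fetch <- function(j) if (j == 0L) x else outs[[j]]
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    outs[[i]] <- switch(
      nd$op,
      module = forward(nd$module, fetch(nd$from), train = train),
      concat = cat_channels(fetch(nd$from[1]), fetch(nd$from[2])),
      detect = {
        det <- nd$module
        maps <- lapply(seq_len(3), function(k) {
          cv <- det$children[[c("cv_s", "cv_m", "cv_l")[k]]]
          forward(cv, fetch(nd$from[k]), train = train)
        })
        maps
      })
    if (nd$op != "detect") {
      bad <- !all(is.finite(outs[[i]]))
      if (bad) {
        stop("non-finite activations in block '", nd$name, "'", call. = FALSE)
      }
    }
  }
  if (train) model$last_out_dims <- lapply(outs, function(o) {
    if (is.list(o)) lapply(o, dim) else dim(o)
  })
  outs[[model$detect_idx]]
}

# backward through the graph; dpreds is a list of three gradients matching
# the detect output. Parameter gradients accumulate inside the modules.
backward_model <- function(model, dpreds) {
  n <- length(model$nodes)
  gbuf <- vector("list", n)
  addg <- function(j, g) {
    if (j == 0L) return(invisible(NULL))
    if (is.null(gbuf[[j]])) gbuf[[j]] <<- g else gbuf[[j]] <<- gbuf[[j]] + g
  }
  # seed detect gradients
  det_nd <- model$nodes[[model$detect_idx]]
  for (k in seq_len(3)) {
    cv <- det_nd$module$children[[c("cv_s", "cv_m", "cv_l")[k]]]
    addg(det_nd$from[k], backward(cv, dpreds[[k]]))
  }
  for (i in rev(seq_len(n))) {
    nd <- model$nodes[[i]]
    if (nd$op == "detect") next
    g <- gbuf[[i]]
    if (is.null(g)) next
    if (nd$op == "module") {
      addg(nd$from, backward(nd$module, g))
    } else if (nd$op == "concat") {
      d1 <- model$last_out_dims[[nd$from[1]]]
      c1 <- d1[3]
      addg(nd$from[1], g[, , seq_len(c1), drop = FALSE])
      addg(nd$from[2], g[, , -seq_len(c1), drop = FALSE])
    }
  }
  invisible(NULL)
}

# shape propagation over the graph; returns per-node profile rows
graph_profile <- function(model, input_size = model$cfg$input_size) {
  shapes <- vector("list", length(model$nodes))
  getsh <- function(j) if (j == 0L) c(input_size, input_size, 3) else shapes[[j]]
  rows <- list()
  for (i in seq_along(model$nodes)) {
    nd <- model$nodes[[i]]
    if (nd$op == "module") {
      p <- module_profile(nd$module, getsh(nd$from))
      shapes[[i]] <- p$shape
      rows[[i]] <- data.frame(idx = i, name = nd$name, op = nd$op,
                              params = n_params(nd$module), flops = p$flops,
                              out = paste(p$shape, collapse = "x"))
    } else if (nd$op == "concat") {
      s1 <- getsh(nd$from[1])
      s2 <- getsh(nd$from[2])
      shapes[[i]] <- c(s1[1], s1[2], s1[3] + s2[3])
      rows[[i]] <- data.frame(idx = i, name = nd$name, op = nd$op, params = 0,
                              flops = 0,
                              out = paste(shapes[[i]], collapse = "x"))
    } else {  # detect
      det <- nd$module
      fl <- 0
      osh <- character(3)
      for (k in seq_len(3)) {
        cv <- det$children[[c("cv_s", "cv_m", "cv_l")[k]]]
        p <- module_profile(cv, getsh(nd$from[k]))
        fl <- fl + p$flops
        osh[k] <- paste(p$shape, collapse = "x")
      }
      rows[[i]] <- data.frame(idx = i, name = nd$name, op = nd$op,
                              params = n_params(det), flops = fl,
                              out = paste(osh, collapse = " | "))
    }
  }
  do.call(rbind, rows)
}

#' Count learnable parameters of a model
#'
#' Total learnable scalar count over the whole graph: convolution weights
#' and biases plus batch-norm affine terms. Matches a per-layer closed-form
#' sum; works without allocated weights.
#'
#' @param model a `uw_model`.
#' @return parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model_modules(model), n_params, numeric(1)))
}

#' Count inference FLOPs of a model
#'
#' Layerwise analytic FLOPs at a given input size with the reporting
#' convention FLOPs = 2 x multiply-accumulates for convolutions and matrix
#' products, plus 2 ops/element for batch-norm; activations and pooling are
#' not counted.
#'
#' @param model a `uw_model`.
#' @param input_size square input in pixels (default: the configured size).
#' @return FLOP count.
#' @export
count_flops <- function(model, input_size = model$cfg$input_size) {
  sum(graph_profile(model, input_size)$flops)
}

#' Model summary table
#'
#' Per-layer table (name, parameters, FLOPs, output shape) plus totals.
#'
#' @param model a `uw_model`.
#' @param input_size square input in pixels.
#' @param print print the table.
#' @return invisibly, a list with `layers` (data.frame), `params`, `flops`.
#' @export
model_summary <- function(model, input_size = model$cfg$input_size,
                          print = TRUE) {
  tab <- graph_profile(model, input_size)
  totals <- list(layers = tab, params = sum(tab$params),
                 flops = sum(tab$flops))
  if (print) {
    print(tab, row.names = FALSE)
    cat(sprintf("variant: %s  scale: %s  classes: %d  input: %d\n",
                model$cfg$variant, model$cfg$scale, model$cfg$num_classes,
                input_size))
    cat(sprintf("total params: %.1f M   total FLOPs: %.1f G\n",
                totals$params / 1e6, totals$flops / 1e9))
  }
  invisible(totals)
}

#' Estimate anchors from a dataset by k-means
#'
#' Clusters ground-truth box sizes (pixels at `input_size`) into 9 anchors,
#' assigned to the three strides by area.
#'
#' @param manifest a dataset manifest (see [read_yolo_dataset()]).
#' @param input_size network input in pixels.
#' @return list of three 3x2 anchor matrices.
#' @export
estimate_anchors <- function(manifest, input_size) {
  wh <- do.call(rbind, lapply(manifest$items, function(it) {
    recs <- read_label_file(it$label)
    if (nrow(recs) == 0) return(NULL)
    cbind(recs$w * input_size, recs$h * input_size)
  }))
  if (is.null(wh) || nrow(wh) < 9) {
    stop("need at least 9 labelled boxes to estimate anchors", call. = FALSE)
  }
  km <- stats::kmeans(wh, centers = 9, nstart = 5)
  centers <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  lapply(0:2, function(i) {
    m <- centers[i * 3 + 1:3, , drop = FALSE]
    dimnames(m) <- NULL
    m
  })
}

#' Read/write model configuration files
#'
#' YAML serialization of a [model_config()].
#'
#' @param path file path.
#' @param cfg a `uw_model_config`.
#' @return `read_model_config` returns a `uw_model_config`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  anchors <- if (!is.null(y$anchors)) {
    lapply(y$anchors, function(a) matrix(unlist(a), ncol = 2, byrow = TRUE))
  } else NULL
  model_config(num_classes = y$num_classes %||% 80,
               input_size = y$input_size %||% 640,
               scale = y$scale %||% "x",
               variant = y$variant %||% "improved",
               repeats_profile = y$repeats_profile,
               mhsa_heads = y$mhsa_heads %||% 4,
               anchors = anchors,
               depthwise = isTRUE(y$depthwise),
               use_bot3 = !isFALSE(y$use_bot3))
}

#' @rdname read_model_config
#' @export
write_model_config <- function(cfg, path) {
  y <- list(num_classes = cfg$num_classes, input_size = cfg$input_size,
            scale = cfg$scale, variant = cfg$variant,
            repeats_profile = as.integer(cfg$repeats),
            mhsa_heads = cfg$mhsa_heads,
            anchors = lapply(cfg$anchors, function(a) {
              lapply(seq_len(nrow(a)), function(i) as.numeric(a[i, ]))
            }),
            depthwise = cfg$depthwise, use_bot3 = cfg$use_bot3)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
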