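# The block zoo: every architectural unit of the detector as an individually
# constructible, shape-contracted module. Feature maps are H x W x C arrays.

#' Convolution + batch norm + SiLU (the "CBS" unit)
#'
#' The standard unit used throughout the detector: a same-padded `k x k`
#' convolution (no bias), batch normalization, SiLU activation. With stride
#' `s` the spatial dims become `ceiling(dim / s)`.
#'
#' @param cin,cout input/output channel counts.
#' @param k odd kernel size (even kernels allowed when `pad` is given).
#' @param stride stride.
#' @param act activation, `"silu"` (default) or `"none"`.
#' @param groups 1 for dense convolution, `cin` for depth-wise.
#' @param pad padding; defaults to `k %/% 2` ("same" arithmetic up to stride).
#' @return a module; apply with [forward()].
#' @export
conv_bn_act <- function(cin, cout, k = 1, stride = 1, act = "silu",
                        groups = 1, pad = NULL) {
  if (is.null(pad)) {
    stopifnot(k %% 2 == 1)
    pad <- k %/% 2
  }
  m <- new_module("conv_bn_act",
                  cfg = list(cin = cin, cout = cout, k = k, stride = stride),
                  children = list(
                    conv = mod_conv2d(cin, cout, k, stride, pad = pad,
                                      groups = groups),
                    bn = mod_batchnorm(cout),
                    act = mod_act(act)))
  m
}

#' @export
forward.uw_conv_bn_act <- function(mod, x, train = FALSE) {
  x <- forward(mod$children$conv, x, train)
  x <- forward(mod$children$bn, x, train)
  forward(mod$children$act, x, train)
}

#' @export
backward.uw_conv_bn_act <- function(mod, dout) {
  dout <- backward(mod$children$act, dout)
  dout <- backward(mod$children$bn, dout)
  backward(mod$children$conv, dout)
}

#' @export
module_profile.uw_conv_bn_act <- function(mod, in_shape) {
  p1 <- module_profile(mod$children$conv, in_shape)
  p2 <- module_profile(mod$children$bn, p1$shape)
  list(shape = p2$shape, flops = p1$flops + p2$flops)
}

#' CSPNeXt block: 3x3 conv then large 5x5 conv, optional residual
#'
#' The inner unit of [csplayer()]: a 3x3 CBS unit followed by a 5x5 CBS unit
#' whose large kernel widens the effective receptive field. With
#' `add = TRUE` (which requires `cin == cout`) the branch output is summed
#' with the input. The 5x5 convolution is dense by default; a depth-wise
#' variant is available via `depthwise = TRUE`.
#'
#' @param cin,cout channel counts; `add = TRUE` requires them equal.
#' @param add logical, residual switch.
#' @param depthwise logical; use a depth-wise 5x5 convolution.
#' @return a module.
#' @export
cspnext_block <- function(cin, cout, add = TRUE, depthwise = FALSE) {
  if (add && cin != cout) {
    stop("cspnext_block with add = TRUE requires cin == cout", call. = FALSE)
  }
  new_module("cspnext_block",
             cfg = list(cin = cin, cout = cout, add = add,
                        kernels = c(3L, 5L), depthwise = depthwise),
             children = list(
               conv3 = conv_bn_act(cin, cout, k = 3),
               conv5 = conv_bn_act(cout, cout, k = 5,
                                   groups = if (depthwise) cout else 1)))
}

#' @export
forward.uw_cspnext_block <- function(mod, x, train = FALSE) {
  y <- forward(mod$children$conv3, x, train)
  y <- forward(mod$children$conv5, y, train)
  if (mod$cfg$add) y + x else y
}

#' @export
backward.uw_cspnext_block <- function(mod, dout) {
  dx <- backward(mod$children$conv5, dout)
  dx <- backward(mod$children$conv3, dx)
  if (mod$cfg$add) dx + dout else dx
}

#' @export
module_profile.uw_cspnext_block <- function(mod, in_shape) {
  p1 <- module_profile(mod$children$conv3, in_shape)
  p2 <- module_profile(mod$children$conv5, p1$shape)
  list(shape = p2$shape, flops = p1$flops + p2$flops)
}

#' Channel attention
#'
#' Global average pooling over space, a 1x1 projection (with bias, no channel
#' reduction), and a hard-sigmoid gate that rescales each channel. The gate is
#' bounded in `[0, 1]`, so no activation magnitude can increase.
#'
#' @param c channel count.
#' @return a module.
#' @export
channel_attention <- function(c) {
  new_module("channel_attention", cfg = list(c = c),
             param_shapes = list(w = c(c, c), b = c))
}

#' @export
forward.uw_channel_attention <- function(mod, x, train = FALSE) {
  need_params(mod)
  d <- dim(x)
  pooled <- colMeans(matrix(x, d[1] * d[2], d[3]))
  z <- as.numeric(crossprod(mod$params$w, pooled)) + as.numeric(mod$params$b)
  g <- hard_sigmoid(z)
  if (train) {
    mod$state$x <- x
    mod$state$pooled <- pooled
    mod$state$z <- z
    mod$state$g <- g
  }
  sweep(x, 3, g, "*")
}

#' @export
backward.uw_channel_attention <- function(mod, dout) {
  st <- mod$state
  d <- dim(st$x)
  n <- d[1] * d[2]
  dx <- sweep(dout, 3, st$g, "*")
  dg <- colSums(matrix(dout * st$x, n, d[3]))
  dz <- dg * hard_sigmoid_grad(st$z)
  acc_grad(mod, "w", outer(st$pooled, dz))
  acc_grad(mod, "b", dz)
  dpool <- as.numeric(mod$params$w %*% dz)
  dx + aperm(array(rep(dpool / n, each = n), dim = d), c(1, 2, 3))
}

#' @export
module_profile.uw_channel_attention <- function(mod, in_shape) {
  c <- mod$cfg$c
  # 1x1 projection on the pooled 1x1 map + bias + per-element gate multiply
  list(shape = in_shape, flops = 2 * c * c + c + prod(in_shape))
}

#' CSP layer with CSPNeXt blocks and channel attention
#'
#' The backbone's core block: two parallel 1x1 convolutions split the input
#' into a main path (through `n` residual [cspnext_block()]s at the hidden
#' width `cout/2`) and a shortcut path; the concatenation passes through
#' [channel_attention()] and a final 1x1 convolution to `cout` channels.
#' Stride 1 throughout: spatial dims are preserved.
#'
#' @param cin,cout channel counts; `cout` must be even.
#' @param n number of CSPNeXt blocks (default 1).
#' @param depthwise passed to [cspnext_block()].
#' @return a module.
#' @export
csplayer <- function(cin, cout, n = 1, depthwise = FALSE) {
  if (cout %% 2 != 0) {
    stop("csplayer needs even cout for the half-width hidden split",
         call. = FALSE)
  }
  h <- cout %/% 2
  blocks <- lapply(seq_len(n), function(i) {
    cspnext_block(h, h, add = TRUE, depthwise = depthwise)
  })
  names(blocks) <- sprintf("block%d", seq_len(n))
  new_module("csplayer",
             cfg = list(cin = cin, cout = cout, n = n, hidden = h),
             children = c(list(main = conv_bn_act(cin, h, 1),
                               short = conv_bn_act(cin, h, 1)),
                          blocks,
                          list(attn = channel_attention(2 * h),
                               final = conv_bn_act(2 * h, cout, 1))))
}

#' @export
forward.uw_csplayer <- function(mod, x, train = FALSE) {
  ch <- mod$children
  m <- forward(ch$main, x, train)
  for (i in seq_len(mod$cfg$n)) {
    m <- forward(ch[[sprintf("block%d", i)]], m, train)
  }
  s <- forward(ch$short, x, train)
  y <- cat_channels(m, s)
  y <- forward(ch$attn, y, train)
  forward(ch$final, y, train)
}

#' @export
backward.uw_csplayer <- function(mod, dout) {
  ch <- mod$children
  h <- mod$cfg$hidden
  dy <- backward(ch$final, dout)
  dy <- backward(ch$attn, dy)
  dm <- dy[, , seq_len(h), drop = FALSE]
  ds <- dy[, , h + seq_len(h), drop = FALSE]
  for (i in rev(seq_len(mod$cfg$n))) {
    dm <- backward(ch[[sprintf("block%d", i)]], dm)
  }
  backward(ch$main, dm) + backward(ch$short, ds)
}

#' @export
module_profile.uw_csplayer <- function(mod, in_shape) {
  ch <- mod$children
  fl <- 0
  pm <- module_profile(ch$main, in_shape)
  fl <- fl + pm$flops
  sh <- pm$shape
  for (i in seq_len(mod$cfg$n)) {
    p <- module_profile(ch[[sprintf("block%d", i)]], sh)
    sh <- p$shape
    fl <- fl + p$flops
  }
  fl <- fl + module_profile(ch$short, in_shape)$flops
  cat_shape <- c(sh[1], sh[2], 2 * mod$cfg$hidden)
  pa <- module_profile(ch$attn, cat_shape)
  pf <- module_profile(ch$final, cat_shape)
  list(shape = pf$shape, flops = fl + pa$flops + pf$flops)
}

#' Spatial pyramid pooling (fast)
#'
#' A 1x1 reducing convolution, three chained stride-1 `k = 5` max pools, the
#' concatenation of the reduced map with the three pooled maps, and a 1x1
#' expanding convolution. The chained equal-kernel pools reproduce parallel
#' 5/9/13 pooling while touching each pixel fewer times.
#'
#' @param cin,cout channel counts.
#' @param k pooling kernel (odd).
#' @return a module.
#' @export
sppf <- function(cin, cout, k = 5) {
  h <- cin %/% 2
  new_module("sppf", cfg = list(cin = cin, cout = cout, k = k, hidden = h),
             children = list(
               reduce = conv_bn_act(cin, h, 1),
               pool1 = mod_maxpool(k), pool2 = mod_maxpool(k),
               pool3 = mod_maxpool(k),
               expand = conv_bn_act(4 * h, cout, 1)))
}

#' @export
forward.uw_sppf <- function(mod, x, train = FALSE) {
  ch <- mod$children
  y0 <- forward(ch$reduce, x, train)
  y1 <- forward(ch$pool1, y0, train)
  y2 <- forward(ch$pool2, y1, train)
  y3 <- forward(ch$pool3, y2, train)
  forward(ch$expand, cat_channels(cat_channels(y0, y1), cat_channels(y2, y3)),
          train)
}

#' @export
backward.uw_sppf <- function(mod, dout) {
  ch <- mod$children
  h <- mod$cfg$hidden
  dy <- backward(ch$expand, dout)
  d0 <- dy[, , seq_len(h), drop = FALSE]
  d1 <- dy[, , h + seq_len(h), drop = FALSE]
  d2 <- dy[, , 2 * h + seq_len(h), drop = FALSE]
  d3 <- dy[, , 3 * h + seq_len(h), drop = FALSE]
  d2 <- d2 + backward(ch$pool3, d3)
  d1 <- d1 + backward(ch$pool2, d2)
  d0 <- d0 + backward(ch$pool1, d1)
  backward(ch$reduce, d0)
}

#' @export
module_profile.uw_sppf <- function(mod, in_shape) {
  ch <- mod$children
  pr <- module_profile(ch$reduce, in_shape)
  pe <- module_profile(ch$expand,
                       c(pr$shape[1], pr$shape[2], 4 * mod$cfg$hidden))
  list(shape = pe$shape, flops = pr$flops + pe$flops)
}

#' Multi-head self-attention over spatial positions
#'
#' Content-only attention (no positional encodings) over the `H*W` positions
#' of a feature map: learned 1x1 projections produce query/key/value
#' encodings, per-head attention weights are `softmax(q k' / sqrt(d/heads))`,
#' and head outputs are concatenated. Output shape equals input shape.
#'
#' @param c channel count (`d`); must be divisible by `heads`.
#' @param heads number of attention heads (default 4).
#' @return a module.
#' @export
mhsa <- function(c, heads = 4) {
  if (c %% heads != 0) {
    stop("mhsa: channels (", c, ") must be divisible by heads (", heads, ")",
         call. = FALSE)
  }
  new_module("mhsa", cfg = list(c = c, heads = heads, dh = c %/% heads),
             param_shapes = list(wq = c(c, c), wk = c(c, c), wv = c(c, c)))
}

#' @export
forward.uw_mhsa <- function(mod, x, train = FALSE) {
  need_params(mod)
  d <- dim(x)
  n <- d[1] * d[2]
  heads <- mod$cfg$heads
  dh <- mod$cfg$dh
  X <- matrix(x, n, d[3])
  Q <- X %*% mod$params$wq
  K <- X %*% mod$params$wk
  V <- X %*% mod$params$wv
  out <- matrix(0, n, d[3])
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    ix <- (h - 1) * dh + seq_len(dh)
    S <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) / sqrt(dh)
    S <- S - apply(S, 1, max)
    Ah <- exp(S)
    Ah <- Ah / rowSums(Ah)
    out[, ix] <- Ah %*% V[, ix, drop = FALSE]
    A[[h]] <- Ah
  }
  if (train) {
    mod$state$X <- X
    mod$state$Q <- Q
    mod$state$K <- K
    mod$state$V <- V
    mod$state$A <- A
    mod$state$dims <- d
  }
  mod$state$last_attention <- A
  array(out, dim = d)
}

#' @export
backward.uw_mhsa <- function(mod, dout) {
  st <- mod$state
  d <- st$dims
  n <- d[1] * d[2]
  heads <- mod$cfg$heads
  dh <- mod$cfg$dh
  dO <- matrix(dout, n, d[3])
  dQ <- matrix(0, n, d[3])
  dK <- matrix(0, n, d[3])
  dV <- matrix(0, n, d[3])
  for (h in seq_len(heads)) {
    ix <- (h - 1) * dh + seq_len(dh)
    Ah <- st$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dV[, ix] <- crossprod(Ah, dOh)
    dA <- tcrossprod(dOh, st$V[, ix, drop = FALSE])
    dS <- Ah * (dA - rowSums(dA * Ah))
    dQ[, ix] <- dS %*% st$K[, ix, drop = FALSE] / sqrt(dh)
    dK[, ix] <- crossprod(dS, st$Q[, ix, drop = FALSE]) / sqrt(dh)
  }
  acc_grad(mod, "wq", crossprod(st$X, dQ))
  acc_grad(mod, "wk", crossprod(st$X, dK))
  acc_grad(mod, "wv", crossprod(st$X, dV))
  dX <- tcrossprod(dQ, mod$params$wq) + tcrossprod(dK, mod$params$wk) +
    tcrossprod(dV, mod$params$wv)
  array(dX, dim = d)
}

#' @export
module_profile.uw_mhsa <- function(mod, in_shape) {
  c <- mod$cfg$c
  n <- in_shape[1] * in_shape[2]
  # q/k/v projections + attention scores + value mixing (2 FLOPs per MAC)
  list(shape = in_shape, flops = 2 * 3 * c * c * n + 2 * 2 * n * n * c)
}

#' Attention weights from the last forward pass
#'
#' Returns the per-head attention matrices (rows sum to 1) cached by the most
#' recent [forward()] call on an [mhsa()] module.
#'
#' @param mod an `mhsa` module.
#' @return list of `n x n` matrices, one per head.
#' @export
mhsa_attention <- function(mod) {
  stopifnot(inherits(mod, "uw_mhsa"))
  mod$state$last_attention
}

#' Bottleneck transformer block
#'
#' A residual bottleneck whose spatial convolution is replaced by [mhsa()]:
#' a 1x1 extraction CBS unit, multi-head self-attention over the flattened
#' positions, a 1x1 expansion CBS unit, and an elementwise-sum skip. Requires
#' `cin == cout`; shape is preserved.
#'
#' @param c channel count.
#' @param heads attention heads.
#' @return a module.
#' @export
bot_block <- function(c, heads = 4) {
  new_module("bot_block", cfg = list(c = c, heads = heads),
             children = list(
               extract = conv_bn_act(c, c, 1),
               attn = mhsa(c, heads),
               expand = conv_bn_act(c, c, 1)))
}

#' @export
forward.uw_bot_block <- function(mod, x, train = FALSE) {
  y <- forward(mod$children$extract, x, train)
  y <- forward(mod$children$attn, y, train)
  y <- forward(mod$children$expand, y, train)
  y + x
}

#' @export
backward.uw_bot_block <- function(mod, dout) {
  dx <- backward(mod$children$expand, dout)
  dx <- backward(mod$children$attn, dx)
  dx <- backward(mod$children$extract, dx)
  dx + dout
}

#' @export
module_profile.uw_bot_block <- function(mod, in_shape) {
  fl <- 0
  sh <- in_shape
  for (ch in mod$children) {
    p <- module_profile(ch, sh)
    sh <- p$shape
    fl <- fl + p$flops
  }
  list(shape = sh, flops = fl)
}

#' BoT3: bottleneck transformer in a CSP split/concat wrapper
#'
#' The C3 topology with the inner convolution stack replaced by a single
#' [bot_block()]: two parallel 1x1 CBS units split the input at hidden width
#' `cout/2`, the main path runs through the bottleneck transformer, the
#' concatenation is fused by a final 1x1 CBS unit. Spatial dims and the
#' configured channel count are preserved.
#'
#' @param cin,cout channel counts; `cout` must be even.
#' @param heads attention heads.
#' @return a module.
#' @export
bot3 <- function(cin, cout, heads = 4) {
  if (cout %% 2 != 0) {
    stop("bot3 needs even cout for the half-width hidden split", call. = FALSE)
  }
  h <- cout %/% 2
  new_module("bot3", cfg = list(cin = cin, cout = cout, hidden = h),
             children = list(
               main = conv_bn_act(cin, h, 1),
               bot = bot_block(h, heads),
               short = conv_bn_act(cin, h, 1),
               final = conv_bn_act(2 * h, cout, 1)))
}

#' @export
forward.uw_bot3 <- function(mod, x, train = FALSE) {
  ch <- mod$children
  m <- forward(ch$bot, forward(ch$main, x, train), train)
  s <- forward(ch$short, x, train)
  forward(ch$final, cat_channels(m, s), train)
}

#' @export
backward.uw_bot3 <- function(mod, dout) {
  ch <- mod$children
  h <- mod$cfg$hidden
  dy <- backward(ch$final, dout)
  dm <- backward(ch$main, backward(ch$bot, dy[, , seq_len(h), drop = FALSE]))
  ds <- backward(ch$short, dy[, , h + seq_len(h), drop = FALSE])
  dm + ds
}

#' @export
module_profile.uw_bot3 <- function(mod, in_shape) {
  ch <- mod$children
  pm <- module_profile(ch$main, in_shape)
  pb <- module_profile(ch$bot, pm$shape)
  ps <- module_profile(ch$short, in_shape)
  cat_shape <- c(pb$shape[1], pb$shape[2], 2 * mod$cfg$hidden)
  pf <- module_profile(ch$final, cat_shape)
  list(shape = pf$shape,
       flops = pm$flops + pb$flops + ps$flops + pf$flops)
}

# ---- classic YOLOv5 blocks (baseline model) ---------------------------------

# standard bottleneck: 1x1 then 3x3, optional residual
c3_bottleneck <- function(c, shortcut = TRUE) {
  new_module("c3_bottleneck", cfg = list(c = c, add = shortcut),
             children = list(cv1 = conv_bn_act(c, c, 1),
                             cv2 = conv_bn_act(c, c, 3)))
}

#' @export
forward.uw_c3_bottleneck <- function(mod, x, train = FALSE) {
  y <- forward(mod$children$cv2, forward(mod$children$cv1, x, train), train)
  if (mod$cfg$add) y + x else y
}

#' @export
backward.uw_c3_bottleneck <- function(mod, dout) {
  dx <- backward(mod$children$cv1, backward(mod$children$cv2, dout))
  if (mod$cfg$add) dx + dout else dx
}

#' @export
module_profile.uw_c3_bottleneck <- function(mod, in_shape) {
  p1 <- module_profile(mod$children$cv1, in_shape)
  p2 <- module_profile(mod$children$cv2, p1$shape)
  list(shape = p2$shape, flops = p1$flops + p2$flops)
}

# classic C3: split convs + n bottlenecks + fuse (no channel attention)
c3_layer <- function(cin, cout, n = 1, shortcut = TRUE) {
  h <- cout %/% 2
  blocks <- lapply(seq_len(n), function(i) c3_bottleneck(h, shortcut))
  names(blocks) <- sprintf("block%d", seq_len(n))
  new_module("c3_layer", cfg = list(cin = cin, cout = cout, n = n, hidden = h),
             children = c(list(main = conv_bn_act(cin, h, 1),
                               short = conv_bn_act(cin, h, 1)),
                          blocks,
                          list(final = conv_bn_act(2 * h, cout, 1))))
}

#' @export
forward.uw_c3_layer <- function(mod, x, train = FALSE) {
  ch <- mod$children
  m <- forward(ch$main, x, train)
  for (i in seq_len(mod$cfg$n)) m <- forward(ch[[sprintf("block%d", i)]], m, train)
  s <- forward(ch$short, x, train)
  forward(ch$final, cat_channels(m, s), train)
}

#' @export
backward.uw_c3_layer <- function(mod, dout) {
  ch <- mod$children
  h <- mod$cfg$hidden
  dy <- backward(ch$final, dout)
  dm <- dy[, , seq_len(h), drop = FALSE]
  ds <- dy[, , h + seq_len(h), drop = FALSE]
  for (i in rev(seq_len(mod$cfg$n))) dm <- backward(ch[[sprintf("block%d", i)]], dm)
  backward(ch$main, dm) + backward(ch$short, ds)
}

#' @export
module_profile.uw_c3_layer <- function(mod, in_shape) {
  ch <- mod$children
  pm <- module_profile(ch$main, in_shape)
  fl <- pm$flops
  sh <- pm$shape
  for (i in seq_len(mod$cfg$n)) {
    p <- module_profile(ch[[sprintf("block%d", i)]], sh)
    sh <- p$shape
    fl <- fl + p$flops
  }
  fl <- fl + module_profile(ch$short, in_shape)$flops
  cat_shape <- c(sh[1], sh[2], 2 * mod$cfg$hidden)
  pf <- module_profile(ch$final, cat_shape)
  list(shape = pf$shape, flops = fl + pf$flops)
}
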