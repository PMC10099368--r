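#' @useDynLib uwdet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- module framework -------------------------------------------------------
# A module is a mutable environment carrying:
#   type          character tag
#   cfg           arbitrary configuration fields
#   param_shapes  named list of integer dim vectors (learnable tensors)
#   params        named list of arrays (NULL until uw_init_params())
#   grads         accumulated gradients, parallel to params
#   state         non-learnable state (e.g. batch-norm running moments)
#   children      named flat list of sub-modules
# Parameters are allocated lazily so that large models can be assembled for
# parameter/FLOP accounting without touching memory for their weights.

new_module <- function(type, cfg = list(), param_shapes = list(),
                       children = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$cfg <- cfg
  e$param_shapes <- param_shapes
  e$params <- NULL
  e$grads <- NULL
  e$state <- list()
  e$children <- children
  class(e) <- c(paste0("uw_", type), "uw_module")
  e
}

is_module <- function(x) inherits(x, "uw_module")

#' Run a module forward
#'
#' Applies a block to a feature map (an `H x W x C` numeric array). When
#' `train = TRUE`, normalization layers use and update per-sample statistics
#' and every module caches what its backward pass needs.
#'
#' @param mod a module built by one of the block constructors.
#' @param x numeric array `H x W x C`.
#' @param train logical; training mode.
#' @return the output feature map.
#' @export
forward <- function(mod, x, train = FALSE) UseMethod("forward")

#' Run a module backward
#'
#' Propagates the gradient of a scalar loss with respect to the module output
#' back to its input, accumulating parameter gradients inside the module.
#' Must follow a `forward(..., train = TRUE)` call on the same module.
#'
#' @param mod a module.
#' @param dout gradient with respect to the module output.
#' @return gradient with respect to the module input.
#' @export
backward <- function(mod, dout) UseMethod("backward")

# per-type analytic profile: list(shape = c(H, W, C), flops = <count>)
module_profile <- function(mod, in_shape) UseMethod("module_profile")

#' Count learnable parameters of a module
#'
#' Counts every learnable scalar (convolution weights and biases plus
#' batch-norm affine terms; running moments are state, not parameters).
#' Works on lazily-built modules whose weights were never allocated.
#'
#' @param mod a module.
#' @return total number of learnable scalars.
#' @export
n_params <- function(mod) {
  stopifnot(is_module(mod))
  own <- sum(vapply(mod$param_shapes, prod, numeric(1)))
  own + sum(vapply(mod$children, n_params, numeric(1)))
}

#' Allocate and initialize module weights
#'
#' Convolution weights get scaled-Gaussian (He) initialization from the
#' current RNG stream, biases zero, batch-norm gain one / offset zero.
#'
#' @param mod a module.
#' @param zero logical; if `TRUE` all weights are zero (useful for tests).
#' @return the module, invisibly.
#' @export
uw_init_params <- function(mod, zero = FALSE) {
  stopifnot(is_module(mod))
  if (length(mod$param_shapes) > 0 && is.null(mod$params)) {
    mod$params <- lapply(names(mod$param_shapes), function(nm) {
      shp <- mod$param_shapes[[nm]]
      n <- prod(shp)
      v <- if (zero) numeric(n) else init_values(mod, nm, shp)
      array(v, dim = shp)
    })
    names(mod$params) <- names(mod$param_shapes)
  }
  for (ch in mod$children) uw_init_params(ch, zero = zero)
  invisible(mod)
}

init_values <- function(mod, nm, shp) {
  n <- prod(shp)
  if (nm %in% c("gamma")) return(rep(1, n))
  if (nm %in% c("beta", "b")) return(numeric(n))
  fan_in <- if (length(shp) == 4) prod(shp[1:3]) else shp[1]
  stats::rnorm(n, sd = sqrt(2 / max(fan_in, 1)))
}

zero_grads <- function(mod) {
  mod$grads <- NULL
  for (ch in mod$children) zero_grads(ch)
  invisible(mod)
}

acc_grad <- function(mod, nm, g) {
  if (is.null(mod$grads)) mod$grads <- list()
  if (is.null(mod$grads[[nm]])) mod$grads[[nm]] <- g else {
    mod$grads[[nm]] <- mod$grads[[nm]] + g
  }
  invisible(NULL)
}

# walk all modules, applying fn(mod)
module_walk <- function(mod, fn) {
  fn(mod)
  for (ch in mod$children) module_walk(ch, fn)
  invisible(NULL)
}

need_params <- function(mod) {
  if (length(mod$param_shapes) > 0 && is.null(mod$params)) {
    stop("module '", mod$type, "' has unallocated weights; call uw_init_params()",
         call. = FALSE)
  }
}

# ---- activations ------------------------------------------------------------

silu <- function(x) x * stats::plogis(x)
silu_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

#' Hard sigmoid
#'
#' Piecewise-linear sigmoid approximation `clip(x/6 + 0.5, 0, 1)`, the gate
#' activation of the channel-attention block.
#'
#' @param x numeric.
#' @return values in `[0, 1]`.
#' @export
hard_sigmoid <- function(x) pmin(pmax(x / 6 + 0.5, 0), 1)
hard_sigmoid_grad <- function(x) ifelse(x > -3 & x < 3, 1 / 6, 0)

# ---- conv2d -----------------------------------------------------------------

# groups is either 1 (dense) or cin (depth-wise, requires cin == cout)
mod_conv2d <- function(cin, cout, k = 1, stride = 1, pad = k %/% 2,
                       bias = FALSE, groups = 1) {
  stopifnot(groups %in% c(1, cin))
  if (groups > 1 && cin != cout) stop("depth-wise conv requires cin == cout")
  shapes <- list(w = c(k, k, cin %/% groups, if (groups > 1) 1 else cout))
  if (groups > 1) shapes$w <- c(k, k, 1, cout)
  if (bias) shapes$b <- cout
  new_module("conv2d",
             cfg = list(cin = cin, cout = cout, k = k, stride = stride,
                        pad = pad, bias = bias, groups = groups),
             param_shapes = shapes)
}

#' @export
forward.uw_conv2d <- function(mod, x, train = FALSE) {
  need_params(mod)
  cfg <- mod$cfg
  if (dim(x)[3] != cfg$cin) {
    stop("conv2d configured for ", cfg$cin, " input channels, got ", dim(x)[3],
         call. = FALSE)
  }
  b <- if (cfg$bias) as.numeric(mod$params$b) else numeric(0)
  if (cfg$groups == 1) {
    wmat <- matrix(mod$params$w, nrow = cfg$k * cfg$k * cfg$cin, ncol = cfg$cout)
    out <- cpp_conv2d_fwd(x, wmat, b, cfg$k, cfg$stride, cfg$pad)
  } else {  # depth-wise: one single-channel conv per channel
    outs <- lapply(seq_len(cfg$cin), function(c) {
      wmat <- matrix(mod$params$w[, , 1, c], nrow = cfg$k * cfg$k, ncol = 1)
      cpp_conv2d_fwd(x[, , c, drop = FALSE], wmat,
                     if (cfg$bias) b[c] else numeric(0),
                     cfg$k, cfg$stride, cfg$pad)
    })
    out <- array(unlist(outs), dim = c(dim(outs[[1]])[1:2], cfg$cin))
  }
  if (train) mod$state$x <- x
  out
}

#' @export
backward.uw_conv2d <- function(mod, dout) {
  cfg <- mod$cfg
  x <- mod$state$x
  if (cfg$groups == 1) {
    wmat <- matrix(mod$params$w, nrow = cfg$k * cfg$k * cfg$cin, ncol = cfg$cout)
    res <- cpp_conv2d_bwd(x, wmat, dout, cfg$k, cfg$stride, cfg$pad, cfg$bias)
    acc_grad(mod, "w", array(res$dw, dim = mod$param_shapes$w))
    if (cfg$bias) acc_grad(mod, "b", as.numeric(res$db))
    res$dx
  } else {
    dx <- array(0, dim = dim(x))
    dw <- array(0, dim = mod$param_shapes$w)
    db <- numeric(cfg$cout)
    for (c in seq_len(cfg$cin)) {
      wmat <- matrix(mod$params$w[, , 1, c], nrow = cfg$k * cfg$k, ncol = 1)
      res <- cpp_conv2d_bwd(x[, , c, drop = FALSE], wmat,
                            dout[, , c, drop = FALSE],
                            cfg$k, cfg$stride, cfg$pad, cfg$bias)
      dx[, , c] <- res$dx[, , 1]
      dw[, , 1, c] <- array(res$dw, dim = c(cfg$k, cfg$k))
      if (cfg$bias) db[c] <- as.numeric(res$db)
    }
    acc_grad(mod, "w", dw)
    if (cfg$bias) acc_grad(mod, "b", db)
    dx
  }
}

#' @export
module_profile.uw_conv2d <- function(mod, in_shape) {
  cfg <- mod$cfg
  ho <- (in_shape[1] + 2 * cfg$pad - cfg$k) %/% cfg$stride + 1
  wo <- (in_shape[2] + 2 * cfg$pad - cfg$k) %/% cfg$stride + 1
  macs <- cfg$k * cfg$k * (cfg$cin / cfg$groups) * cfg$cout * ho * wo
  flops <- 2 * macs + if (cfg$bias) cfg$cout * ho * wo else 0
  list(shape = c(ho, wo, cfg$cout), flops = flops)
}

# ---- batch norm -------------------------------------------------------------

mod_batchnorm <- function(c, eps = 1e-3, momentum = 0.03) {
  m <- new_module("batchnorm",
                  cfg = list(c = c, eps = eps, momentum = momentum),
                  param_shapes = list(gamma = c, beta = c))
  m$state$running_mean <- numeric(c)
  m$state$running_var <- rep(1, c)
  m
}

#' @export
forward.uw_batchnorm <- function(mod, x, train = FALSE) {
  need_params(mod)
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  frozen <- isTRUE(mod$state$frozen)
  if ((train && !frozen) || isTRUE(mod$state$accumulate)) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    if (isTRUE(mod$state$accumulate)) {
      mod$state$acc_mean <- mod$state$acc_mean + mu
      mod$state$acc_var <- mod$state$acc_var + v * n / max(n - 1, 1)
      mod$state$acc_n <- mod$state$acc_n + 1
    } else {
      mom <- mod$cfg$momentum
      mod$state$running_mean <- (1 - mom) * mod$state$running_mean + mom * mu
      mod$state$running_var <- (1 - mom) * mod$state$running_var +
        mom * v * n / max(n - 1, 1)
    }
  } else {
    mu <- mod$state$running_mean
    v <- mod$state$running_var
  }
  invstd <- 1 / sqrt(v + mod$cfg$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, as.numeric(mod$params$gamma), "*"), 2,
             as.numeric(mod$params$beta), "+")
  if (train) {
    mod$state$xhat <- xhat
    mod$state$invstd <- invstd
    mod$state$dims <- d
    mod$state$bwd_frozen <- frozen
  }
  array(y, dim = d)
}

#' @export
backward.uw_batchnorm <- function(mod, dout) {
  d <- mod$state$dims
  n <- d[1] * d[2]
  dy <- matrix(dout, n, d[3])
  xhat <- mod$state$xhat
  acc_grad(mod, "gamma", colSums(dy * xhat))
  acc_grad(mod, "beta", colSums(dy))
  g <- as.numeric(mod$params$gamma)
  dxhat <- sweep(dy, 2, g, "*")
  if (isTRUE(mod$state$bwd_frozen)) {
    # frozen statistics are constants with respect to the input
    dx <- sweep(dxhat, 2, mod$state$invstd, "*")
  } else {
    # standard batch-norm backward over the n = H*W normalization axis
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dx <- sweep(t1 - t2, 2, mod$state$invstd, "*")
  }
  array(dx, dim = d)
}

#' @export
module_profile.uw_batchnorm <- function(mod, in_shape) {
  list(shape = in_shape, flops = 2 * prod(in_shape))
}

# ---- activations as modules -------------------------------------------------

mod_act <- function(kind = c("silu", "hardsigmoid", "none")) {
  kind <- match.arg(kind)
  new_module("act", cfg = list(kind = kind))
}

#' @export
forward.uw_act <- function(mod, x, train = FALSE) {
  if (train) mod$state$x <- x
  switch(mod$cfg$kind,
         silu = silu(x),
         hardsigmoid = hard_sigmoid(x),
         none = x)
}

#' @export
backward.uw_act <- function(mod, dout) {
  x <- mod$state$x
  switch(mod$cfg$kind,
         silu = dout * silu_grad(x),
         hardsigmoid = dout * hard_sigmoid_grad(x),
         none = dout)
}

#' @export
module_profile.uw_act <- function(mod, in_shape) {
  list(shape = in_shape, flops = 0)
}

# ---- sequential -------------------------------------------------------------

mod_sequential <- function(children) {
  if (is.null(names(children))) {
    names(children) <- sprintf("m%d", seq_along(children))
  }
  new_module("sequential", children = children)
}

#' @export
forward.uw_sequential <- function(mod, x, train = FALSE) {
  for (ch in mod$children) x <- forward(ch, x, train = train)
  x
}

#' @export
backward.uw_sequential <- function(mod, dout) {
  for (ch in rev(mod$children)) dout <- backward(ch, dout)
  dout
}

#' @export
module_profile.uw_sequential <- function(mod, in_shape) {
  fl <- 0
  for (ch in mod$children) {
    p <- module_profile(ch, in_shape)
    in_shape <- p$shape
    fl <- fl + p$flops
  }
  list(shape = in_shape, flops = fl)
}

# ---- max pool / upsample ----------------------------------------------------

mod_maxpool <- function(k = 5, stride = 1, pad = k %/% 2) {
  new_module("maxpool", cfg = list(k = k, stride = stride, pad = pad))
}

#' @export
forward.uw_maxpool <- function(mod, x, train = FALSE) {
  res <- cpp_maxpool_fwd(x, mod$cfg$k, mod$cfg$stride, mod$cfg$pad)
  if (train) {
    mod$state$idx <- res$idx
    mod$state$dims <- dim(x)
  }
  res$out
}

#' @export
backward.uw_maxpool <- function(mod, dout) {
  d <- mod$state$dims
  cpp_maxpool_bwd(mod$state$idx, dout, d[1], d[2])
}

#' @export
module_profile.uw_maxpool <- function(mod, in_shape) {
  ho <- (in_shape[1] + 2 * mod$cfg$pad - mod$cfg$k) %/% mod$cfg$stride + 1
  wo <- (in_shape[2] + 2 * mod$cfg$pad - mod$cfg$k) %/% mod$cfg$stride + 1
  list(shape = c(ho, wo, in_shape[3]), flops = 0)
}

mod_upsample <- function(factor = 2) {
  new_module("upsample", cfg = list(factor = factor))
}

#' @export
forward.uw_upsample <- function(mod, x, train = FALSE) {
  f <- mod$cfg$factor
  if (train) mod$state$dims <- dim(x)
  x[rep(seq_len(dim(x)[1]), each = f), rep(seq_len(dim(x)[2]), each = f), ,
    drop = FALSE]
}

#' @export
backward.uw_upsample <- function(mod, dout) {
  f <- mod$cfg$factor
  d <- mod$state$dims
  dx <- array(0, dim = d)
  for (i in seq_len(f)) {
    for (j in seq_len(f)) {
      dx <- dx + dout[seq(i, by = f, length.out = d[1]),
                      seq(j, by = f, length.out = d[2]), , drop = FALSE]
    }
  }
  dx
}

#' @export
module_profile.uw_upsample <- function(mod, in_shape) {
  f <- mod$cfg$factor
  list(shape = c(in_shape[1] * f, in_shape[2] * f, in_shape[3]), flops = 0)
}

# concat along channels (graph-level helper, not a module)
cat_channels <- function(a, b) {
  stopifnot(all(dim(a)[1:2] == dim(b)[1:2]))
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}
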