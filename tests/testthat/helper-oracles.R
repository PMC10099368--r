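# Independent oracles used by the tests. Each reimplements an operation in
# the most literal way available (sliding windows, nested loops, dense
# threshold sweeps) and stays independent of the package's code paths.

# direct sliding-window convolution on an H x W x Cin array
oracle_conv2d <- function(x, w, bias = NULL, stride = 1, pad = 0) {
  k <- dim(w)[1]
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  ho <- (d[1] + 2 * pad - k) %/% stride + 1
  wo <- (d[2] + 2 * pad - k) %/% stride + 1
  cout <- dim(w)[4]
  out <- array(0, dim = c(ho, wo, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(ho)) {
      for (j in seq_len(wo)) {
        i0 <- (i - 1) * stride + 1
        j0 <- (j - 1) * stride + 1
        out[i, j, co] <- sum(xp[i0:(i0 + k - 1), j0:(j0 + k - 1), ] *
                               w[, , , co]) +
          if (is.null(bias)) 0 else bias[co]
      }
    }
  }
  out
}

# per-position two-nested-loop multi-head attention (z = W' p convention)
oracle_mhsa <- function(x, wq, wk, wv, heads) {
  d <- dim(x)
  n <- d[1] * d[2]
  C <- d[3]
  dh <- C %/% heads
  X <- matrix(x, n, C)
  Q <- X %*% wq
  K <- X %*% wk
  V <- X %*% wv
  out <- matrix(0, n, C)
  for (h in seq_len(heads)) {
    ix <- (h - 1) * dh + seq_len(dh)
    for (i in seq_len(n)) {
      logits <- numeric(n)
      for (j in seq_len(n)) {
        logits[j] <- sum(Q[i, ix] * K[j, ix]) / sqrt(dh)
      }
      a <- exp(logits - max(logits))
      a <- a / sum(a)
      for (j in seq_len(n)) {
        out[i, ix] <- out[i, ix] + a[j] * V[j, ix]
      }
    }
  }
  array(out, dim = d)
}

# stride-1 same-padded max pool with kernel k (parallel form)
oracle_maxpool <- function(x, k) {
  d <- dim(x)
  pad <- k %/% 2
  out <- array(0, dim = d)
  for (c in seq_len(d[3])) {
    xp <- matrix(-Inf, d[1] + 2 * pad, d[2] + 2 * pad)
    xp[pad + seq_len(d[1]), pad + seq_len(d[2])] <- x[, , c]
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        out[i, j, c] <- max(xp[i:(i + k - 1), j:(j + k - 1)])
      }
    }
  }
  out
}

# quadratic-scan suppression: a detection survives iff no higher-confidence
# same-class SURVIVOR overlaps it above the threshold (computed iteratively
# but phrased as an independent pairwise scan)
oracle_nms <- function(dets, iou_thresh, conf_thresh) {
  dets <- dets[dets$conf >= conf_thresh, , drop = FALSE]
  dets <- dets[order(-dets$conf), , drop = FALSE]
  n <- nrow(dets)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !alive[j]) next
      if (dets$class_id[i] != dets$class_id[j]) next
      o <- uwdet::iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                      as.numeric(dets[j, c("x1", "y1", "x2", "y2")]))
      if (o > iou_thresh) alive[j] <- FALSE
    }
  }
  dets[alive, , drop = FALSE]
}

# dense-threshold numeric integration of the PR curve: sweep a fine grid of
# confidence cutoffs, compute (recall, precision-envelope) points, integrate
oracle_ap_dense <- function(dets, truths, iou_threshold) {
  if (nrow(truths) == 0 || nrow(dets) == 0) return(0)
  if (is.null(dets$image)) dets$image <- rep("img", nrow(dets))
  if (is.null(truths$image)) truths$image <- rep("img", nrow(truths))
  cuts <- sort(unique(c(seq(0, 1, by = 1e-3), dets$conf - 1e-9)))
  pts <- t(vapply(cuts, function(ct) {
    d <- dets[dets$conf >= ct, , drop = FALSE]
    if (nrow(d) == 0) return(c(0, 1))
    tal <- uwdet::match_detections(d, truths, iou_threshold,
                                   num_classes = max(truths$class_id) + 1)
    c(uwdet::recall(tal), uwdet::precision(tal))
  }, numeric(2)))
  rec <- pts[, 1]
  prec <- pts[, 2]
  ord <- order(rec, -prec)
  rec <- rec[ord]
  prec <- prec[ord]
  # precision envelope, then 101-point sampling (same integral definition)
  env <- rev(cummax(rev(prec)))
  grid <- seq(0, 1, by = 0.01)
  mean(vapply(grid, function(r) {
    ix <- which(rec >= r - 1e-12)
    if (length(ix) == 0) 0 else max(env[ix])
  }, numeric(1)))
}

# exhaustive one-to-one assignment: over all injective det->truth maps that
# respect class and IoU threshold, maximize TP count (ties by total IoU)
oracle_exhaustive_tally <- function(dets, truths, iou_threshold) {
  nd <- nrow(dets)
  nt <- nrow(truths)
  best_tp <- 0
  db <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  tb <- as.matrix(truths[, c("x1", "y1", "x2", "y2")])
  feas <- matrix(FALSE, nd, nt)
  for (i in seq_len(nd)) {
    for (j in seq_len(nt)) {
      feas[i, j] <- dets$class_id[i] == truths$class_id[j] &&
        uwdet::iou(db[i, ], tb[j, ]) >= iou_threshold
    }
  }
  assign_rec <- function(i, used) {
    if (i > nd) return(0)
    best <- assign_rec(i + 1, used)  # leave det i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && feas[i, j]) {
        u <- used
        u[j] <- TRUE
        best <- max(best, 1 + assign_rec(i + 1, u))
      }
    }
    best
  }
  tp <- if (nt == 0 || nd == 0) 0 else assign_rec(1, logical(nt))
  list(tp = tp, fp = nd - tp, fn = nt - tp)
}

# closed-form parameter counts (independent formulas, no package walker)
cf_conv_bn <- function(cin, cout, k) k * k * cin * cout + 2 * cout
cf_cspnext <- function(h) cf_conv_bn(h, h, 3) + cf_conv_bn(h, h, 5)
cf_attn <- function(c) c * c + c
cf_csplayer <- function(cin, cout, n) {
  h <- cout / 2
  2 * cf_conv_bn(cin, h, 1) + n * cf_cspnext(h) + cf_attn(2 * h) +
    cf_conv_bn(2 * h, cout, 1)
}
cf_sppf <- function(cin, cout) {
  cf_conv_bn(cin, cin / 2, 1) + cf_conv_bn(2 * cin, cout, 1)
}
cf_bot <- function(c) 2 * cf_conv_bn(c, c, 1) + 3 * c * c
cf_bot3 <- function(cin, cout) {
  h <- cout / 2
  2 * cf_conv_bn(cin, h, 1) + cf_bot(h) + cf_conv_bn(2 * h, cout, 1)
}
cf_c3 <- function(cin, cout, n, h = cout / 2) {
  2 * cf_conv_bn(cin, h, 1) + n * (cf_conv_bn(h, h, 1) + cf_conv_bn(h, h, 3)) +
    cf_conv_bn(2 * h, cout, 1)
}

# numeric gradient checker: loss = sum(forward(mod, x) * R)
numgrad_check <- function(mod, x, n_entries = 4, eps = 1e-5, seed = 99) {
  set.seed(seed)
  y <- uwdet::forward(mod, x, train = TRUE)
  R <- array(stats::rnorm(length(y)), dim = dim(y))
  dx <- uwdet::backward(mod, R)
  worst <- 0
  # input gradient at sampled entries
  for (ix in sample(length(x), min(n_entries, length(x)))) {
    xp <- x
    xp[ix] <- xp[ix] + eps
    xm <- x
    xm[ix] <- xm[ix] - eps
    num <- (sum(uwdet::forward(mod, xp, train = TRUE) * R) -
              sum(uwdet::forward(mod, xm, train = TRUE) * R)) / (2 * eps)
    worst <- max(worst, abs(num - dx[ix]) / max(abs(num), 1e-4))
  }
  worst
}
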