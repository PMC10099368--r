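# Block-level contracts: shapes, closed-form parameter counts, residual
# identities, oracle equivalences, and backward-pass gradient checks.

test_that("conv_bn_act obeys stride arithmetic and the zero fixed point", {
  cb <- init_mod(conv_bn_act(3, 8, k = 3, stride = 2))
  y <- forward(cb, rand_fmap(64, 64, 3))
  expect_equal(dim(y), c(32, 32, 8))
  # batch norm at identity (fresh running stats), SiLU(0) = 0
  y0 <- forward(cb, array(0, dim = c(16, 16, 3)))
  expect_equal(max(abs(y0)), 0)
  expect_error(forward(cb, rand_fmap(8, 8, 5)), "input channels")
})

test_that("convolution matches a sliding-window dot-product oracle", {
  set.seed(3)
  x <- rand_fmap(5, 5, 1, seed = 3)
  cv <- uwdet:::mod_conv2d(1, 4, k = 3, stride = 1, bias = TRUE)
  uw_init_params(cv)
  y <- forward(cv, x)
  yo <- oracle_conv2d(x, cv$params$w, as.numeric(cv$params$b), stride = 1,
                      pad = 1)
  expect_lt(max(abs(y - yo)), 1e-5)
  # and for stride 2 on a wider map
  x2 <- rand_fmap(9, 9, 3, seed = 4)
  cv2 <- uwdet:::mod_conv2d(3, 2, k = 3, stride = 2)
  uw_init_params(cv2)
  expect_lt(max(abs(forward(cv2, x2) -
                      oracle_conv2d(x2, cv2$params$w, NULL, 2, 1))), 1e-5)
})

test_that("cspnext block: residual identity, 5x5 kernel, closed-form params", {
  blk <- init_mod(cspnext_block(16, 16, add = TRUE))
  zero_bn_gammas(blk)
  x <- rand_fmap(7, 7, 16, seed = 2)
  expect_equal(forward(blk, x), x)  # zeroed branch scales -> identity
  expect_identical(blk$cfg$kernels[2], 5L)
  blk64 <- cspnext_block(64, 64)
  expect_equal(n_params(blk64),
               3 * 3 * 64 * 64 + 5 * 5 * 64 * 64 + 2 * (2 * 64))
  expect_error(cspnext_block(8, 16, add = TRUE), "cin == cout")
})

test_that("channel attention gates in [0,1] and pools exactly", {
  ca <- init_mod(channel_attention(6))
  x <- rand_fmap(9, 9, 6, seed = 8, sd = 2)
  y <- forward(ca, x)
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  expect_equal(dim(y), dim(x))
  # identity projection, zero bias, channel-constant 3 -> gate hard_sigmoid(3)=1
  ca2 <- channel_attention(2)
  uw_init_params(ca2, zero = TRUE)
  ca2$params$w <- diag(2)
  xc <- array(rep(c(3, -9), each = 16), dim = c(4, 4, 2))
  expect_equal(hard_sigmoid(3), 1.0)
  y2 <- forward(ca2, xc)
  expect_equal(y2[, , 1], xc[, , 1])        # gate 1 passes through
  expect_equal(max(abs(y2[, , 2])), 0)      # hard_sigmoid(-9) = 0 blocks
})

test_that("csplayer preserves shape and splits at half width", {
  lay <- csplayer(12, 16)
  expect_equal(lay$cfg$n, 1)  # default single CSPNeXt block
  expect_equal(formals(csplayer)$n, 1)
  init_mod(lay)
  y <- forward(lay, rand_fmap(12, 12, 12, seed = 5))
  expect_equal(dim(y), c(12, 12, 16))
  # concat width = 2 x hidden before the final conv (shape-propagation walk)
  expect_equal(lay$children$attn$cfg$c, 2 * lay$cfg$hidden)
  expect_equal(lay$children$final$cfg$cin, 2 * lay$cfg$hidden)
  expect_equal(n_params(lay), cf_csplayer(12, 16, 1))
  expect_error(csplayer(8, 9), "even")
})

test_that("sppf: constant maps, shape preservation, SPP equivalence", {
  x <- array(1.7, dim = c(6, 6, 2))
  expect_true(all(uwdet:::cpp_maxpool_fwd(x, 5, 1, 2)$out == 1.7))
  sp <- init_mod(sppf(8, 12))
  y <- forward(sp, rand_fmap(10, 10, 8, seed = 6))
  expect_equal(dim(y), c(10, 10, 12))
  # chained k=5 pools == parallel k=5/9/13 pooling
  z <- rand_fmap(8, 8, 3, seed = 7)
  p1 <- uwdet:::cpp_maxpool_fwd(z, 5, 1, 2)$out
  p2 <- uwdet:::cpp_maxpool_fwd(p1, 5, 1, 2)$out
  p3 <- uwdet:::cpp_maxpool_fwd(p2, 5, 1, 2)$out
  expect_lt(max(abs(p1 - oracle_maxpool(z, 5))), 1e-6)
  expect_lt(max(abs(p2 - oracle_maxpool(z, 9))), 1e-6)
  expect_lt(max(abs(p3 - oracle_maxpool(z, 13))), 1e-6)
})

test_that("mhsa matches the brute-force attention oracle and normalizes rows", {
  expect_equal(formals(mhsa)$heads, 4)
  at <- init_mod(mhsa(8, heads = 2), seed = 11)
  x <- rand_fmap(4, 4, 8, seed = 12)
  y <- forward(at, x)
  yo <- oracle_mhsa(x, at$params$wq, at$params$wk, at$params$wv, heads = 2)
  expect_lt(max(abs(y - yo)), 1e-5)
  for (A in mhsa_attention(at)) {
    expect_true(all(abs(rowSums(A) - 1) < 1e-6))
  }
  # largest spec'd case: 8 x 8 x 16
  at2 <- init_mod(mhsa(16, heads = 4), seed = 13)
  x2 <- rand_fmap(8, 8, 16, seed = 14)
  expect_lt(max(abs(forward(at2, x2) -
                      oracle_mhsa(x2, at2$params$wq, at2$params$wk,
                                  at2$params$wv, 4))), 1e-5)
  # singleton softmax: 1x1 spatial input -> output is the value projection
  at3 <- init_mod(mhsa(4, heads = 2), seed = 15)
  x3 <- rand_fmap(1, 1, 4, seed = 16)
  expect_equal(as.numeric(forward(at3, x3)),
               as.numeric(matrix(x3, 1, 4) %*% at3$params$wv),
               tolerance = 1e-10)
  expect_error(mhsa(10, heads = 4), "divisible")
})

test_that("bot block: residual identity, shape, fewer params than 3x3 conv", {
  bb <- init_mod(bot_block(8))
  zero_bn_gammas(bb)
  # zeroed extraction/expansion branch -> pure skip
  x <- rand_fmap(5, 5, 8, seed = 21)
  expect_equal(forward(bb, x), x)
  bb2 <- init_mod(bot_block(16, heads = 4), seed = 22)
  y <- forward(bb2, rand_fmap(8, 8, 16, seed = 23))
  expect_equal(dim(y), c(8, 8, 16))
  # parameter count strictly below a 3x3-conv ResNet bottleneck at equal width
  c <- 64
  expect_lt(n_params(bot_block(c)), 3 * 3 * c * c + 2 * c)
  expect_equal(n_params(bot_block(c)), cf_bot(c))
})

test_that("bot3 preserves size, holds exactly one MHSA, reduces when zeroed", {
  b3 <- init_mod(bot3(16, 16), seed = 31)
  x <- rand_fmap(6, 6, 16, seed = 32)
  y <- forward(b3, x)
  expect_equal(dim(y), dim(x))
  expect_equal(count_modules(b3, "uw_mhsa"), 1)
  expect_equal(n_params(b3), cf_bot3(16, 16))
  # zero the main-branch entry conv and the bot interior: output must equal
  # final(concat(0, short(x)))
  uw_init_params(b3$children$main, zero = TRUE)  # already allocated; force
  b3$children$main$children$conv$params$w[] <- 0
  zero_bn_gammas(b3$children$main)
  zero_bn_gammas(b3$children$bot)
  uwdet:::module_walk(b3$children$bot, function(m) {
    if (!is.null(m$params)) for (nm in names(m$params)) m$params[[nm]][] <- 0
  })
  y2 <- forward(b3, x)
  s <- forward(b3$children$short, x)
  manual <- forward(b3$children$final,
                    uwdet:::cat_channels(array(0, dim = dim(s)), s))
  expect_equal(y2, manual)
})

test_that("stride-1 blocks preserve spatial dims across random configs", {
  set.seed(41)
  for (rep in 1:6) {
    h <- sample(4:10, 1)
    w <- sample(4:10, 1)
    cin <- 2 * sample(2:6, 1)
    cout <- 4 * sample(1:3, 1)  # divisible by 4: bot3 hidden = cout/2 splits
                                # across 2 attention heads
    mk <- switch(sample(4, 1),
                 csplayer(cin, cout),
                 bot3(cin, cout, heads = 2),
                 sppf(cin, cout),
                 cspnext_block(cin, cin))
    uw_init_params(mk)
    y <- forward(mk, rand_fmap(h, w, cin, seed = 100 + rep))
    expect_equal(dim(y)[1:2], c(h, w))
    declared <- if (inherits(mk, "uw_cspnext_block")) cin else cout
    expect_equal(dim(y)[3], declared)
    expect_true(all(is.finite(y)))
  }
})

test_that("backward passes agree with numeric gradients", {
  checks <- list(
    conv_bn_act(3, 4, k = 3),
    cspnext_block(4, 4),
    channel_attention(4),
    csplayer(4, 4),
    sppf(4, 4),
    mhsa(4, heads = 2),
    bot3(4, 4, heads = 2)
  )
  for (i in seq_along(checks)) {
    mod <- init_mod(checks[[i]], seed = 50 + i)
    x <- rand_fmap(5, 5, if (inherits(mod, "uw_conv_bn_act")) 3 else 4,
                   seed = 60 + i)
    expect_lt(numgrad_check(mod, x), 1e-4)
  }
})

test_that("depth-wise 5x5 variant is available but not the default", {
  blk <- cspnext_block(8, 8)
  expect_false(blk$cfg$depthwise)
  dwb <- init_mod(cspnext_block(8, 8, depthwise = TRUE), seed = 71)
  y <- forward(dwb, rand_fmap(6, 6, 8, seed = 72))
  expect_equal(dim(y), c(6, 6, 8))
  # depth-wise 5x5 has k*k*c (+bn) instead of k*k*c^2 parameters
  expect_equal(n_params(dwb),
               3 * 3 * 8 * 8 + 2 * 8 + 5 * 5 * 8 + 2 * 8)
})
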