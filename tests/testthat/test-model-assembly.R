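# Graph structure audits, parameter/FLOP accounting against closed-form
# sums and the reported footprints, and forward contracts.

test_that("improved backbone is 1 stem (3 convs) + 4 stages with SPPF last", {
  cfg <- model_config(num_classes = 5, input_size = 416, scale = "n",
                      variant = "improved", repeats_profile = "unit")
  bb <- build_backbone(cfg)
  names_ <- vapply(bb$nodes, `[[`, character(1), "name")
  expect_equal(sum(grepl("^stem", names_)), 3)
  expect_equal(sum(grepl("^stage\\d_conv$", names_)), 4)
  expect_equal(sum(grepl("^stage\\d_csp$", names_)), 4)
  expect_equal(sum(names_ == "stage4_sppf"), 1)
  # SPPF sits in stage 4, between its conv and its CSP layer
  expect_equal(which(names_ == "stage4_sppf"),
               which(names_ == "stage4_conv") + 1)
})

test_that("416 input yields the 52/26/13 pyramid", {
  cfg <- model_config(num_classes = 5, input_size = 416, scale = "n",
                      variant = "improved", repeats_profile = "unit")
  model <- build_model(cfg)
  prof <- uwdet:::graph_profile(model, 416)
  shp <- function(i) as.integer(strsplit(prof$out[i], "x")[[1]])
  expect_equal(shp(model$pyramid["p3"])[1:2], c(52, 52))
  expect_equal(shp(model$pyramid["p4"])[1:2], c(26, 26))
  expect_equal(shp(model$pyramid["p5"])[1:2], c(13, 13))
})

test_that("exactly one BoT3 sits on the stride-16 neck branch", {
  cfg <- model_config(num_classes = 5, scale = "n", input_size = 416,
                      repeats_profile = "unit")
  model <- build_model(cfg)
  bot3_nodes <- which(vapply(model$nodes, function(nd) {
    !is.null(nd$module) && inherits(nd$module, "uw_bot3")
  }, logical(1)))
  expect_length(bot3_nodes, 1)
  expect_equal(model$nodes[[bot3_nodes]]$name, "fuse_bu_p4")
  expect_equal(unname(model$heads["m"]), bot3_nodes)
  # removing it restores the classic neck graph node-for-node
  cfg2 <- model_config(num_classes = 5, scale = "n", input_size = 416,
                       repeats_profile = "unit", use_bot3 = FALSE)
  model2 <- build_model(cfg2)
  expect_equal(vapply(model2$nodes, `[[`, character(1), "name"),
               vapply(model$nodes, `[[`, character(1), "name"))
  expect_true(inherits(model2$nodes[[model2$heads["m"]]]$module,
                       "uw_c3_layer"))
})

test_that("head emits 3*(5+nc) channels at the neck's spatial sizes", {
  for (nc in c(5L, 80L)) {
    cfg <- model_config(num_classes = nc, input_size = 416, scale = "n",
                        repeats_profile = "unit")
    model <- build_model(cfg)
    prof <- uwdet:::graph_profile(model, 416)
    det_row <- prof[prof$name == "detect", ]
    shapes <- strsplit(det_row$out, " \\| ")[[1]]
    expect_equal(shapes, c(paste0("52x52x", 3 * (5 + nc)),
                           paste0("26x26x", 3 * (5 + nc)),
                           paste0("13x13x", 3 * (5 + nc))))
  }
})

test_that("parameter counting matches closed forms, small and large", {
  # single conv 3->16 k3 (no bias) + affine BN = 432 + 32
  expect_equal(n_params(conv_bn_act(3, 16, 3)), 432 + 32)
  # whole nano model equals an independent per-block closed-form sum
  cfg <- model_config(num_classes = 5, input_size = 416, scale = "n",
                      repeats_profile = "unit")
  w <- function(c) uwdet:::cfg_width(cfg, c)
  half <- max(w(64) %/% 2, 8)
  d3 <- uwdet:::cfg_depth(cfg, 3)
  no <- 3 * (5 + 5)
  expected <-
    cf_conv_bn(3, half, 3) + cf_conv_bn(half, half, 3) +
    cf_conv_bn(half, w(64), 3) +
    cf_conv_bn(w(64), w(128), 3) + cf_csplayer(w(128), w(128), 1) +
    cf_conv_bn(w(128), w(256), 3) + cf_csplayer(w(256), w(256), 1) +
    cf_conv_bn(w(256), w(512), 3) + cf_csplayer(w(512), w(512), 1) +
    cf_conv_bn(w(512), w(1024), 3) + cf_sppf(w(1024), w(1024)) +
    cf_csplayer(w(1024), w(1024), 1) +
    cf_conv_bn(w(1024), w(512), 1) + cf_c3(2 * w(512), w(512), d3) +
    cf_conv_bn(w(512), w(256), 1) + cf_c3(2 * w(256), w(256), d3) +
    cf_conv_bn(w(256), w(256), 3) + cf_bot3(2 * w(256), w(512)) +
    cf_conv_bn(w(512), w(512), 3) + cf_c3(2 * w(512), w(1024), d3) +
    (w(256) * no + no) + (w(512) * no + no) + (w(1024) * no + no)
  expect_equal(count_parameters(build_model(cfg)), expected)
})

test_that("baseline x-scale model reproduces the reported 86.7M/205.7G", {
  cfg <- model_config(num_classes = 80, input_size = 640, scale = "x",
                      variant = "baseline")
  model <- build_model(cfg)
  expect_lt(abs(count_parameters(model) / 1e6 - 86.7), 0.06)
  expect_lt(abs(count_flops(model, 640) / 1e9 - 205.7), 0.06)
})

test_that("improved x-scale footprint lands on the reported 208.0M/432.8G", {
  cfg <- model_config(num_classes = 80, input_size = 640, scale = "x",
                      variant = "improved")  # footprint repeats profile
  model <- build_model(cfg)
  p <- count_parameters(model) / 1e6
  f <- count_flops(model, 640) / 1e9
  expect_lt(abs(p / 208.0 - 1), 0.01)
  expect_lt(abs(f / 432.8 - 1), 0.01)
  # and it is strictly heavier than the baseline at equal scale
  base <- build_model(model_config(num_classes = 80, input_size = 640,
                                   scale = "x", variant = "baseline"))
  expect_gt(count_parameters(model), count_parameters(base))
})

test_that("FLOP accounting matches the analytic convention", {
  # one k3 conv, Cin = Cout = 1, 8x8 map, stride 1, pad 1 -> 2*9*64 FLOPs
  cv <- uwdet:::mod_conv2d(1, 1, k = 3, stride = 1)
  expect_equal(uwdet:::module_profile(cv, c(8, 8, 1))$flops, 1152)
  # whole-model FLOPs equal the sum of the per-node profile (0.1%)
  cfg <- model_config(num_classes = 5, input_size = 416, scale = "n",
                      repeats_profile = "unit")
  model <- build_model(cfg)
  prof <- uwdet:::graph_profile(model, 416)
  expect_equal(count_flops(model, 416), sum(prof$flops))
  # independent closed-form check of one stage's conv FLOPs
  # stage1_conv: w(64)->w(128) k3 s2 at 208 -> 104: 2*9*16*32*104^2 + bn
  expect_equal(prof$flops[prof$name == "stage1_conv"],
               2 * 9 * 16 * 32 * 104^2 + 2 * 32 * 104^2)
})

test_that("forward is finite on zero input and deterministic in eval mode", {
  cfg <- model_config(num_classes = 3, input_size = 64, scale = "n",
                      repeats_profile = "unit")
  model <- build_model(cfg)
  set.seed(5)
  init_model(model)
  z <- array(0, dim = c(64, 64, 3))
  p1 <- forward_model(model, z)
  expect_true(all(vapply(p1, function(m) all(is.finite(m)), logical(1))))
  x <- rand_fmap(64, 64, 3, seed = 6)
  a <- forward_model(model, x)
  b <- forward_model(model, x)
  expect_identical(a, b)
})

test_that("configuration errors are caught", {
  expect_error(model_config(input_size = 100), "divisible by 32")
  expect_error(model_config(scale = "q"))
  cfg <- model_config(num_classes = 3, input_size = 64, scale = "n",
                      repeats_profile = "unit")
  model <- build_model(cfg)
  expect_error(forward_model(model, array(0, c(64, 64, 3))), "unallocated")
})

test_that("model config round-trips through YAML", {
  cfg <- model_config(num_classes = 7, input_size = 416, scale = "s",
                      variant = "improved", repeats_profile = c(2, 3, 4, 5),
                      mhsa_heads = 2, use_bot3 = FALSE)
  path <- tempfile(fileext = ".yaml")
  write_model_config(cfg, path)
  cfg2 <- read_model_config(path)
  expect_equal(cfg2$num_classes, 7)
  expect_equal(cfg2$repeats, c(2L, 3L, 4L, 5L))
  expect_equal(cfg2$anchors, cfg$anchors)
  expect_false(cfg2$use_bot3)
  expect_equal(cfg2$mhsa_heads, 2)
})
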