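# Shared fixtures, built in code at test time.

rand_fmap <- function(h, w, c, seed = 1, sd = 1) {
  set.seed(seed)
  array(stats::rnorm(h * w * c, sd = sd), dim = c(h, w, c))
}

# initialize a module with batch norm effectively at identity in eval mode
# (running mean 0, var 1, gamma 1, beta 0 are the construction defaults)
init_mod <- function(mod, seed = 1, zero = FALSE) {
  set.seed(seed)
  uw_init_params(mod, zero = zero)
  mod
}

# set every batch-norm gamma inside a module tree to zero
zero_bn_gammas <- function(mod) {
  uwdet:::module_walk(mod, function(m) {
    if (inherits(m, "uw_batchnorm")) m$params$gamma[] <- 0
  })
  mod
}

# count modules of a given class inside a tree
count_modules <- function(mod, cls) {
  n <- 0
  uwdet:::module_walk(mod, function(m) if (inherits(m, cls)) n <<- n + 1)
  n
}

# simple detection/truth data.frames
make_dets <- function(x1, y1, x2, y2, conf, class_id, image = NULL) {
  d <- data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2, conf = conf,
                  class_id = as.integer(class_id))
  if (!is.null(image)) d$image <- image
  d
}

make_truths <- function(x1, y1, x2, y2, class_id, image = NULL) {
  t <- data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                  class_id = as.integer(class_id))
  if (!is.null(image)) t$image <- image
  t
}

# a tiny on-disk YOLO dataset of solid-color images with one centered box
write_tiny_dataset <- function(root, n = 4, split = "train", size = 48) {
  items <- lapply(seq_len(n), function(i) {
    img <- array((i / (n + 1)), dim = c(size, size, 3))
    img[seq(size %/% 4, 3 * size %/% 4), seq(size %/% 4, 3 * size %/% 4), 1] <- 0.9
    labels <- data.frame(class_id = (i - 1L) %% 3L, cx = 0.5, cy = 0.5,
                         w = 0.5, h = 0.5)
    list(image = img, labels = labels)
  })
  write_yolo_dataset(items, root, split,
                     class_names = paste0("class", 0:2))
}

# degraded synthetic image fixture with a blue-green cast and compressed
# contrast (the enhancement module's measurable target)
degraded_fixture <- function(size = 64, seed = 5) {
  set.seed(seed)
  base <- array(stats::runif(size * size * 3, 0.45, 0.55),
                dim = c(size, size, 3))
  base[, , 1] <- base[, , 1] * 0.4        # cast: attenuate red
  base[, , 2] <- base[, , 2] * 1.05
  base[, , 3] <- base[, , 3] * 1.10
  pmin(pmax(base, 0), 1)
}
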