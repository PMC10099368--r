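# Synthetic underwater-like labeled scenes. Five organism classes drawn as
# class-distinct parametric shapes on a textured seafloor, then degraded the
# way shallow-water imagery degrades: blue-green color cast (red attenuated
# most), contrast compression, Gaussian blur, additive sensor noise.
# Degradations are purely photometric, so emitted boxes are exact.

#' Specification for a synthetic underwater scene
#'
#' @param size image side in pixels (default 416, the working input size).
#' @param n_objects integer range (min, max) of organisms per scene.
#' @param n_classes number of organism classes (default 5).
#' @param scale_range object diameter range as a fraction of the image side.
#' @param occlusion_prob probability that a new object may overlap an
#'   existing one (otherwise placement retries for a clear spot).
#' @param cast_strength blue-green cast: the red channel is attenuated by
#'   `1 - cast_strength`.
#' @param contrast_factor fraction of contrast removed: intensities shrink
#'   towards mid-gray by `1 - contrast_factor`.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param noise_sigma additive Gaussian noise sigma (intensity units).
#' @param seed base RNG seed.
#' @return an object of class `uw_scene_spec`.
#' @export
scene_spec <- function(size = 416, n_objects = c(3, 8), n_classes = 5,
                       scale_range = c(0.10, 0.28), occlusion_prob = 0.3,
                       cast_strength = 0.4, contrast_factor = 0.5,
                       blur_sigma = 1.2, noise_sigma = 0.02, seed = 0) {
  stopifnot(n_objects[1] <= n_objects[2], scale_range[1] <= scale_range[2],
            occlusion_prob >= 0, occlusion_prob <= 1,
            cast_strength >= 0, cast_strength < 1,
            contrast_factor >= 0, contrast_factor < 1)
  structure(list(size = size, n_objects = n_objects, n_classes = n_classes,
                 scale_range = scale_range, occlusion_prob = occlusion_prob,
                 cast_strength = cast_strength,
                 contrast_factor = contrast_factor, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, seed = seed),
            class = "uw_scene_spec")
}

# fixed shape-and-color palette; one entry per class so a small detector can
# genuinely learn class separation
class_palette <- function(i) {
  pal <- list(
    list(shape = "ellipse", col = c(0.85, 0.45, 0.40)),   # holothurian-like
    list(shape = "star", col = c(0.95, 0.75, 0.30)),      # starfish-like
    list(shape = "spiky", col = c(0.25, 0.15, 0.30)),     # urchin-like
    list(shape = "fan", col = c(0.90, 0.85, 0.75)),       # scallop-like
    list(shape = "blob", col = c(0.25, 0.55, 0.30))       # waterweed-like
  )
  pal[[(i - 1) %% length(pal) + 1]]
}

# boolean mask of a parametric shape centered at (cy, cx) with radius r
shape_mask <- function(shape, size, cy, cx, r, phase, aspect) {
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- (yy - cy) / aspect
  dx <- xx - cx
  rho <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  switch(shape,
         ellipse = rho <= r,
         star = rho <= r * (0.55 + 0.45 * cos(5 * th + phase)),
         spiky = rho <= r * (0.78 + 0.22 * cos(14 * th + phase)),
         fan = rho <= r * (0.65 + 0.35 * abs(cos(4 * th + phase))),
         blob = rho <= r * (0.60 + 0.40 * cos(3 * th + phase)))
}

smooth_noise <- function(size, sigma) {
  n <- matrix(stats::runif(size * size), size, size)
  b <- EBImage::gblur(EBImage::Image(n), sigma = sigma)
  b <- EBImage::imageData(b)
  rng <- range(b)
  (b - rng[1]) / max(rng[2] - rng[1], 1e-9)
}

#' Generate one synthetic underwater scene
#'
#' Draws class-distinct shapes on a seafloor-textured background, records
#' their exact bounding boxes, then applies the photometric degradation
#' chain cast -> contrast compression -> blur -> noise.
#'
#' @param spec a [scene_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list with `image` (degraded `size x size x 3` array), `labels`
#'   (normalized center-format data.frame) and `clean` (the pre-degradation
#'   image, useful as an enhancement reference).
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "uw_scene_spec"))
  with_seed(seed, {
    size <- spec$size
    # seafloor: greenish-blue base modulated by smooth texture
    tex <- smooth_noise(size, sigma = max(size / 24, 2))
    img <- array(0, dim = c(size, size, 3))
    img[, , 1] <- 0.35 + 0.15 * tex
    img[, , 2] <- 0.45 + 0.20 * tex
    img[, , 3] <- 0.45 + 0.18 * tex
    n_obj <- sample(seq(spec$n_objects[1], spec$n_objects[2]), 1)
    boxes <- NULL
    labels <- empty_labels()
    for (k in seq_len(n_obj)) {
      cls <- sample.int(spec$n_classes, 1)
      pal <- class_palette(cls)
      placed <- FALSE
      for (try in 1:50) {
        r <- stats::runif(1, spec$scale_range[1], spec$scale_range[2]) *
          size / 2
        cy <- stats::runif(1, r + 1, size - r)
        cx <- stats::runif(1, r + 1, size - r)
        cand <- c(cx - r, cy - r, cx + r, cy + r)
        allow_overlap <- stats::runif(1) < spec$occlusion_prob
        if (!is.null(boxes) && !allow_overlap) {
          ious <- apply(boxes, 1, function(b) iou(cand, b))
          if (any(ious > 0.25)) next
        }
        mask <- shape_mask(pal$shape, size, cy, cx, r,
                           phase = stats::runif(1, 0, 2 * pi),
                           aspect = stats::runif(1, 0.7, 1.3))
        if (!any(mask)) next
        col <- pmin(pmax(pal$col + stats::rnorm(3, sd = 0.04), 0), 1)
        shade <- 0.85 + 0.3 * tex  # reuse texture as cheap shading
        for (c in 1:3) {
          ch <- img[, , c]
          ch[mask] <- (col[c] * shade)[mask]
          img[, , c] <- ch
        }
        rr <- range(which(rowSums(mask) > 0))
        cc <- range(which(colSums(mask) > 0))
        bb <- c(cc[1] - 1, rr[1] - 1, cc[2], rr[2])  # x1 y1 x2 y2, half-open
        boxes <- rbind(boxes, bb)
        labels <- rbind(labels, data.frame(
          class_id = cls - 1L,
          cx = (bb[1] + bb[3]) / 2 / size, cy = (bb[2] + bb[4]) / 2 / size,
          w = (bb[3] - bb[1]) / size, h = (bb[4] - bb[2]) / size))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place object ", k, " after bounded retries",
             call. = FALSE)
      }
    }
    clean <- img
    # degradation chain: cast -> contrast compression -> blur -> noise
    img[, , 1] <- img[, , 1] * (1 - spec$cast_strength)
    img <- 0.5 + (img - 0.5) * (1 - spec$contrast_factor)
    if (spec$blur_sigma > 0) {
      a <- aperm(img, c(2, 1, 3))
      a <- EBImage::imageData(EBImage::gblur(
        EBImage::Image(a, colormode = "Color"), sigma = spec$blur_sigma))
      img <- aperm(a, c(2, 1, 3))
    }
    if (spec$noise_sigma > 0) {
      img <- img + array(stats::rnorm(length(img), sd = spec$noise_sigma),
                         dim = dim(img))
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, labels = labels, clean = clean)
  })
}

#' Generate a YOLO-layout synthetic dataset on disk
#'
#' Writes `n_train` + `n_val` scenes with disjoint per-split seed streams.
#'
#' @param spec a [scene_spec()].
#' @param n_train,n_val scene counts per split.
#' @param out_dir dataset root to create.
#' @return list of manifests `train` and `val`.
#' @export
generate_dataset <- function(spec, n_train, n_val, out_dir) {
  stopifnot(n_train >= 1, n_val >= 1)
  class_names <- paste0("class", seq_len(spec$n_classes) - 1)
  mk <- function(n, split, seed_off) {
    items <- lapply(seq_len(n), function(i) {
      sc <- generate_scene(spec, seed = spec$seed + seed_off + i)
      list(image = sc$image, labels = sc$labels)
    })
    write_yolo_dataset(items, out_dir, split, class_names,
                       stem_fmt = paste0(split, "_%04d"))
  }
  list(train = mk(n_train, "train", 0L),
       val = mk(n_val, "val", 100000L))
}
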