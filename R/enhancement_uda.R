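# Two-step underwater image enhancement in the minimal-color-loss /
# locally-adaptive-contrast family, plus the union dataset augmentation
# (UDA) that doubles a training split with enhanced copies. Enhancement is
# per-pixel/per-neighborhood photometric: geometry and hence every bounding
# box is untouched, so label files are duplicated byte-identical. It is a
# training-time augmentation only and is never applied to evaluation images.

#' Enhancement parameters
#'
#' @param strength color-correction strength in `[0, 1]`: how far attenuated
#'   channels are pulled towards the locally dominant channel (default 0.8).
#' @param radius local window radius in pixels for the channel statistics
#'   and the contrast statistics (default 10).
#' @param gain_bounds ordered `(min, max)` clamp for the local contrast gain
#'   (default `c(1, 3)`: contrast is never reduced, at most tripled).
#' @param target_std the local standard deviation the contrast step aims
#'   for, in intensity units (default 0.1).
#' @return an object of class `uw_enhancement_params`.
#' @export
enhancement_params <- function(strength = 0.8, radius = 10,
                               gain_bounds = c(1, 3), target_std = 0.1) {
  stopifnot(strength >= 0, radius >= 1, gain_bounds[1] <= gain_bounds[2],
            target_std > 0)
  structure(list(strength = min(strength, 1), radius = as.integer(radius),
                 gain_bounds = gain_bounds, target_std = target_std),
            class = "uw_enhancement_params")
}

check_rgb <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  }
  invisible(img)
}

# local box mean with replicated borders
box_mean <- function(x, radius) {
  k <- 2 * radius + 1
  f <- matrix(1 / (k * k), k, k)
  EBImage::imageData(EBImage::filter2(EBImage::Image(x), f,
                                      boundary = "replicate"))
}

#' Channel-mean imbalance of an RGB image
#'
#' `max_c |mean_c - gray_mean|`: zero for a perfectly balanced image, large
#' under a color cast. This is the metric the color-correction step reduces.
#'
#' @param img `H x W x 3` array.
#' @return nonnegative scalar.
#' @export
channel_imbalance <- function(img) {
  check_rgb(img)
  m <- apply(img, 3, mean)
  max(abs(m - mean(m)))
}

#' Mean local standard deviation of an RGB image
#'
#' Average over pixels of the windowed luminance standard deviation; the
#' quantity the contrast step raises on low-contrast input.
#'
#' @param img `H x W x 3` array.
#' @param radius window radius in pixels.
#' @return nonnegative scalar.
#' @export
mean_local_std <- function(img, radius = 10) {
  check_rgb(img)
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  mu <- box_mean(lum, radius)
  v <- pmax(box_mean(lum^2, radius) - mu^2, 0)
  mean(sqrt(v))
}

#' Local adaptive color correction
#'
#' Step 1 of the enhancement: each attenuated channel is compensated towards
#' the locally dominant channel. With local window means `M_c`, the channel
#' with the highest global mean is the reference; every other channel moves
#' by `strength * (M_ref - M_c)` per pixel; the reference channel itself is
#' left untouched (minimal shift of the dominant channel). Output is clipped
#' to `[0, 1]`; the channel-mean imbalance does not increase.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param p an [enhancement_params()].
#' @return corrected image.
#' @export
mlle_color_correct <- function(img, p = enhancement_params()) {
  check_rgb(img)
  d <- dim(img)
  if (2 * p$radius + 1 > min(d[1], d[2])) {
    stop("window larger than image", call. = FALSE)
  }
  gm <- apply(img, 3, mean)
  dom <- which.max(gm)
  M <- lapply(1:3, function(c) box_mean(img[, , c], p$radius))
  out <- img
  for (c in setdiff(1:3, dom)) {
    out[, , c] <- img[, , c] + p$strength * (M[[dom]] - M[[c]])
  }
  pmin(pmax(out, 0), 1)
}

#' Locally adaptive contrast improvement
#'
#' Step 2 of the enhancement: a local mean/variance remapping
#' `out = mu + g * (in - mu)` with the adaptive gain
#' `g = clamp(target_std / (sigma_local + eps), gain_min, gain_max)` shared
#' across channels (computed on luminance, so hue is preserved). Flat images
#' are fixed points; on low-contrast input the mean local standard
#' deviation increases.
#'
#' @inheritParams mlle_color_correct
#' @return contrast-enhanced image.
#' @export
mlle_contrast_enhance <- function(img, p = enhancement_params()) {
  check_rgb(img)
  d <- dim(img)
  if (2 * p$radius + 1 > min(d[1], d[2])) {
    stop("window larger than image", call. = FALSE)
  }
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  mu_l <- box_mean(lum, p$radius)
  sd_l <- sqrt(pmax(box_mean(lum^2, p$radius) - mu_l^2, 0))
  g <- pmin(pmax(p$target_std / (sd_l + 1e-6), p$gain_bounds[1]),
            p$gain_bounds[2])
  out <- img
  for (c in 1:3) {
    mu_c <- box_mean(img[, , c], p$radius)
    out[, , c] <- mu_c + g * (img[, , c] - mu_c)
  }
  pmin(pmax(out, 0), 1)
}

#' Full two-step enhancement
#'
#' The composition of [mlle_color_correct()] (step 1) then
#' [mlle_contrast_enhance()] (step 2).
#'
#' @inheritParams mlle_color_correct
#' @return enhanced image.
#' @export
mlle_enhance <- function(img, p = enhancement_params()) {
  mlle_contrast_enhance(mlle_color_correct(img, p), p)
}

#' Union dataset augmentation (UDA)
#'
#' Writes a new YOLO-layout training split that is the union of the original
#' training images and their enhanced copies: `|UDA| = 2 |train|`. Enhanced
#' copies carry byte-identical label files. Validation/test splits are not
#' touched — enhancement is a training-set augmentation only.
#'
#' @param train a `uw_manifest` for the training split.
#' @param p an [enhancement_params()].
#' @param out_dir output dataset root.
#' @param split output split name (default: the input split name).
#' @return the manifest of the doubled split.
#' @export
build_uda_dataset <- function(train, p = enhancement_params(), out_dir,
                              split = train$split) {
  stopifnot(inherits(train, "uw_manifest"))
  img_dir <- file.path(out_dir, "images", split)
  lbl_dir <- file.path(out_dir, "labels", split)
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lbl_dir, recursive = TRUE, showWarnings = FALSE)
  for (it in train$items) {
    stem <- tools::file_path_sans_ext(basename(it$image))
    file.copy(it$image, file.path(img_dir, basename(it$image)),
              overwrite = TRUE)
    file.copy(it$label, file.path(lbl_dir, paste0(stem, ".txt")),
              overwrite = TRUE)
    enhanced <- mlle_enhance(load_image(it$image), p)
    save_image(enhanced, file.path(img_dir, paste0(stem, "_mlle.png")))
    file.copy(it$label, file.path(lbl_dir, paste0(stem, "_mlle.txt")),
              overwrite = TRUE)
  }
  if (!is.null(train$class_names)) {
    yaml::write_yaml(list(names = as.list(train$class_names)),
                     file.path(out_dir, "dataset.yaml"))
  }
  read_yolo_dataset(out_dir, split)
}
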