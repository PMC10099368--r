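# YOLO-layout dataset reading/writing, letterbox resizing and mosaic
# augmentation. Label files hold one `class_id cx cy w h` line per box,
# center-format, normalized to [0, 1]. Internally boxes are pixel xyxy,
# 0-based half-open. Padding gray is 114/255.

PAD_GRAY <- 114 / 255

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

empty_labels <- function() {
  data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

#' Read one YOLO label file
#'
#' @param path label file; may be empty (background image).
#' @return data.frame with columns `class_id, cx, cy, w, h`.
#' @export
read_label_file <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_labels())
  recs <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 5 || anyNA(vals)) {
      stop("malformed label line at ", path, ":", i, " ('", lines[i], "')",
           call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, recs)
  df <- data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
                   w = m[, 4], h = m[, 5])
  bad <- which(df$w <= 0 | df$h <= 0 | df$cx < 0 | df$cx > 1 | df$cy < 0 |
                 df$cy > 1)
  if (length(bad) > 0) {
    stop("invalid box geometry at ", path, ":", bad[1], call. = FALSE)
  }
  df
}

#' Write one YOLO label file
#'
#' @param labels data.frame `class_id, cx, cy, w, h`.
#' @param path output path.
#' @export
write_label_file <- function(labels, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", labels$class_id, labels$cx,
                   labels$cy, labels$w, labels$h)
  writeLines(lines, path)
  invisible(path)
}

#' Read a YOLO-layout dataset split
#'
#' Expects `root/images/<split>` and `root/labels/<split>` with one `.txt`
#' label file per image (empty files mark background images). Class names
#' come from `root/dataset.yaml` (`names:` entry) when present.
#'
#' @param root dataset root directory.
#' @param split split name (e.g. `"train"`).
#' @param num_classes optional; class ids are validated against it (or
#'   against the length of the class-name list).
#' @return a manifest: list with `split`, `items` (image/label path pairs),
#'   `class_names`, `root`; class `uw_manifest`.
#' @export
read_yolo_dataset <- function(root, split, num_classes = NULL) {
  img_dir <- file.path(root, "images", split)
  lbl_dir <- file.path(root, "labels", split)
  if (!dir.exists(img_dir)) {
    stop("missing images directory: ", img_dir, call. = FALSE)
  }
  if (!dir.exists(lbl_dir)) {
    stop("missing labels directory: ", lbl_dir, call. = FALSE)
  }
  class_names <- NULL
  dy <- file.path(root, "dataset.yaml")
  if (file.exists(dy)) {
    y <- yaml::read_yaml(dy)
    class_names <- unlist(y$names)
  }
  if (is.null(num_classes) && !is.null(class_names)) {
    num_classes <- length(class_names)
  }
  imgs <- sort(list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$",
                          ignore.case = TRUE, full.names = TRUE))
  if (length(imgs) == 0) stop("no images in ", img_dir, call. = FALSE)
  lbls <- file.path(lbl_dir,
                    paste0(tools::file_path_sans_ext(basename(imgs)), ".txt"))
  missing <- !file.exists(lbls)
  if (any(missing)) {
    stop("missing label files for: ",
         paste(basename(imgs[missing]), collapse = ", "), call. = FALSE)
  }
  items <- Map(function(i, l) list(image = i, label = l), imgs, lbls)
  names(items) <- basename(imgs)
  for (it in items) {
    recs <- read_label_file(it$label)
    if (!is.null(num_classes) && nrow(recs) > 0 &&
        any(recs$class_id < 0 | recs$class_id >= num_classes)) {
      stop("class id out of range [0, ", num_classes, ") in ", it$label,
           call. = FALSE)
    }
  }
  structure(list(split = split, items = items, class_names = class_names,
                 root = root),
            class = "uw_manifest")
}

#' @export
print.uw_manifest <- function(x, ...) {
  cat(sprintf("<uw_manifest> split '%s': %d images, %s classes\n", x$split,
              length(x$items),
              if (is.null(x$class_names)) "?" else length(x$class_names)))
  invisible(x)
}

#' Read an RGB image as an H x W x 3 array in [0, 1]
#'
#' @param path PNG/JPEG file.
#' @return numeric array `H x W x 3`.
#' @export
load_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  aperm(a, c(2, 1, 3))  # EBImage stores width-major
}

#' Write an H x W x 3 array in [0, 1] to an image file
#'
#' @param img numeric array `H x W x 3`.
#' @param path output path; format from extension.
#' @export
save_image <- function(img, path) {
  a <- aperm(pmin(pmax(img, 0), 1), c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

# bilinear resize of an H x W x C array
resize_image <- function(img, h, w) {
  a <- aperm(img, c(2, 1, 3))
  r <- EBImage::resize(EBImage::Image(a, colormode = "Color"), w = w, h = h)
  aperm(EBImage::imageData(r), c(2, 1, 3))
}

#' Letterbox an image (aspect-preserving resize with gray padding)
#'
#' Resizes so the longer side fits `size`, pads the rest symmetrically with
#' 114-gray, and remaps normalized labels into the new frame.
#'
#' @param img `H x W x 3` array.
#' @param labels data.frame `class_id, cx, cy, w, h` (may be empty).
#' @param size target square side (divisible by 32).
#' @return list with `image`, `labels`, and `meta` (scale and padding, for
#'   [unletterbox_boxes()]).
#' @export
letterbox <- function(img, labels = empty_labels(), size = 416) {
  stopifnot(size %% 32 == 0)
  d <- dim(img)
  h <- d[1]
  w <- d[2]
  scale <- min(size / h, size / w)
  nh <- round(h * scale)
  nw <- round(w * scale)
  resized <- if (nh == h && nw == w) img else resize_image(img, nh, nw)
  top <- (size - nh) %/% 2
  left <- (size - nw) %/% 2
  canvas <- array(PAD_GRAY, dim = c(size, size, 3))
  canvas[top + seq_len(nh), left + seq_len(nw), ] <- resized
  out <- labels
  if (nrow(labels) > 0) {
    out$cx <- (labels$cx * nw + left) / size
    out$cy <- (labels$cy * nh + top) / size
    out$w <- labels$w * nw / size
    out$h <- labels$h * nh / size
  }
  list(image = canvas, labels = out,
       meta = list(scale = scale, top = top, left = left, nh = nh, nw = nw,
                   orig = c(h, w), size = size))
}

#' Map letterboxed pixel boxes back to original image coordinates
#'
#' @param boxes matrix/data.frame with columns `x1, y1, x2, y2` in
#'   letterboxed pixels.
#' @param meta the `meta` element returned by [letterbox()].
#' @return boxes in original-image pixels, clipped to the image.
#' @export
unletterbox_boxes <- function(boxes, meta) {
  b <- as.data.frame(boxes)
  b$x1 <- pmin(pmax((b$x1 - meta$left) / meta$scale, 0), meta$orig[2])
  b$x2 <- pmin(pmax((b$x2 - meta$left) / meta$scale, 0), meta$orig[2])
  b$y1 <- pmin(pmax((b$y1 - meta$top) / meta$scale, 0), meta$orig[1])
  b$y2 <- pmin(pmax((b$y2 - meta$top) / meta$scale, 0), meta$orig[1])
  b
}

#' Plain (non-aspect-preserving) resize with unchanged normalized labels
#'
#' @inheritParams letterbox
#' @return list with `image` and `labels`.
#' @export
resize_plain <- function(img, labels = empty_labels(), size = 416) {
  list(image = resize_image(img, size, size), labels = labels)
}

# normalized center-format -> pixel xyxy (0-based half-open)
labels_to_xyxy <- function(labels, h, w) {
  data.frame(x1 = (labels$cx - labels$w / 2) * w,
             y1 = (labels$cy - labels$h / 2) * h,
             x2 = (labels$cx + labels$w / 2) * w,
             y2 = (labels$cy + labels$h / 2) * h,
             class_id = labels$class_id)
}

xyxy_to_labels <- function(b, h, w) {
  data.frame(class_id = b$class_id,
             cx = (b$x1 + b$x2) / 2 / w, cy = (b$y1 + b$y2) / 2 / h,
             w = (b$x2 - b$x1) / w, h = (b$y2 - b$y1) / h)
}

#' Mosaic augmentation: stitch four images around a random center
#'
#' Four images drawn from the manifest are scaled (aspect preserved) and
#' anchored at a random center on a `size x size` canvas; boxes are
#' remapped, clipped to the canvas, and dropped when the clipped area falls
#' below 4 px^2 or a side degenerates below 1 px.
#'
#' @param manifest a `uw_manifest` with at least 4 images.
#' @param seed integer seed; the mosaic is a pure function of
#'   (manifest, seed, size).
#' @param size canvas side in pixels.
#' @return list with `image` and pixel-frame `labels`
#'   (`class_id, cx, cy, w, h` normalized to the canvas).
#' @export
mosaic_augment <- function(manifest, seed, size = 416) {
  if (length(manifest$items) < 4) {
    stop("mosaic needs at least 4 images in the manifest", call. = FALSE)
  }
  with_seed(seed, {
    picks <- sample(seq_along(manifest$items), 4)
    xc <- round(stats::runif(1, 0.25, 0.75) * size)
    yc <- round(stats::runif(1, 0.25, 0.75) * size)
    canvas <- array(PAD_GRAY, dim = c(size, size, 3))
    all_boxes <- list()
    for (q in 1:4) {
      it <- manifest$items[[picks[q]]]
      img <- load_image(it$image)
      lb <- read_label_file(it$label)
      d <- dim(img)
      s <- min(size / d[1], size / d[2])
      nh <- max(round(d[1] * s), 1)
      nw <- max(round(d[2] * s), 1)
      img <- resize_image(img, nh, nw)
      # quadrant target rects (x=cols, y=rows), 1-based inclusive
      if (q == 1) {        # top-left: anchor bottom-right at center
        x2 <- xc; y2 <- yc; x1 <- max(1, x2 - nw + 1); y1 <- max(1, y2 - nh + 1)
        sx2 <- nw; sy2 <- nh; sx1 <- nw - (x2 - x1); sy1 <- nh - (y2 - y1)
      } else if (q == 2) { # top-right
        x1 <- xc + 1; y2 <- yc; x2 <- min(size, x1 + nw - 1)
        y1 <- max(1, y2 - nh + 1)
        sx1 <- 1; sy2 <- nh; sx2 <- 1 + (x2 - x1); sy1 <- nh - (y2 - y1)
      } else if (q == 3) { # bottom-left
        x2 <- xc; y1 <- yc + 1; x1 <- max(1, x2 - nw + 1)
        y2 <- min(size, y1 + nh - 1)
        sx2 <- nw; sy1 <- 1; sx1 <- nw - (x2 - x1); sy2 <- 1 + (y2 - y1)
      } else {             # bottom-right
        x1 <- xc + 1; y1 <- yc + 1; x2 <- min(size, x1 + nw - 1)
        y2 <- min(size, y1 + nh - 1)
        sx1 <- 1; sy1 <- 1; sx2 <- 1 + (x2 - x1); sy2 <- 1 + (y2 - y1)
      }
      if (x2 < x1 || y2 < y1) next
      canvas[y1:y2, x1:x2, ] <- img[sy1:sy2, sx1:sx2, , drop = FALSE]
      if (nrow(lb) > 0) {
        bx <- labels_to_xyxy(lb, nh, nw)
        # shift into canvas frame: source pixel (sy1, sx1) lands at (y1, x1)
        bx$x1 <- bx$x1 - (sx1 - 1) + (x1 - 1)
        bx$x2 <- bx$x2 - (sx1 - 1) + (x1 - 1)
        bx$y1 <- bx$y1 - (sy1 - 1) + (y1 - 1)
        bx$y2 <- bx$y2 - (sy1 - 1) + (y1 - 1)
        # clip to the pasted region (visible part only)
        bx$x1 <- pmax(bx$x1, x1 - 1); bx$x2 <- pmin(bx$x2, x2)
        bx$y1 <- pmax(bx$y1, y1 - 1); bx$y2 <- pmin(bx$y2, y2)
        all_boxes[[q]] <- bx
      }
    }
    boxes <- do.call(rbind, all_boxes)
    if (!is.null(boxes) && nrow(boxes) > 0) {
      ww <- boxes$x2 - boxes$x1
      hh <- boxes$y2 - boxes$y1
      keep <- ww >= 1 & hh >= 1 & (ww * hh) >= 4
      boxes <- boxes[keep, , drop = FALSE]
      labels <- xyxy_to_labels(boxes, size, size)
    } else {
      labels <- empty_labels()
    }
    list(image = canvas, labels = labels)
  })
}

#' Write a set of (image, labels) pairs as a YOLO-layout dataset split
#'
#' @param items list of `list(image =, labels =)` pairs.
#' @param root dataset root.
#' @param split split name.
#' @param class_names character vector written to `root/dataset.yaml`.
#' @param stem_fmt sprintf format for file stems.
#' @return the manifest of the written split.
#' @export
write_yolo_dataset <- function(items, root, split, class_names = NULL,
                               stem_fmt = "img_%04d") {
  img_dir <- file.path(root, "images", split)
  lbl_dir <- file.path(root, "labels", split)
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lbl_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(items)) {
    stem <- sprintf(stem_fmt, i)
    save_image(items[[i]]$image, file.path(img_dir, paste0(stem, ".png")))
    write_label_file(items[[i]]$labels, file.path(lbl_dir, paste0(stem, ".txt")))
  }
  if (!is.null(class_names)) {
    dy <- file.path(root, "dataset.yaml")
    y <- if (file.exists(dy)) yaml::read_yaml(dy) else list()
    y$names <- as.list(class_names)
    yaml::write_yaml(y, dy)
  }
  read_yolo_dataset(root, split)
}
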