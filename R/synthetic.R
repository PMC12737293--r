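# Synthetic underwater scenes: green/blue-tinted noisy backgrounds with a
# sediment band, four parametric organism shapes (spiked disc ~ echinus,
# five-armed star ~ starfish, elongated low-contrast blob ~ holothurian,
# fan/half-disc ~ scallop), Gaussian blur and additive noise. Labels are the
# tight bounding boxes of the drawn masks, recorded before blurring, in
# normalized YOLO center/size form. The generator emulates the statistical
# structure that matters to the detector (small targets, low contrast,
# occlusion, color cast, blur), not photometric realism.

#' Specification of a synthetic underwater scene
#'
#' @param image_size square image side in pixels (>= 64).
#' @param counts named integer vector: instances per class, names
#'   "echinus", "starfish", "holothurian", "scallop". Each entry may be a
#'   single count or the upper end of a 0..n range drawn uniformly when
#'   `randomize_counts = TRUE`.
#' @param radius_range object radius range in pixels.
#' @param tint base background color (RGB in \[0,1\]), greenish-blue.
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables).
#' @param noise_sigma additive Gaussian noise sd on \[0,1\] intensities.
#' @param occlusion_prob probability that a new instance is allowed to overlap
#'   an existing one.
#' @param randomize_counts draw each class count uniformly from 0..counts.
#' @param seed RNG seed for [generate_scene()].
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_size = 256L,
                       counts = c(echinus = 3L, starfish = 1L,
                                  holothurian = 1L, scallop = 1L),
                       radius_range = c(9, 22),
                       tint = c(0.10, 0.35, 0.30),
                       blur_sigma = 1.0,
                       noise_sigma = 0.03,
                       occlusion_prob = 0.2,
                       randomize_counts = FALSE,
                       seed = 0L) {
  stopifnot(image_size >= 64L, all(counts >= 0L),
            occlusion_prob >= 0, occlusion_prob <= 1,
            length(tint) == 3L, all(tint >= 0), all(tint <= 1))
  structure(list(image_size = as.integer(image_size), counts = counts,
                 radius_range = radius_range, tint = tint,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 occlusion_prob = occlusion_prob,
                 randomize_counts = isTRUE(randomize_counts),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Class roster of the synthetic scenes
#' @return character vector of the four class names (ids 0..3).
#' @export
seadetect_classes <- function() c("echinus", "starfish", "holothurian", "scallop")

# mask of one parametric shape on the full pixel grid; returns logical (H, W)
shape_mask <- function(class_name, H, W, cx, cy, r0, phi, elong) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  dx <- xs - cx
  dy <- ys - cy
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  switch(class_name,
    echinus = rr <= r0 * (0.55 + 0.45 * cos(9 * (th - phi))^2),
    starfish = rr <= r0 * (0.40 + 0.60 * ((cos(5 * (th - phi)) + 1) / 2)^1.4),
    holothurian = {
      dxp <- cos(phi) * dx + sin(phi) * dy
      dyp <- -sin(phi) * dx + cos(phi) * dy
      (dxp / (r0 * elong))^2 + (dyp / (r0 * 0.55))^2 <=
        1 + 0.10 * sin(6 * th)
    },
    scallop = {
      dxp <- cos(phi) * dx + sin(phi) * dy
      dyp <- -sin(phi) * dx + cos(phi) * dy
      rr <= r0 & dyp >= -0.25 * r0
    },
    stop("unknown class: ", class_name))
}

shape_color <- function(class_name, tint) {
  switch(class_name,
    echinus = c(0.09, 0.06, 0.12),
    starfish = c(0.80, 0.45, 0.20),
    # holothurian stays close to the sediment color: low contrast by design
    holothurian = pmin(1, tint * 0.6 + c(0.28, 0.24, 0.12)),
    scallop = c(0.72, 0.68, 0.58))
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  g <- stats::dnorm(seq_len(k) - (k + 1) / 2, sd = sigma)
  g <- g / sum(g)
  ker <- outer(g, g)
  H <- dim(img)[1]; W <- dim(img)[2]
  x <- aperm(img, c(3, 1, 2))
  dim(x) <- c(1, 3, H, W)
  w <- array(0, c(3, 1, k, k))
  for (ch in 1:3) w[ch, 1, , ] <- ker
  p <- k %/% 2L
  y <- hval(ag_conv2d(NULL, list(id = NA_integer_, value = x),
                      list(id = NA_integer_, value = w), NULL,
                      stride = 1L, pad = rep(p, 4L), groups = 3L))
  dim(y) <- c(3, H, W)
  aperm(y, c(2, 3, 1))
}

#' Generate one labeled synthetic underwater scene
#'
#' Deterministic given `spec$seed`. Instance placement rejects bounding-box
#' overlap unless an occlusion draw allows it; if a non-overlapping position
#' cannot be found the instance is dropped with a warning.
#'
#' @param spec a [scene_spec()].
#' @return a `labeled_scene`: list with `image` (H, W, 3 array in \[0,1\]),
#'   `labels` (data.frame class_id, cx, cy, w, h, normalized to \[0,1\]) and
#'   `masks` (list of logical matrices, one per label).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    H <- spec$image_size; W <- spec$image_size
    # background: vertical green-blue gradient + soft low-frequency blobs
    depth <- matrix(rep(seq_len(H) / H, W), H, W)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- spec$tint[ch] * (1.15 - 0.4 * depth)
    for (bl in 1:3) {
      bx <- stats::runif(1, 1, W); by <- stats::runif(1, 1, H)
      br <- stats::runif(1, W / 6, W / 2)
      amp <- stats::runif(1, -0.04, 0.06)
      xs <- matrix(rep(seq_len(W), each = H), H, W)
      ys <- matrix(rep(seq_len(H), W), H, W)
      bump <- amp * exp(-((xs - bx)^2 + (ys - by)^2) / (2 * br^2))
      for (ch in 1:3) img[, , ch] <- img[, , ch] + bump
    }
    # sediment band along the bottom
    band_top <- as.integer(H * 0.82)
    sed <- pmin(1, spec$tint * 0.6 + c(0.30, 0.26, 0.14))
    for (ch in 1:3) img[band_top:H, , ch] <- sed[ch]

    classes <- seadetect_classes()
    labels <- list()
    masks <- list()
    boxes <- matrix(numeric(), 0, 4)
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      n_req <- spec$counts[[cl]]
      if (spec$randomize_counts && n_req > 0) n_req <- sample.int(n_req + 1L, 1L) - 1L
      for (k in seq_len(n_req)) {
        placed <- FALSE
        for (try in seq_len(40L)) {
          r0 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
          phi <- stats::runif(1, 0, 2 * pi)
          elong <- stats::runif(1, 2.2, 3.2)
          margin <- r0 * if (cl == "holothurian") elong else 1
          if (2 * (margin + 1) >= W) next   # too large for this canvas
          cx <- stats::runif(1, margin + 1, W - margin - 1)
          cy_lo <- if (cl %in% c("holothurian", "scallop")) {
            max(margin + 1, H * 0.55)
          } else margin + 1
          cy_hi <- H - margin - 1
          if (cy_lo >= cy_hi) next
          cy <- stats::runif(1, cy_lo, cy_hi)
          m <- shape_mask(cl, H, W, cx, cy, r0, phi, elong)
          if (!any(m)) next
          rows <- range(which(rowSums(m) > 0))
          cols <- range(which(colSums(m) > 0))
          bb <- c(cols[1] - 1, rows[1] - 1, cols[2], rows[2])  # x1 y1 x2 y2
          overlap_ok <- stats::runif(1) < spec$occlusion_prob
          if (!overlap_ok && nrow(boxes) &&
              any(iou_many(bb, boxes) > 0)) next
          col <- shape_color(cl, spec$tint)
          shade <- 1 + 0.15 * sin(4 * atan2(row(m) - cy, col(m) - cx))
          for (ch in 1:3) {
            pl <- img[, , ch]
            pl[m] <- pmin(1, pmax(0, col[ch] * shade[m]))
            img[, , ch] <- pl
          }
          boxes <- rbind(boxes, bb)
          labels[[length(labels) + 1L]] <- data.frame(
            class_id = ci - 1L,
            cx = (bb[1] + bb[3]) / 2 / W, cy = (bb[2] + bb[4]) / 2 / H,
            w = (bb[3] - bb[1]) / W, h = (bb[4] - bb[2]) / H)
          masks[[length(masks) + 1L]] <- m
          placed <- TRUE
          break
        }
        if (!placed) {
          warning(sprintf("could not place %s instance %d without overlap", cl, k))
        }
      }
    }
    img <- gaussian_blur(img, spec$blur_sigma)
    if (spec$noise_sigma > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
    }
    img <- pmin(pmax(img, 0), 1)
    lab <- if (length(labels)) do.call(rbind, labels) else
      data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                 w = numeric(), h = numeric())
    structure(list(image = img, labels = lab, masks = masks),
              class = "labeled_scene")
  })
}

# ---- YOLO-format dataset IO -------------------------------------------------

largest_remainder_split <- function(n, ratio) {
  raw <- n * ratio / sum(ratio)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Write labeled scenes as a YOLO-format dataset
#'
#' Layout: `images/{train,val,test}/scene_NNNN.png`,
#' `labels/{train,val,test}/scene_NNNN.txt` (lines `class cx cy w h`,
#' normalized, 6 decimals) plus a `dataset.yaml` manifest.
#'
#' @param scenes list of `labeled_scene` objects.
#' @param dir output directory (created).
#' @param split numeric ratios for train/val/test (default 7:2:1). Scenes are
#'   assigned in order.
#' @return `dir`, invisibly.
#' @export
write_yolo_dataset <- function(scenes, dir, split = c(0.7, 0.2, 0.1)) {
  stopifnot(length(split) == 3L, all(split >= 0))
  splits <- c("train", "val", "test")
  counts <- largest_remainder_split(length(scenes), split)
  assign_split <- rep(splits, counts)
  for (sp in splits) {
    dir.create(file.path(dir, "images", sp), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "labels", sp), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(scenes)) {
    sp <- assign_split[i]
    stem <- sprintf("scene_%04d", i)
    png::writePNG(scenes[[i]]$image,
                  file.path(dir, "images", sp, paste0(stem, ".png")))
    lab <- scenes[[i]]$labels
    lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                     lab$class_id, lab$cx, lab$cy, lab$w, lab$h)
    writeLines(lines, file.path(dir, "labels", sp, paste0(stem, ".txt")))
  }
  yaml::write_yaml(list(path = normalizePath(dir),
                        names = as.list(seadetect_classes()),
                        nc = 4L,
                        train = "images/train", val = "images/val",
                        test = "images/test"),
                   file.path(dir, "dataset.yaml"))
  invisible(dir)
}

parse_yolo_label_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  }
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 5L || anyNA(vals)) {
      stop(sprintf("malformed label line %d in %s: '%s'", i, path, lines[i]))
    }
    data.frame(class_id = as.integer(vals[1]), cx = vals[2], cy = vals[3],
               w = vals[4], h = vals[5])
  })
  do.call(rbind, rows)
}

#' Read a YOLO-format dataset written by [write_yolo_dataset()]
#'
#' @param dir dataset directory.
#' @param load_images read the PNGs into arrays (TRUE) or keep paths only.
#' @return list with one element per split, each a list of scenes
#'   (`image` or `image_path`, `labels`), plus `names`.
#' @export
read_yolo_dataset <- function(dir, load_images = TRUE) {
  out <- list()
  for (sp in c("train", "val", "test")) {
    idir <- file.path(dir, "images", sp)
    if (!dir.exists(idir)) next
    imgs <- sort(list.files(idir, pattern = "\\.png$", full.names = TRUE))
    out[[sp]] <- lapply(imgs, function(ip) {
      lp <- file.path(dir, "labels", sp,
                      sub("\\.png$", ".txt", basename(ip)))
      if (!file.exists(lp)) stop("missing label file: ", lp)
      sc <- list(labels = parse_yolo_label_file(lp), image_path = ip)
      if (load_images) sc$image <- png::readPNG(ip)
      sc
    })
  }
  manifest <- file.path(dir, "dataset.yaml")
  out$names <- if (file.exists(manifest)) {
    unlist(yaml::read_yaml(manifest)$names)
  } else seadetect_classes()
  out
}

#' Convert normalized YOLO labels to pixel-corner ground-truth boxes
#'
#' @param labels data.frame (class_id, cx, cy, w, h), normalized.
#' @param img_h,img_w image size in pixels.
#' @param image image index stored in the output (default 1).
#' @return data.frame (image, class_id, x1, y1, x2, y2).
#' @export
yolo_to_corners <- function(labels, img_h, img_w, image = 1L) {
  data.frame(image = image, class_id = labels$class_id,
             x1 = (labels$cx - labels$w / 2) * img_w,
             y1 = (labels$cy - labels$h / 2) * img_h,
             x2 = (labels$cx + labels$w / 2) * img_w,
             y2 = (labels$cy + labels$h / 2) * img_h)
}

# ---- mosaic augmentation ----------------------------------------------------

#' Mosaic augmentation: combine four labeled scenes into one composite
#'
#' A 2x2 composite is assembled around a random center; each quadrant is
#' filled with a crop of one source image (top-left quadrant takes the
#' bottom-right corner of its source, and so on), labels are remapped into
#' composite coordinates, clipped to their quadrant, and dropped when the
#' clipped area falls below 1 px^2.
#'
#' @param samples list of exactly 4 `labeled_scene` objects (images at least
#'   `out_size` in each dimension).
#' @param out_size composite side length in pixels.
#' @param seed RNG seed for the center draw.
#' @param center optional c(x, y) center override in pixels.
#' @return a `labeled_scene` (no masks).
#' @export
mosaic_augment <- function(samples, out_size, seed = 0L, center = NULL) {
  if (length(samples) != 4L) stop("mosaic_augment needs exactly 4 samples")
  with_seed(seed, {
    if (is.null(center)) {
      center <- round(stats::runif(2, 0.35, 0.65) * out_size)
    }
    mx <- as.integer(center[1]); my <- as.integer(center[2])
    mx <- min(max(mx, 1L), out_size - 1L)
    my <- min(max(my, 1L), out_size - 1L)
    comp <- array(0, c(out_size, out_size, 3))
    quads <- list(  # x1, y1, x2, y2 of each quadrant in the composite
      c(1L, 1L, mx, my),
      c(mx + 1L, 1L, out_size, my),
      c(1L, my + 1L, mx, out_size),
      c(mx + 1L, my + 1L, out_size, out_size))
    anchors <- c("br", "bl", "tr", "tl")  # source corner used per quadrant
    labels <- list()
    for (qi in 1:4) {
      sc <- samples[[qi]]
      sh <- dim(sc$image)[1]; sw <- dim(sc$image)[2]
      q <- quads[[qi]]
      qw <- q[3] - q[1] + 1L
      qh <- q[4] - q[2] + 1L
      if (sh < qh || sw < qw) stop("mosaic source smaller than its quadrant")
      sx1 <- switch(anchors[qi], br = , tr = sw - qw + 1L, bl = , tl = 1L)
      sy1 <- switch(anchors[qi], br = , bl = sh - qh + 1L, tr = , tl = 1L)
      comp[q[2]:q[4], q[1]:q[3], ] <-
        sc$image[sy1:(sy1 + qh - 1L), sx1:(sx1 + qw - 1L), , drop = FALSE]
      lab <- sc$labels
      if (!nrow(lab)) next
      px <- yolo_to_corners(lab, sh, sw)
      # shift into composite coordinates
      ox <- q[1] - sx1
      oy <- q[2] - sy1
      x1 <- pmax(px$x1 + ox, q[1] - 1)
      y1 <- pmax(px$y1 + oy, q[2] - 1)
      x2 <- pmin(px$x2 + ox, q[3])
      y2 <- pmin(px$y2 + oy, q[4])
      keep <- (x2 - x1) * (y2 - y1) >= 1 & x2 > x1 & y2 > y1
      if (!any(keep)) next
      labels[[length(labels) + 1L]] <- data.frame(
        class_id = lab$class_id[keep],
        cx = (x1[keep] + x2[keep]) / 2 / out_size,
        cy = (y1[keep] + y2[keep]) / 2 / out_size,
        w = (x2[keep] - x1[keep]) / out_size,
        h = (y2[keep] - y1[keep]) / out_size)
    }
    lab <- if (length(labels)) do.call(rbind, labels) else
      data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
                 w = numeric(), h = numeric())
    structure(list(image = comp, labels = lab), class = "labeled_scene")
  })
}
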