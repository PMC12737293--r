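# Detector assembly: a small-width CSP backbone (Conv/C3/SPPF), FPN-PAN neck
# and a three-scale anchor head, with two optional edits: one SCSA block
# inserted directly after SPPF, and selected C3 blocks swapped for
# C3k2-PSConv. Parameter reports cover every variant.

default_anchors <- function() {
  a <- array(0, c(3, 3, 2))
  a[1, , ] <- matrix(c(10, 13, 16, 30, 33, 23), 3, 2, byrow = TRUE)
  a[2, , ] <- matrix(c(30, 61, 62, 45, 59, 119), 3, 2, byrow = TRUE)
  a[3, , ] <- matrix(c(116, 90, 156, 198, 373, 326), 3, 2, byrow = TRUE)
  a
}

make_divisible <- function(x, divisor = 8L) as.integer(ceiling(x / divisor) * divisor)

#' Model configuration
#'
#' @param num_classes number of object classes (default 4: echinus, starfish,
#'   holothurian, scallop).
#' @param depth_multiple scales the repeat counts of C3 stages (0.33 for the
#'   small variant).
#' @param width_multiple scales channel widths, rounded up to multiples of 8
#'   (0.50 for the small variant).
#' @param input_size training/inference resolution (square), must be divisible
#'   by 32.
#' @param anchors 3x3x2 array of anchor (w, h) pairs in input pixels, one row
#'   of three anchors per output stride (8, 16, 32).
#' @param use_scsa insert one SCSA attention block after SPPF.
#' @param use_c3k2_psconv swap the C3 blocks named in `psconv_positions` for
#'   C3k2-PSConv.
#' @param psconv_positions character vector of replaceable C3 node names; the
#'   default list (second backbone C3 stage plus the neck P3 and P5 blocks) is
#'   the documented configuration that reconciles the published parameter
#'   budget. Valid names: "c3b", "c3c", "c3a", "c3d", "neck_c3_p4a",
#'   "neck_c3_p3", "neck_c3_p4", "neck_c3_p5".
#' @param seed RNG seed used for weight initialization.
#' @return a `seadetect_config` list.
#' @export
model_config <- function(num_classes = 4L, depth_multiple = 0.33,
                         width_multiple = 0.50, input_size = 640L,
                         anchors = default_anchors(), use_scsa = FALSE,
                         use_c3k2_psconv = FALSE,
                         psconv_positions = c("c3b", "neck_c3_p3", "neck_c3_p5"),
                         seed = 0L) {
  stopifnot(num_classes >= 1L, depth_multiple > 0, depth_multiple <= 1,
            width_multiple > 0, width_multiple <= 1,
            input_size %% 32L == 0L, all(anchors > 0))
  structure(list(num_classes = as.integer(num_classes),
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 input_size = as.integer(input_size),
                 anchors = anchors,
                 use_scsa = isTRUE(use_scsa),
                 use_c3k2_psconv = isTRUE(use_c3k2_psconv),
                 psconv_positions = psconv_positions,
                 seed = as.integer(seed)),
            class = "seadetect_config")
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Build a detector variant as a layer graph
#'
#' Assembles the backbone, FPN-PAN neck and detection head according to the
#' configuration's variant flags. The graph is a DAG of named nodes; each node
#' holds a module and the names of its input nodes.
#'
#' @param cfg a [model_config()].
#' @return a `seadetect_model` environment with `$nodes`, `$cfg`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "seadetect_config"))
  wm <- cfg$width_multiple
  dm <- cfg$depth_multiple
  cw <- function(x) make_divisible(x * wm, 8L)
  dn <- function(n) max(1L, round(n * dm))
  c64 <- cw(64); c128 <- cw(128); c256 <- cw(256); c512 <- cw(512); c1024 <- cw(1024)

  c3_or_ps <- function(name, c1, c2, n, shortcut = TRUE) {
    if (cfg$use_c3k2_psconv && name %in% cfg$psconv_positions) {
      new_c3k2_psconv(c1, c2)
    } else {
      new_c3(c1, c2, n, shortcut)
    }
  }

  nodes <- list()
  add <- function(name, from, module) {
    nodes[[length(nodes) + 1L]] <<- list(name = name, from = from, module = module)
  }

  with_seed(cfg$seed, {
    # backbone
    add("stem", "input", new_cbs(3L, c64, k = 6L, s = 2L, p = 2L))
    add("conv1", "stem", new_cbs(c64, c128, 3L, 2L))
    add("c3a", "conv1", c3_or_ps("c3a", c128, c128, dn(3L)))
    add("conv2", "c3a", new_cbs(c128, c256, 3L, 2L))
    add("c3b", "conv2", c3_or_ps("c3b", c256, c256, dn(6L)))          # P3 feature
    add("conv3", "c3b", new_cbs(c256, c512, 3L, 2L))
    add("c3c", "conv3", c3_or_ps("c3c", c512, c512, dn(9L)))          # P4 feature
    add("conv4", "c3c", new_cbs(c512, c1024, 3L, 2L))
    add("c3d", "conv4", c3_or_ps("c3d", c1024, c1024, dn(3L)))
    add("sppf", "c3d", new_sppf(c1024, c1024))
    top <- "sppf"
    if (cfg$use_scsa) {
      add("scsa", "sppf", new_scsa(c1024))
      top <- "scsa"
    }
    # neck: top-down then bottom-up
    add("n_conv1", top, new_cbs(c1024, c512, 1L))
    add("n_up1", "n_conv1", new_upsample())
    add("n_cat1", c("n_up1", "c3c"), new_concat())
    add("neck_c3_p4a", "n_cat1", c3_or_ps("neck_c3_p4a", c1024, c512, dn(3L), FALSE))
    add("n_conv2", "neck_c3_p4a", new_cbs(c512, c256, 1L))
    add("n_up2", "n_conv2", new_upsample())
    add("n_cat2", c("n_up2", "c3b"), new_concat())
    add("neck_c3_p3", "n_cat2", c3_or_ps("neck_c3_p3", c512, c256, dn(3L), FALSE))
    add("n_down1", "neck_c3_p3", new_cbs(c256, c256, 3L, 2L))
    add("n_cat3", c("n_down1", "n_conv2"), new_concat())
    add("neck_c3_p4", "n_cat3", c3_or_ps("neck_c3_p4", c512, c512, dn(3L), FALSE))
    add("n_down2", "neck_c3_p4", new_cbs(c512, c512, 3L, 2L))
    add("n_cat4", c("n_down2", "n_conv1"), new_concat())
    add("neck_c3_p5", "n_cat4", c3_or_ps("neck_c3_p5", c1024, c1024, dn(3L), FALSE))
    add("detect", c("neck_c3_p3", "neck_c3_p4", "neck_c3_p5"),
        new_detect(cfg$num_classes, c(c256, c512, c1024), cfg$anchors))
  })

  m <- new.env(parent = emptyenv())
  m$nodes <- nodes
  m$cfg <- cfg
  class(m) <- "seadetect_model"
  m
}

model_node <- function(model, name) {
  for (nd in model$nodes) if (nd$name == name) return(nd)
  NULL
}

#' Forward pass of a detector
#'
#' @param model a `seadetect_model` from [build_model()].
#' @param images numeric array (B, 3, H, W) with H and W divisible by 32.
#' @param tp optional autodiff tape; NULL for inference.
#' @param training logical, batch-norm mode.
#' @return list of three raw prediction handles, each of value shape
#'   (B, 3, grid_h, grid_w, 5 + num_classes), strides 8/16/32.
#' @export
forward_detector <- function(model, images, tp = NULL, training = FALSE) {
  d <- dim(images)
  if (is.list(images)) {               # already a handle
    d <- dim(hval(images))
  }
  if (length(d) != 4L || d[2] != 3L) {
    stop("images must be a (B, 3, H, W) array")
  }
  if (d[3] %% 32L != 0L || d[4] %% 32L != 0L) {
    stop(sprintf("image size %dx%d not divisible by 32", d[3], d[4]))
  }
  x <- if (is.list(images)) images else list(id = NA_integer_, value = images)
  outs <- list(input = x)
  for (nd in model$nodes) {
    inp <- if (length(nd$from) == 1L) outs[[nd$from]] else lapply(nd$from, function(f) outs[[f]])
    outs[[nd$name]] <- sd_forward(nd$module, tp, inp, training)
  }
  outs$detect
}

#' Count trainable parameters of a model variant
#'
#' Reports a per-layer table and totals, both raw (every trainable array,
#' including the two batch-norm affine vectors per convolution) and BN-fused
#' (each conv+BN pair folded into a conv with bias, the deployment convention
#' in which published model sizes are quoted).
#'
#' @param model a `seadetect_model`.
#' @return a `seadetect_param_report`: list with `layers` (data.frame),
#'   `total`, `total_fused`, `total_m`, `total_fused_m` (millions, half-up
#'   rounded to 2 decimals).
#' @export
count_parameters <- function(model) {
  rows <- lapply(model$nodes, function(nd) {
    cc <- sd_param_census(nd$module)
    data.frame(layer = nd$name, kind = class(nd$module)[1],
               params = cc[1], bn_channels = cc[2],
               params_fused = cc[1] - cc[2], stringsAsFactors = FALSE)
  })
  layers <- do.call(rbind, rows)
  total <- sum(layers$params)
  fused <- sum(layers$params_fused)
  out <- list(layers = layers, total = total, total_fused = fused,
              total_m = round_half_up(total / 1e6, 2L),
              total_fused_m = round_half_up(fused / 1e6, 2L))
  class(out) <- "seadetect_param_report"
  out
}

round_half_up <- function(x, digits = 2L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' @export
print.seadetect_param_report <- function(x, ...) {
  print(x$layers, row.names = FALSE)
  cat(sprintf("total: %d (%.2f M) | BN-fused: %d (%.2f M)\n",
              x$total, x$total_m, x$total_fused, x$total_fused_m))
  invisible(x)
}

#' Build a named variant of the detector
#'
#' @param variant one of "baseline", "scsa", "psconv", "full".
#' @param ... passed to [model_config()].
#' @return a `seadetect_model`.
#' @export
build_variant <- function(variant = c("baseline", "scsa", "psconv", "full"), ...) {
  variant <- match.arg(variant)
  cfg <- model_config(use_scsa = variant %in% c("scsa", "full"),
                      use_c3k2_psconv = variant %in% c("psconv", "full"), ...)
  build_model(cfg)
}

# ---- decoding ---------------------------------------------------------------

#' Decode raw head outputs into pixel-space detections
#'
#' Applies the standard sigmoid-offset anchor decoding: center = (2*sigmoid(t)
#' - 0.5 + cell) * stride, size = (2*sigmoid(t))^2 * anchor; confidence =
#' objectness x best class score. Boxes are clipped to the image.
#'
#' @param raw list of three raw arrays (B, 3, gy, gx, 5+nc) (values, not
#'   handles).
#' @param cfg the [model_config()] used to build the model.
#' @param conf_threshold minimum confidence in \[0, 1\].
#' @param img_size c(H, W) of the decoded image space; defaults to
#'   `cfg$input_size` square.
#' @return data.frame of detection records: image, class_id (0-based),
#'   confidence, x1, y1, x2, y2 (pixels).
#' @export
decode_predictions <- function(raw, cfg, conf_threshold = 0.25, img_size = NULL) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1)
  raw <- lapply(raw, function(r) if (is.list(r)) hval(r) else r)
  if (is.null(img_size)) img_size <- c(cfg$input_size, cfg$input_size)
  strides <- c(8L, 16L, 32L)
  nc <- cfg$num_classes
  out <- list()
  for (s in seq_along(raw)) {
    p <- stats::plogis(raw[[s]])
    d <- dim(p)
    B <- d[1]; gy <- d[3]; gx <- d[4]
    stride <- img_size[1] / gy        # equals strides[s] for square inputs
    for (b in seq_len(B)) {
      for (a in seq_len(3L)) {
        pm <- matrix(p[b, a, , , ], gy * gx, d[5])
        obj <- pm[, 5]
        cls <- pm[, 6:(5 + nc), drop = FALSE]
        best <- max.col(cls, ties.method = "first")
        conf <- obj * cls[cbind(seq_len(nrow(cls)), best)]
        keep <- which(conf >= conf_threshold)
        if (!length(keep)) next
        gyx <- arrayInd(keep, c(gy, gx))
        cy <- (2 * pm[keep, 2] - 0.5 + gyx[, 1] - 1) * stride
        cx <- (2 * pm[keep, 1] - 0.5 + gyx[, 2] - 1) * stride
        w <- (2 * pm[keep, 3])^2 * cfg$anchors[s, a, 1]
        h <- (2 * pm[keep, 4])^2 * cfg$anchors[s, a, 2]
        out[[length(out) + 1L]] <- data.frame(
          image = b, class_id = best[keep] - 1L, confidence = conf[keep],
          x1 = pmin(pmax(cx - w / 2, 0), img_size[2]),
          y1 = pmin(pmax(cy - h / 2, 0), img_size[1]),
          x2 = pmin(pmax(cx + w / 2, 0), img_size[2]),
          y2 = pmin(pmax(cy + h / 2, 0), img_size[1]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(image = integer(), class_id = integer(),
                      confidence = numeric(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  }
  do.call(rbind, out)
}

# ---- checkpointing ----------------------------------------------------------

#' Save model weights and configuration
#' @param model a `seadetect_model`.
#' @param path output file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  buffers <- lapply(model$nodes, function(nd) collect_buffers(nd$module))
  names(buffers) <- vapply(model$nodes, `[[`, "", "name")
  saveRDS(list(cfg = model$cfg, params = sd_model_params(model),
               buffers = buffers), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path RDS file.
#' @return a rebuilt `seadetect_model` with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg)
  for (nd in model$nodes) {
    sd_set_params(nd$module, ck$params[[nd$name]])
    restore_buffers(nd$module, ck$buffers[[nd$name]])
  }
  model
}

sd_model_params <- function(model) {
  out <- lapply(model$nodes, function(nd) sd_get_params(nd$module))
  names(out) <- vapply(model$nodes, `[[`, "", "name")
  out
}

collect_buffers <- function(mod, path = "") {
  out <- list()
  for (nm in names(mod$buffers)) out[[paste0(path, nm)]] <- mod$buffers[[nm]]
  for (cn in names(mod$children)) {
    out <- c(out, collect_buffers(mod$children[[cn]], paste0(path, cn, ".")))
  }
  out
}

restore_buffers <- function(mod, values, path = "") {
  for (nm in names(mod$buffers)) {
    key <- paste0(path, nm)
    if (!is.null(values[[key]])) mod$buffers[[nm]] <- values[[key]]
  }
  for (cn in names(mod$children)) {
    restore_buffers(mod$children[[cn]], values, paste0(path, cn, "."))
  }
  invisible(mod)
}
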