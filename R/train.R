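# Minimal deterministic training loop: Adam (beta1 = 0.937 following the
# published hyperparameter sheet, lr 0.01, weight decay 5e-4), linear warm-up
# over the first epochs then cosine decay. Sized for overfitting small
# synthetic fixtures on a CPU, not for large-scale training.

#' Training hyperparameters
#'
#' @param epochs number of epochs.
#' @param batch_size images per step.
#' @param lr0 initial learning rate (after warm-up).
#' @param beta1,beta2 Adam moment decay rates.
#' @param weight_decay L2 penalty added to gradients.
#' @param warmup_epochs epochs of linear learning-rate warm-up.
#' @param lrf final learning-rate fraction of `lr0` (cosine decay target).
#' @param lambda loss component weights c(box=, obj=, cls=).
#' @param mosaic_prob probability of replacing a batch element by a mosaic
#'   composite of four training scenes.
#' @param seed RNG seed for shuffling and mosaic draws.
#' @return a list of hyperparameters.
#' @export
train_hyper <- function(epochs = 30L, batch_size = 2L, lr0 = 0.01,
                        beta1 = 0.937, beta2 = 0.999, weight_decay = 5e-4,
                        warmup_epochs = 3L, lrf = 0.01,
                        lambda = c(box = 0.05, obj = 1.0, cls = 0.5),
                        mosaic_prob = 0, seed = 0L) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr0 = lr0, beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
       warmup_epochs = as.integer(warmup_epochs), lrf = lrf, lambda = lambda,
       mosaic_prob = mosaic_prob, seed = as.integer(seed))
}

# scene image (H,W,3) -> model input (3,H,W)
scene_to_input <- function(img) {
  x <- aperm(img, c(3, 1, 2))
  dim(x) <- c(1, dim(x))
  x
}

#' Train a detector on labeled scenes
#'
#' @param model a `seadetect_model` (mutated in place).
#' @param scenes list of `labeled_scene` objects (images must match
#'   `model$cfg$input_size`).
#' @param hyper a [train_hyper()] list.
#' @param verbose print per-epoch losses.
#' @return list with `model` and `history` (data.frame epoch, box, obj, cls,
#'   total, lr). Aborts with a diagnostic if the loss becomes non-finite.
#' @export
train_detector <- function(model, scenes, hyper = train_hyper(),
                           verbose = FALSE) {
  stopifnot(length(scenes) >= 1L)
  cfg <- model$cfg
  refs <- unlist(lapply(model$nodes, function(nd) {
    rr <- sd_param_refs(nd$module)
    if (length(rr)) names(rr) <- paste0(nd$name, ".", names(rr))
    rr
  }), recursive = FALSE)
  mstate <- lapply(refs, function(r) r$env$params[[r$key]] * 0)
  vstate <- lapply(refs, function(r) r$env$params[[r$key]] * 0)
  tstep <- 0L
  history <- list()
  sz <- cfg$input_size
  grids <- lapply(c(8L, 16L, 32L), function(s) c(sz %/% s, sz %/% s))
  n <- length(scenes)
  steps_per_epoch <- max(1L, n %/% hyper$batch_size)
  warm_steps <- hyper$warmup_epochs * steps_per_epoch
  total_steps <- hyper$epochs * steps_per_epoch

  with_seed(hyper$seed, {
    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      ep_loss <- c(box = 0, obj = 0, cls = 0, total = 0)
      lr_used <- NA_real_
      for (step in seq_len(steps_per_epoch)) {
        take <- ord[((step - 1L) * hyper$batch_size) %% n +
                      seq_len(hyper$batch_size)]
        take <- ((take - 1L) %% n) + 1L
        batch <- vector("list", length(take))
        for (bi in seq_along(take)) {
          sc <- scenes[[take[bi]]]
          if (hyper$mosaic_prob > 0 && stats::runif(1) < hyper$mosaic_prob) {
            picks <- sample.int(n, 4L, replace = TRUE)
            sc <- mosaic_augment(scenes[picks], sz,
                                 seed = sample.int(1e6, 1L))
          }
          batch[[bi]] <- sc
        }
        x <- array(0, c(length(batch), 3, sz, sz))
        gts <- list()
        for (bi in seq_along(batch)) {
          x[bi, , , ] <- scene_to_input(batch[[bi]]$image)[1, , , ]
          lb <- batch[[bi]]$labels
          if (nrow(lb)) {
            gts[[length(gts) + 1L]] <- data.frame(image = bi,
                                                  class_id = lb$class_id,
                                                  cx = lb$cx, cy = lb$cy,
                                                  w = lb$w, h = lb$h)
          }
        }
        gts <- if (length(gts)) do.call(rbind, gts) else
          data.frame(image = integer(), class_id = integer(), cx = numeric(),
                     cy = numeric(), w = numeric(), h = numeric())
        ta <- assign_targets(gts, cfg$anchors, grids, sz)
        tp <- ag_tape()
        raw <- forward_detector(model, x, tp, training = TRUE)
        ls <- compute_loss(raw, ta, cfg, tp, lambda = hyper$lambda)
        if (!is.finite(ls$total_value)) {
          stop(sprintf("training diverged at epoch %d step %d (loss %g)",
                       epoch, step, ls$total_value))
        }
        grads <- ag_backward(tp, ls$total)
        gmap <- unlist(lapply(model$nodes, function(nd) {
          gg <- sd_param_grads(nd$module, grads)
          if (length(gg)) names(gg) <- paste0(nd$name, ".", names(gg))
          gg
        }), recursive = FALSE)
        tstep <- tstep + 1L
        lr <- if (tstep <= warm_steps && warm_steps > 0) {
          hyper$lr0 * tstep / warm_steps
        } else {
          prog <- (tstep - warm_steps) / max(1L, total_steps - warm_steps)
          hyper$lrf * hyper$lr0 +
            (1 - hyper$lrf) * hyper$lr0 * 0.5 * (1 + cos(pi * min(1, prog)))
        }
        lr_used <- lr
        b1 <- hyper$beta1; b2 <- hyper$beta2
        for (nm in names(refs)) {
          g <- gmap[[nm]]
          r <- refs[[nm]]
          p <- r$env$params[[r$key]]
          if (is.null(g)) g <- p * 0
          g <- g + hyper$weight_decay * p
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g * g
          mhat <- mstate[[nm]] / (1 - b1^tstep)
          vhat <- vstate[[nm]] / (1 - b2^tstep)
          r$env$params[[r$key]] <- p - lr * mhat / (sqrt(vhat) + 1e-8)
        }
        ep_loss <- ep_loss + c(ls$box, ls$obj, ls$cls, ls$total_value)
      }
      ep_loss <- ep_loss / steps_per_epoch
      history[[epoch]] <- data.frame(epoch = epoch, box = ep_loss[1],
                                     obj = ep_loss[2], cls = ep_loss[3],
                                     total = ep_loss[4], lr = lr_used)
      if (verbose) {
        message(sprintf("epoch %3d  box %.4f  obj %.4f  cls %.4f  total %.4f",
                        epoch, ep_loss[1], ep_loss[2], ep_loss[3], ep_loss[4]))
      }
    }
  })
  list(model = model, history = do.call(rbind, history))
}

#' Run inference on scenes and return NMS-filtered detections
#'
#' @param model trained `seadetect_model`.
#' @param scenes list of `labeled_scene`s (or images).
#' @param conf_threshold confidence cutoff.
#' @param iou_threshold NMS threshold.
#' @return detection data.frame (image indexes into `scenes`).
#' @export
detect_scenes <- function(model, scenes, conf_threshold = 0.25,
                          iou_threshold = 0.45) {
  out <- list()
  for (i in seq_along(scenes)) {
    img <- if (is.list(scenes[[i]])) scenes[[i]]$image else scenes[[i]]
    x <- scene_to_input(img)
    raw <- forward_detector(model, x, NULL, training = FALSE)
    dd <- decode_predictions(lapply(raw, hval), model$cfg, conf_threshold,
                             img_size = dim(img)[1:2])
    if (nrow(dd)) {
      dd$image <- i
      out[[length(out) + 1L]] <- nms(dd, iou_threshold)
    }
  }
  if (!length(out)) {
    return(data.frame(image = integer(), class_id = integer(),
                      confidence = numeric(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  }
  do.call(rbind, out)
}
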