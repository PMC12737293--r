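# Composite detection objective: complete-IoU box regression plus binary
# cross-entropy for objectness and classification, over anchor-based target
# assignments (w/h ratio gate 4.0, center cell plus the two nearest neighbor
# cells, the standard assignment for this head).

#' Assign ground-truth boxes to anchors and grid cells
#'
#' For every scale, a ground truth is assigned to each anchor whose w/h ratio
#' to the target is within the gate (max(r, 1/r) < `ratio_gate` on both axes),
#' at its center cell and at the two nearest neighbor cells (one in x, one in
#' y, chosen by which side of the cell center the box center falls on).
#'
#' @param gts data.frame (image, class_id, cx, cy, w, h), normalized, all of
#'   cx, cy, w, h in (0, 1].
#' @param anchors 3x3x2 anchor array in input pixels.
#' @param grids list of three c(gy, gx) grid sizes (strides 8/16/32).
#' @param input_size input resolution in pixels.
#' @param ratio_gate anchor/target size-ratio gate (default 4).
#' @return data.frame (scale, b, a, gi, gj, tx, ty, tw, th, cls) where gi/gj
#'   are 0-based cell x/y indices, tx/ty are offsets from the cell origin in
#'   (-0.5, 1.5) and tw/th are box sizes in grid units.
#' @export
assign_targets <- function(gts, anchors, grids, input_size, ratio_gate = 4.0) {
  if (nrow(gts)) {
    if (any(gts$cx <= 0 | gts$cx > 1 | gts$cy <= 0 | gts$cy > 1 |
            gts$w <= 0 | gts$w > 1 | gts$h <= 0 | gts$h > 1)) {
      stop("assign_targets: ground-truth boxes must be normalized to (0, 1]")
    }
  }
  out <- list()
  strides <- input_size / vapply(grids, `[`, numeric(1), 1)
  for (s in seq_along(grids)) {
    gy <- grids[[s]][1]; gx <- grids[[s]][2]
    stride <- strides[s]
    for (r in seq_len(nrow(gts))) {
      tw <- gts$w[r] * gx
      th <- gts$h[r] * gy
      for (a in 1:3) {
        aw <- anchors[s, a, 1] / stride
        ah <- anchors[s, a, 2] / stride
        rw <- tw / aw; rh <- th / ah
        if (max(rw, 1 / rw, rh, 1 / rh) >= ratio_gate) next
        cxg <- gts$cx[r] * gx
        cyg <- gts$cy[r] * gy
        gi0 <- min(floor(cxg), gx - 1)
        gj0 <- min(floor(cyg), gy - 1)
        cells <- list(c(gi0, gj0))
        fx <- cxg - gi0; fy <- cyg - gj0
        if (fx < 0.5 && gi0 >= 1) cells <- c(cells, list(c(gi0 - 1, gj0)))
        if (fx >= 0.5 && gi0 < gx - 1) cells <- c(cells, list(c(gi0 + 1, gj0)))
        if (fy < 0.5 && gj0 >= 1) cells <- c(cells, list(c(gi0, gj0 - 1)))
        if (fy >= 0.5 && gj0 < gy - 1) cells <- c(cells, list(c(gi0, gj0 + 1)))
        for (cc in cells) {
          out[[length(out) + 1L]] <- data.frame(
            scale = s, b = gts$image[r], a = a, gi = cc[1], gj = cc[2],
            tx = cxg - cc[1], ty = cyg - cc[2], tw = tw, th = th,
            cls = gts$class_id[r])
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(scale = integer(), b = integer(), a = integer(),
                      gi = integer(), gj = integer(), tx = numeric(),
                      ty = numeric(), tw = numeric(), th = numeric(),
                      cls = integer()))
  }
  do.call(rbind, out)
}

# differentiable complete-IoU loss on (N,4) center/size boxes; `tb` is a
# constant matrix, alpha is detached as usual
ciou_loss_ag <- function(tp, pb, tb) {
  nb <- function(h, j) ag_narrow(tp, h, 2L, j, j)
  pcx <- nb(pb, 1L); pcy <- nb(pb, 2L); pw <- nb(pb, 3L); ph <- nb(pb, 4L)
  tcx <- tb[, 1, drop = FALSE]; tcy <- tb[, 2, drop = FALSE]
  tw <- tb[, 3, drop = FALSE]; th <- tb[, 4, drop = FALSE]
  hw <- ag_mulc(tp, pw, 0.5); hh <- ag_mulc(tp, ph, 0.5)
  px1 <- ag_sub(tp, pcx, hw); px2 <- ag_add(tp, pcx, hw)
  py1 <- ag_sub(tp, pcy, hh); py2 <- ag_add(tp, pcy, hh)
  tx1 <- tcx - tw / 2; tx2 <- tcx + tw / 2
  ty1 <- tcy - th / 2; ty2 <- tcy + th / 2
  iw <- ag_clampmin(tp, ag_sub(tp, ag_emin(tp, px2, tx2), ag_emax(tp, px1, tx1)), 0)
  ih <- ag_clampmin(tp, ag_sub(tp, ag_emin(tp, py2, ty2), ag_emax(tp, py1, ty1)), 0)
  inter <- ag_mul(tp, iw, ih)
  area <- ag_add(tp, ag_mul(tp, pw, ph), tw * th)
  uni <- ag_addc(tp, ag_sub(tp, area, inter), 1e-9)
  iou_h <- ag_div(tp, inter, uni)
  cw <- ag_sub(tp, ag_emax(tp, px2, tx2), ag_emin(tp, px1, tx1))
  ch <- ag_sub(tp, ag_emax(tp, py2, ty2), ag_emin(tp, py1, ty1))
  c2 <- ag_addc(tp, ag_add(tp, ag_pow2(tp, cw), ag_pow2(tp, ch)), 1e-9)
  rho2 <- ag_add(tp, ag_pow2(tp, ag_sub(tp, pcx, tcx)),
                 ag_pow2(tp, ag_sub(tp, pcy, tcy)))
  va <- ag_atan(tp, ag_div(tp, pw, ag_clampmin(tp, ph, 1e-9)))
  v <- ag_mulc(tp, ag_pow2(tp, ag_addc(tp, ag_neg(tp, va),
                                       atan(tw / pmax(th, 1e-9)))), 4 / pi^2)
  alpha <- hval(v) / (1 - hval(iou_h) + hval(v) + 1e-9)   # detached
  loss <- ag_add(tp, ag_addc(tp, ag_neg(tp, iou_h), 1),
                 ag_add(tp, ag_div(tp, rho2, c2), ag_mul(tp, v, alpha)))
  loss
}

#' Compute the composite detection loss
#'
#' box term: mean complete-IoU loss over assigned cells; objectness and class
#' terms: mean binary cross-entropy with logits (objectness targets 1 at
#' assigned cells, 0 elsewhere; one-hot class targets at assigned cells).
#' Scales with no assignments contribute 0 to box and class terms.
#'
#' @param raw list of three raw prediction handles from [forward_detector()].
#' @param ta target assignment from [assign_targets()].
#' @param cfg the [model_config()].
#' @param tp tape (NULL for evaluation only).
#' @param lambda named weights c(box=, obj=, cls=).
#' @return list with `total` (handle), and numeric `box`, `obj`, `cls`,
#'   `total_value`.
#' @export
compute_loss <- function(raw, ta, cfg, tp = NULL,
                         lambda = c(box = 0.05, obj = 1.0, cls = 0.5)) {
  nc <- cfg$num_classes
  nattr <- 5L + nc
  strides <- c(8L, 16L, 32L)
  box_terms <- list(); obj_terms <- list(); cls_terms <- list()
  for (s in seq_along(raw)) {
    d <- dim(hval(raw[[s]]))
    if (any(!is.finite(hval(raw[[s]])))) stop("compute_loss: non-finite logits")
    B <- d[1]; gy <- d[3]; gx <- d[4]
    m <- ag_reshape(tp, raw[[s]], c(B * 3L * gy * gx, nattr))
    tas <- ta[ta$scale == s, , drop = FALSE]
    obj_target <- numeric(B * 3L * gy * gx)
    if (nrow(tas)) {
      idx <- tas$b + B * ((tas$a - 1L) + 3L * (tas$gj + gy * tas$gi))
      obj_target[idx] <- 1
      sel <- ag_index_rows(tp, m, idx)
      ps <- ag_sigmoid(tp, ag_narrow(tp, sel, 2L, 1L, 4L))
      pxy <- ag_addc(tp, ag_mulc(tp, ag_narrow(tp, ps, 2L, 1L, 2L), 2), -0.5)
      anc <- cbind(cfg$anchors[s, tas$a, 1], cfg$anchors[s, tas$a, 2]) / strides[s]
      pwh <- ag_mul(tp, ag_pow2(tp, ag_mulc(tp, ag_narrow(tp, ps, 2L, 3L, 4L), 2)),
                    anc)
      pb <- ag_concat(tp, list(pxy, pwh), 2L)
      tb <- cbind(tas$tx, tas$ty, tas$tw, tas$th)
      box_terms[[length(box_terms) + 1L]] <- ag_mean(tp, ciou_loss_ag(tp, pb, tb))
      if (nc > 0) {
        onehot <- matrix(0, nrow(tas), nc)
        onehot[cbind(seq_len(nrow(tas)), tas$cls + 1L)] <- 1
        cls_terms[[length(cls_terms) + 1L]] <-
          ag_bce_logits(tp, ag_narrow(tp, sel, 2L, 6L, 5L + nc), onehot)
      }
    }
    obj_logits <- ag_narrow(tp, m, 2L, 5L, 5L)
    obj_terms[[length(obj_terms) + 1L]] <-
      ag_bce_logits(tp, obj_logits, matrix(obj_target, ncol = 1L))
  }
  mean_terms <- function(terms) {
    if (!length(terms)) return(NULL)
    acc <- terms[[1L]]
    for (i in seq_along(terms)[-1L]) acc <- ag_add(tp, acc, terms[[i]])
    ag_mulc(tp, acc, 1 / length(terms))
  }
  box_h <- mean_terms(box_terms)
  obj_h <- mean_terms(obj_terms)
  cls_h <- mean_terms(cls_terms)
  zero <- list(id = NA_integer_, value = 0)
  total <- ag_add(tp, ag_add(tp,
    ag_mulc(tp, box_h %||% zero, lambda[["box"]]),
    ag_mulc(tp, obj_h, lambda[["obj"]])),
    ag_mulc(tp, cls_h %||% zero, lambda[["cls"]]))
  list(total = total,
       box = if (is.null(box_h)) 0 else as.numeric(hval(box_h)),
       obj = as.numeric(hval(obj_h)),
       cls = if (is.null(cls_h)) 0 else as.numeric(hval(cls_h)),
       total_value = as.numeric(hval(total)))
}
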