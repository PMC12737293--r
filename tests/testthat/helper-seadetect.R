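# Shared helpers: independent brute-force oracles (plain loops, no package
# primitives) used to validate the vectorized implementations.

h_of <- function(v) list(id = NA_integer_, value = v)

rarr <- function(..., seed = NULL) {
  d <- c(...)
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(prod(d)), d)
}

# mean over H / W by explicit double loops
oracle_directional_pool <- function(x) {
  d <- dim(x)
  xh <- array(0, c(d[1], d[2], d[4]))
  xw <- array(0, c(d[1], d[2], d[3]))
  for (b in seq_len(d[1])) for (cc in seq_len(d[2])) {
    for (w in seq_len(d[4])) xh[b, cc, w] <- mean(x[b, cc, , w])
    for (hh in seq_len(d[3])) xw[b, cc, hh] <- mean(x[b, cc, hh, ])
  }
  list(xh = xh, xw = xw)
}

oracle_dwconv1d <- function(x, w, bias) {
  d <- dim(x)
  k <- ncol(w)
  p <- (k - 1) / 2
  y <- array(0, d)
  for (b in seq_len(d[1])) for (cc in seq_len(d[2])) for (l in seq_len(d[3])) {
    acc <- bias[cc]
    for (t in seq_len(k)) {
      src <- l + t - 1 - p
      if (src >= 1 && src <= d[3]) acc <- acc + w[cc, t] * x[b, cc, src]
    }
    y[b, cc, l] <- acc
  }
  y
}

oracle_gn <- function(x, gamma, beta, G, eps = 1e-5) {
  d <- dim(x)                      # (B, C, L)
  cg <- d[2] / G
  y <- x
  for (b in seq_len(d[1])) for (g in seq_len(G)) {
    ch <- ((g - 1) * cg + 1):(g * cg)
    v <- x[b, ch, ]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    for (cc in ch) {
      y[b, cc, ] <- gamma[cc] * (x[b, cc, ] - mu) / sqrt(va + eps) + beta[cc]
    }
  }
  y
}

sigm <- function(x) 1 / (1 + exp(-x))

# full SMSA unrolled with loops, reading the module's own parameter arrays
oracle_smsa <- function(mod, x) {
  d <- dim(x)
  C <- d[2]
  cg <- C / 4
  p <- oracle_directional_pool(x)
  run_seq <- function(s, gamma, beta) {
    parts <- vector("list", 4)
    for (i in 1:4) {
      sub <- s[, ((i - 1) * cg + 1):(i * cg), , drop = FALSE]
      parts[[i]] <- oracle_dwconv1d(sub, mod$params[[paste0("w", i)]],
                                    mod$params[[paste0("b", i)]])
    }
    y <- array(0, dim(s))
    for (i in 1:4) y[, ((i - 1) * cg + 1):(i * cg), ] <- parts[[i]]
    sigm(oracle_gn(y, gamma, beta, 4))
  }
  ah <- run_seq(p$xh, mod$params$gn_h_gamma, mod$params$gn_h_beta)  # (B,C,W)
  aw <- run_seq(p$xw, mod$params$gn_w_gamma, mod$params$gn_w_beta)  # (B,C,H)
  y <- x
  for (b in seq_len(d[1])) for (cc in seq_len(C)) {
    for (hh in seq_len(d[3])) for (w in seq_len(d[4])) {
      y[b, cc, hh, w] <- x[b, cc, hh, w] * aw[b, cc, hh] * ah[b, cc, w]
    }
  }
  y
}

# PCSA unrolled with loops for small pooled grids
oracle_pcsa <- function(mod, x, pooled = NULL) {
  d <- dim(x)
  C <- d[2]
  oh <- min(mod$pooled[1], d[3]); ow <- min(mod$pooled[2], d[4])
  # adaptive average pooling
  xp <- array(0, c(d[1], C, oh, ow))
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    hs <- floor((i - 1) * d[3] / oh) + 1; he <- ceiling(i * d[3] / oh)
    ws <- floor((j - 1) * d[4] / ow) + 1; we <- ceiling(j * d[4] / ow)
    for (b in seq_len(d[1])) for (cc in seq_len(C)) {
      xp[b, cc, i, j] <- mean(x[b, cc, hs:he, ws:we])
    }
  }
  n <- oh * ow
  y <- x
  for (b in seq_len(d[1])) {
    xt <- matrix(xp[b, , , ], C, n)        # column-major: token = (i, j) pairs
    q <- xt * mod$params$wq + mod$params$bq
    k <- xt * mod$params$wk + mod$params$bk
    v <- xt * mod$params$wv + mod$params$bv
    denom <- if (mod$scale_denominator == "sqrt_C") sqrt(C) else C
    sc <- q %*% t(k) / denom
    a <- t(apply(sc, 1, function(r) exp(r - max(r, 0)) / sum(exp(r - max(r, 0)))))
    xa <- a %*% v
    gate <- sigm(rowMeans(xa))
    for (cc in seq_len(C)) y[b, cc, , ] <- x[b, cc, , ] * gate[cc]
  }
  y
}

# direct convolution by loops, asymmetric pad c(l, r, t, b), groups supported
oracle_conv2d <- function(x, w, bias, stride, pad, groups = 1) {
  d <- dim(x); wd <- dim(w)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Cout <- wd[1]; kh <- wd[3]; kw <- wd[4]
  Hp <- H + pad[3] + pad[4]; Wp <- W + pad[1] + pad[2]
  xp <- array(0, c(B, C, Hp, Wp))
  xp[, , pad[3] + (1:H), pad[1] + (1:W)] <- x
  Ho <- (Hp - kh) %/% stride + 1; Wo <- (Wp - kw) %/% stride + 1
  cpg <- C / groups; opg <- Cout / groups
  y <- array(0, c(B, Cout, Ho, Wo))
  for (b in seq_len(B)) for (o in seq_len(Cout)) {
    g <- ceiling(o / opg)
    cin <- ((g - 1) * cpg + 1):(g * cpg)
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      acc <- if (is.null(bias)) 0 else bias[o]
      for (ci in seq_along(cin)) for (u in seq_len(kh)) for (vv in seq_len(kw)) {
        acc <- acc + w[o, ci, u, vv] *
          xp[b, cin[ci], (i - 1) * stride + u, (j - 1) * stride + vv]
      }
      y[b, o, i, j] <- acc
    }
  }
  y
}

oracle_bn_eval <- function(x, gamma, beta, rm, rv, eps = 1e-3) {
  d <- dim(x)
  y <- x
  for (cc in seq_len(d[2])) {
    y[, cc, , ] <- gamma[cc] * (x[, cc, , ] - rm[cc]) / sqrt(rv[cc] + eps) + beta[cc]
  }
  y
}

silu_f <- function(x) x * sigm(x)

# full PSConv unrolled (eval-mode BN), reading the module's parameters
oracle_psconv <- function(mod, x) {
  branch_out <- list()
  for (i in 1:4) {
    br <- mod$children[[paste0("branch", i)]]
    cv <- br$children$conv
    bn <- br$children$bn
    y <- oracle_conv2d(x, cv$params$w, NULL, cv$stride, cv$pad, cv$groups)
    y <- oracle_bn_eval(y, bn$params$gamma, bn$params$beta,
                        bn$buffers$rmean, bn$buffers$rvar, bn$eps)
    branch_out[[i]] <- silu_f(y)
  }
  cat_d <- dim(branch_out[[1]])
  conc <- array(0, c(cat_d[1], 4 * cat_d[2], cat_d[3], cat_d[4]))
  for (i in 1:4) {
    conc[, ((i - 1) * cat_d[2] + 1):(i * cat_d[2]), , ] <- branch_out[[i]]
  }
  fs <- mod$children$fuse
  cv <- fs$children$conv; bn <- fs$children$bn
  y <- oracle_conv2d(conc, cv$params$w, NULL, cv$stride, cv$pad, cv$groups)
  y <- oracle_bn_eval(y, bn$params$gamma, bn$params$beta,
                      bn$buffers$rmean, bn$buffers$rvar, bn$eps)
  silu_f(y)
}

# O(n^2) reference NMS (single image/class handled by grouping outside)
oracle_nms <- function(dets, thr) {
  keep <- logical(nrow(dets))
  for (img in unique(dets$image)) for (cl in unique(dets$class_id)) {
    rows <- which(dets$image == img & dets$class_id == cl)
    if (!length(rows)) next
    ord <- rows[order(-dets$confidence[rows])]
    chosen <- integer()
    for (r in ord) {
      ok <- TRUE
      for (cr in chosen) {
        if (iou(as.numeric(dets[r, c("x1", "y1", "x2", "y2")]),
                as.numeric(dets[cr, c("x1", "y1", "x2", "y2")])) >= thr) {
          ok <- FALSE
          break
        }
      }
      if (ok) chosen <- c(chosen, r)
    }
    keep[chosen] <- TRUE
  }
  dets[keep, , drop = FALSE]
}

# all-points AP by direct definition: for each distinct recall level r,
# take the best precision achieved at recall >= r
oracle_ap <- function(tp_flags_ordered, npos) {
  tp <- cumsum(tp_flags_ordered)
  fp <- cumsum(!tp_flags_ordered)
  rec <- tp / npos
  prec <- tp / (tp + fp)
  levels <- sort(unique(rec))
  ap <- 0
  prev <- 0
  for (r in levels) {
    if (r == 0) next
    pmax_here <- max(prec[rec >= r])
    ap <- ap + (r - prev) * pmax_here
    prev <- r
  }
  ap
}

make_box_df <- function(image, class_id, conf, boxes) {
  data.frame(image = image, class_id = class_id, confidence = conf,
             x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3], y2 = boxes[, 4])
}

tiny_cfg <- function(input_size = 64L, seed = 7L, ...) {
  model_config(num_classes = 4L, width_multiple = 0.25, input_size = input_size,
               seed = seed, ...)
}
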