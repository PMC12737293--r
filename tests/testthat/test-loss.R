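test_that("anchor assignment gates by size ratio and expands to neighbor cells", {
  cfg <- tiny_cfg(64L)
  grids <- list(c(8, 8), c(4, 4), c(2, 2))

  empty <- assign_targets(data.frame(image = integer(), class_id = integer(),
                                     cx = numeric(), cy = numeric(),
                                     w = numeric(), h = numeric()),
                          cfg$anchors, grids, 64L)
  expect_equal(nrow(empty), 0)

  # a gt exactly matching anchor (1,1) = 10x13 px, centered
  gt <- data.frame(image = 1, class_id = 0, cx = 0.5, cy = 0.5,
                   w = 10 / 64, h = 13 / 64)
  ta <- assign_targets(gt, cfg$anchors, grids, 64L)
  center <- ta[ta$scale == 1 & ta$a == 1 & ta$gi == 4 & ta$gj == 4, ]
  expect_gte(nrow(center), 1)

  expect_error(assign_targets(data.frame(image = 1, class_id = 0, cx = 1.2,
                                         cy = 0.5, w = 0.1, h = 0.1),
                              cfg$anchors, grids, 64L), "normalized")

  # brute-force re-implementation of the ratio gate on a toy scene
  set.seed(41)
  gts <- data.frame(image = rep(1:2, each = 3), class_id = sample(0:3, 6, TRUE),
                    cx = runif(6, 0.1, 0.9), cy = runif(6, 0.1, 0.9),
                    w = runif(6, 0.05, 0.6), h = runif(6, 0.05, 0.6))
  ta <- assign_targets(gts, cfg$anchors, grids, 64L)
  brute <- 0L
  for (r in seq_len(nrow(gts))) for (s in 1:3) for (a in 1:3) {
    stride <- 64 / grids[[s]][1]
    tw <- gts$w[r] * grids[[s]][2]; th <- gts$h[r] * grids[[s]][1]
    aw <- cfg$anchors[s, a, 1] / stride; ah <- cfg$anchors[s, a, 2] / stride
    if (max(tw / aw, aw / tw, th / ah, ah / th) < 4) {
      # count candidate cells exactly as specified: center + up to 2 neighbors
      cxg <- gts$cx[r] * grids[[s]][2]; cyg <- gts$cy[r] * grids[[s]][1]
      gi <- min(floor(cxg), grids[[s]][2] - 1)
      gj <- min(floor(cyg), grids[[s]][1] - 1)
      ncell <- 1L
      if (cxg - gi < 0.5 && gi >= 1) ncell <- ncell + 1L
      if (cxg - gi >= 0.5 && gi < grids[[s]][2] - 1) ncell <- ncell + 1L
      if (cyg - gj < 0.5 && gj >= 1) ncell <- ncell + 1L
      if (cyg - gj >= 0.5 && gj < grids[[s]][1] - 1) ncell <- ncell + 1L
      brute <- brute + ncell
    }
  }
  expect_equal(nrow(ta), brute)
})

test_that("loss vanishes for saturated perfect predictions and empty scenes", {
  cfg <- tiny_cfg(64L)
  grids <- list(c(8, 8), c(4, 4), c(2, 2))
  gt <- data.frame(image = 1, class_id = 2, cx = 0.5, cy = 0.5,
                   w = 12 / 64, h = 12 / 64)
  ta <- assign_targets(gt, cfg$anchors, grids, 64L)
  raw <- list(array(-20, c(1, 3, 8, 8, 9)), array(-20, c(1, 3, 4, 4, 9)),
              array(-20, c(1, 3, 2, 2, 9)))
  # invert the decode transform at every assigned cell
  strides <- c(8, 16, 32)
  for (r in seq_len(nrow(ta))) {
    s <- ta$scale[r]
    aw <- cfg$anchors[s, ta$a[r], 1] / strides[s]
    ah <- cfg$anchors[s, ta$a[r], 2] / strides[s]
    lx <- qlogis((ta$tx[r] + 0.5) / 2)
    ly <- qlogis((ta$ty[r] + 0.5) / 2)
    lw <- qlogis(sqrt(ta$tw[r] / aw) / 2)
    lh <- qlogis(sqrt(ta$th[r] / ah) / 2)
    raw[[s]][1, ta$a[r], ta$gj[r] + 1, ta$gi[r] + 1, 1:5] <- c(lx, ly, lw, lh, 20)
    raw[[s]][1, ta$a[r], ta$gj[r] + 1, ta$gi[r] + 1, 5 + ta$cls[r] + 1] <- 20
  }
  ls <- compute_loss(lapply(raw, h_of), ta, cfg)
  expect_lt(ls$box, 1e-6)
  expect_lt(ls$obj, 1e-6)
  expect_lt(ls$cls, 1e-6)
  expect_lt(ls$total_value, 1e-5)

  # no ground truth, strongly negative objectness logits
  empty_ta <- assign_targets(gt[0, ], cfg$anchors, grids, 64L)
  ls0 <- compute_loss(lapply(raw, function(r) h_of(r * 0 - 20)), empty_ta, cfg)
  expect_equal(ls0$box, 0)
  expect_equal(ls0$cls, 0)
  expect_lt(ls0$obj, 1e-6)
})

test_that("single-cell losses equal hand-computed closed forms", {
  cfg <- tiny_cfg(64L)
  grids <- list(c(8, 8), c(4, 4), c(2, 2))
  # force exactly one assignment: small box clear of all cell borders
  gt <- data.frame(image = 1, class_id = 1, cx = 9.6 / 64, cy = 9.6 / 64,
                   w = 10 / 64, h = 13 / 64)
  ta <- assign_targets(gt, cfg$anchors, grids, 64L)
  ta <- ta[ta$scale == 1 & ta$a == 1, ][1, ]  # evaluate that single row
  raw <- list(array(0, c(1, 3, 8, 8, 9)), array(-30, c(1, 3, 4, 4, 9)),
              array(-30, c(1, 3, 2, 2, 9)))
  ls <- compute_loss(lapply(raw, h_of), ta, cfg)

  # box: all logits zero -> decoded offset (0.5, 0.5), size = anchor
  pred <- c(0.5, 0.5, cfg$anchors[1, 1, ] / 8)
  tgt <- c(ta$tx, ta$ty, ta$tw, ta$th)
  hand_ciou <- ciou_loss(c(pred[1] - pred[3] / 2, pred[2] - pred[4] / 2,
                           pred[1] + pred[3] / 2, pred[2] + pred[4] / 2),
                         c(tgt[1] - tgt[3] / 2, tgt[2] - tgt[4] / 2,
                           tgt[1] + tgt[3] / 2, tgt[2] + tgt[4] / 2))
  expect_equal(ls$box / 3, hand_ciou / 3, tolerance = 1e-6)

  # cls: one cell, logits 0 against one-hot -> mean BCE = log(2)
  expect_equal(ls$cls / 3, log(2) / 3, tolerance = 1e-9)

  # obj on scale 1: one positive cell among 192, logits all 0 -> BCE log(2);
  # scales 2 and 3: logits -30, target 0 -> ~0
  expect_equal(ls$obj, log(2) / 3, tolerance = 1e-4)
})

test_that("loss component weights scale their terms linearly", {
  cfg <- tiny_cfg(64L)
  grids <- list(c(8, 8), c(4, 4), c(2, 2))
  set.seed(42)
  gt <- data.frame(image = 1, class_id = 0, cx = 0.4, cy = 0.6,
                   w = 0.2, h = 0.25)
  ta <- assign_targets(gt, cfg$anchors, grids, 64L)
  raw <- lapply(list(c(1, 3, 8, 8, 9), c(1, 3, 4, 4, 9), c(1, 3, 2, 2, 9)),
                function(d) h_of(array(rnorm(prod(d)), d)))
  l1 <- compute_loss(raw, ta, cfg, lambda = c(box = 0.05, obj = 1, cls = 0.5))
  l2 <- compute_loss(raw, ta, cfg, lambda = c(box = 0.10, obj = 2, cls = 1.5))
  expect_equal(l2$total_value - l1$total_value,
               0.05 * l1$box + 1 * l1$obj + 1 * l1$cls, tolerance = 1e-10)
})

test_that("backprop gradients match finite differences on a tiny model", {
  cfg <- model_config(num_classes = 2L, width_multiple = 0.25, input_size = 32L,
                      seed = 5L)
  m <- build_model(cfg)
  x <- rarr(1, 3, 32, 32, seed = 50)
  gt <- data.frame(image = 1, class_id = 1, cx = 0.5, cy = 0.45,
                   w = 0.3, h = 0.35)
  grids <- list(c(4, 4), c(2, 2), c(1, 1))
  ta <- assign_targets(gt, cfg$anchors, grids, 32L)
  loss_value <- function() {
    raw <- forward_detector(m, x, NULL, training = FALSE)
    compute_loss(raw, ta, cfg, NULL)$total_value
  }
  tp <- seadetect:::ag_tape()
  raw <- forward_detector(m, x, tp, training = FALSE)
  ls <- compute_loss(raw, ta, cfg, tp)
  grads <- seadetect:::ag_backward(tp, ls$total)
  picks <- c("stem", "c3b", "sppf", "neck_c3_p3", "detect")
  gmaps <- lapply(picks, function(p) {
    seadetect:::sd_param_grads(seadetect:::model_node(m, p)$module, grads)
  })
  names(gmaps) <- picks

  set.seed(51)
  checked <- 0L
  for (pick in picks) {
    nd <- seadetect:::model_node(m, pick)
    refs <- seadetect:::sd_param_refs(nd$module)
    gmap <- gmaps[[pick]]
    nm <- sample(names(refs), 1)
    r <- refs[[nm]]
    i <- sample(length(r$env$params[[r$key]]), 1)
    g_an <- if (is.null(gmap[[nm]])) 0 else as.numeric(gmap[[nm]])[i]
    eps <- 1e-4
    orig <- r$env$params[[r$key]][i]
    r$env$params[[r$key]][i] <- orig + eps; f1 <- loss_value()
    r$env$params[[r$key]][i] <- orig - eps; f0 <- loss_value()
    r$env$params[[r$key]][i] <- orig
    fd <- (f1 - f0) / (2 * eps)
    expect_equal(g_an, fd, tolerance = 1e-3)
    checked <- checked + 1L
  }
  expect_equal(checked, 5L)
})

test_that("short training runs descend and are reproducible", {
  run_once <- function() {
    m <- build_model(tiny_cfg(64L, seed = 9L))
    sc <- generate_scene(scene_spec(image_size = 64,
                                    counts = c(echinus = 1, starfish = 1,
                                               holothurian = 0, scallop = 0),
                                    seed = 2))
    train_detector(m, list(sc), train_hyper(epochs = 4, batch_size = 1,
                                            seed = 3))$history
  }
  h1 <- run_once()
  expect_true(all(is.finite(h1$total)))
  expect_lt(h1$total[nrow(h1)], h1$total[1])
  h2 <- run_once()
  expect_identical(h1$total, h2$total)  # bitwise reproducible on one thread
})
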