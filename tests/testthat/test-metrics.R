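test_that("IoU handles identity, disjoint, partial overlap and degenerate boxes", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0.0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)),
               iou(c(1, 0, 3, 2), c(0, 0, 2, 2)))     # symmetric
  expect_equal(iou(c(1, 1, 1, 3), c(0, 0, 2, 2)), 0)  # zero-area box
})

test_that("complete-IoU loss follows its closed form", {
  expect_equal(ciou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2)), 0.0)
  # concentric, same aspect: center and aspect terms vanish
  a <- c(1, 1, 5, 5); b <- c(2, 2, 4, 4)
  expect_equal(ciou_loss(a, b), 1 - iou(a, b))
  # hand evaluation for two touching squares (0,0,2,2) vs (2,2,4,4):
  # IoU 0; centers (1,1),(3,3) -> rho2 = 8; enclosing 4x4 -> c2 = 32;
  # same aspect -> v = 0; loss = 1 + 8/32 = 1.25
  expect_equal(ciou_loss(c(0, 0, 2, 2), c(2, 2, 4, 4)), 1.25)
  # aspect term: (0,0,2,2) vs (0,0,4,1) at same corner
  p <- c(0, 0, 2, 2); g <- c(0, 0, 4, 1)
  i <- iou(p, g)
  v <- (4 / pi^2) * (atan(4 / 1) - atan(1))^2
  al <- v / (1 - i + v)
  rho2 <- (1 - 2)^2 + (1 - 0.5)^2
  c2 <- 4^2 + 2^2
  expect_equal(ciou_loss(p, g), 1 - i + rho2 / c2 + al * v, tolerance = 1e-12)
  expect_gte(ciou_loss(p, g), 0)
})

test_that("NMS keeps the strongest box, is idempotent, and matches brute force", {
  one <- make_box_df(1L, 0L, 0.7, matrix(c(0, 0, 4, 4), 1))
  expect_equal(nms(one, 0.5), one)

  two <- make_box_df(1L, 0L, c(0.9, 0.8),
                     matrix(c(0, 0, 4, 4, 0, 0, 4, 4), 2, byrow = TRUE))
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  set.seed(31)
  for (trial in 1:5) {
    n <- 25
    xy <- matrix(runif(2 * n, 0, 80), n)
    wh <- matrix(runif(2 * n, 5, 30), n)
    dets <- make_box_df(sample(1:2, n, TRUE), sample(0:1, n, TRUE), runif(n),
                        cbind(xy, xy + wh))
    a <- nms(dets, 0.5)
    expect_equal(a, oracle_nms(dets, 0.5))
    expect_equal(nms(a, 0.5), a)    # idempotent
    km <- as.matrix(a[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
      if (i != j && a$image[i] == a$image[j] && a$class_id[i] == a$class_id[j]) {
        expect_lt(iou(km[i, ], km[j, ]), 0.5)
      }
    }
  }
})

test_that("matching is one-to-one, greedy by confidence, and conserves counts", {
  gts <- make_box_df(1L, 0L, 1, matrix(c(0, 0, 10, 10, 20, 20, 30, 30),
                                       2, byrow = TRUE))[, -3]
  perfect <- make_box_df(1L, 0L, 1.0, as.matrix(gts[, c("x1", "y1", "x2", "y2")]))
  mm <- match_detections(perfect, gts)
  expect_equal(c(mm$tp, mm$fp, mm$fn), c(2, 0, 0))

  none <- perfect[0, ]
  gts5 <- do.call(rbind, replicate(5, gts[1, , drop = FALSE], simplify = FALSE))
  gts5$x1 <- gts5$x1 + (0:4) * 50; gts5$x2 <- gts5$x2 + (0:4) * 50
  mm0 <- match_detections(none, gts5)
  expect_equal(c(mm0$tp, mm0$fp, mm0$fn), c(0, 0, 5))

  # 3 detections / 2 gts: the higher-confidence det takes the shared gt
  gt2 <- make_box_df(1L, 0L, 1, matrix(c(0, 0, 10, 10, 40, 0, 50, 10),
                                       2, byrow = TRUE))[, -3]
  d3 <- make_box_df(1L, 0L, c(0.9, 0.8, 0.7),
                    matrix(c(1, 0, 11, 10,      # overlaps gt1 (IoU ~ 0.8)
                             0, 1, 10, 11,      # also overlaps gt1
                             100, 100, 110, 110),  # matches nothing
                           3, byrow = TRUE))
  m3 <- match_detections(d3, gt2)
  expect_equal(m3$tp_flags, c(TRUE, FALSE, FALSE))
  expect_equal(m3$tp + m3$fn, nrow(gt2))
  expect_equal(m3$tp + m3$fp, nrow(d3))

  set.seed(32)
  for (trial in 1:4) {
    n <- 12; g <- 8
    dets <- make_box_df(1L, sample(0:1, n, TRUE), runif(n),
                        { xy <- matrix(runif(2 * n, 0, 60), n)
                          cbind(xy, xy + matrix(runif(2 * n, 8, 25), n)) })
    gtr <- make_box_df(1L, sample(0:1, g, TRUE), 1,
                       { xy <- matrix(runif(2 * g, 0, 60), g)
                         cbind(xy, xy + matrix(runif(2 * g, 8, 25), g)) })[, -3]
    mm <- match_detections(dets, gtr)
    for (cl in 0:1) {
      expect_equal(sum(mm$tp_flags[dets$class_id == cl]) +
                     (mm_cl <- match_detections(dets[dets$class_id == cl, ],
                                                gtr[gtr$class_id == cl, ]))$fn,
                   sum(gtr$class_id == cl))
    }
  }
})

test_that("precision/recall ratios and 0/0 conventions hold", {
  expect_equal(precision_recall(8, 2, 0)$precision, 0.8)
  expect_equal(precision_recall(0, 0, 3)$precision, 0)
  expect_equal(precision_recall(6, 1, 4)$recall, 0.6)
  expect_equal(precision_recall(0, 2, 0)$recall, 0)
  expect_error(precision_recall(-1, 0, 0), "non-negative")
})

test_that("average precision integrates the PR curve correctly", {
  gts <- make_box_df(1L, 0L, 1, matrix(c(0, 0, 10, 10, 30, 30, 40, 40),
                                       2, byrow = TRUE))[, -3]
  perfect <- make_box_df(1L, 0L, c(0.9, 0.8),
                         as.matrix(gts[, c("x1", "y1", "x2", "y2")]))
  expect_equal(average_precision(perfect, gts)$ap, 1.0)

  allfp <- make_box_df(1L, 0L, c(0.9, 0.8),
                       matrix(c(100, 100, 110, 110, 200, 200, 210, 210),
                              2, byrow = TRUE))
  expect_equal(average_precision(allfp, gts)$ap, 0.0)

  # toy sweep: confidences 0.9 (TP), 0.8 (FP), 0.7 (TP)
  toy <- make_box_df(1L, 0L, c(0.9, 0.8, 0.7),
                     matrix(c(0, 0, 10, 10,
                              100, 100, 110, 110,
                              30, 30, 40, 40), 3, byrow = TRUE))
  ap <- average_precision(toy, gts)$ap
  expect_equal(ap, oracle_ap(c(TRUE, FALSE, TRUE), 2))
  expect_equal(ap, 0.5 * 1 + 0.5 * (2 / 3))   # frozen hand integration

  # invariance to monotone confidence rescaling
  toy2 <- toy; toy2$confidence <- plogis(5 * toy$confidence - 2)
  expect_equal(average_precision(toy2, gts)$ap, ap)

  # a trailing false positive never increases AP; a leading TP never lowers it
  worse <- rbind(toy, make_box_df(1L, 0L, 0.1,
                                  matrix(c(300, 300, 310, 310), 1)))
  expect_lte(average_precision(worse, gts)$ap, ap)
  gts3 <- rbind(gts, make_box_df(1L, 0L, 1, matrix(c(60, 60, 70, 70), 1))[, -3])
  better <- rbind(make_box_df(1L, 0L, 0.95, matrix(c(60, 60, 70, 70), 1)), toy)
  expect_gte(average_precision(better, gts3)$ap,
             average_precision(toy, gts3)$ap)

  expect_error(average_precision(toy, gts[0, ]), "no ground truths")
})

test_that("mAP is the arithmetic mean of per-class APs", {
  expect_equal(mean_average_precision(1.0), 1.0)
  expect_equal(mean_average_precision(c(0.5, 1.0)), 0.75)
  expect_equal(mean_average_precision(rep(0.642, 4)), 0.642)
  expect_error(mean_average_precision(numeric()), "empty")
})

test_that("random detection sets agree with the brute-force AP oracle", {
  set.seed(33)
  for (trial in 1:5) {
    g <- 6
    gxy <- matrix(runif(2 * g, 0, 100), g)
    gts <- make_box_df(1L, 0L, 1, cbind(gxy, gxy + 15))[, -3]
    n <- 10
    jit <- matrix(rnorm(2 * n, 0, 6), n)
    pick <- sample(g, n, TRUE)
    dxy <- gxy[pick, ] + jit
    dets <- make_box_df(1L, 0L, runif(n), cbind(dxy, dxy + 15))
    res <- average_precision(dets, gts)
    ord <- order(-dets$confidence)
    flags <- match_detections(dets[ord, ], gts)$tp_flags
    expect_equal(res$ap, oracle_ap(flags, g), tolerance = 1e-12)
  }
})
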