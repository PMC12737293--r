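test_that("scene generation is deterministic, labeled, and respects counts", {
  bg <- generate_scene(scene_spec(counts = c(echinus = 0, starfish = 0,
                                             holothurian = 0, scallop = 0),
                                  seed = 1))
  expect_equal(nrow(bg$labels), 0)
  expect_equal(dim(bg$image), c(256, 256, 3))
  expect_true(all(bg$image >= 0 & bg$image <= 1))

  s1 <- generate_scene(scene_spec(seed = 1))
  s2 <- generate_scene(scene_spec(seed = 1))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$labels, s2$labels)
  s3 <- generate_scene(scene_spec(seed = 2))
  expect_false(identical(s1$image, s3$image))

  # 3 echinus + 1 starfish, occlusion forbidden: exactly 4 disjoint boxes
  sc <- generate_scene(scene_spec(counts = c(echinus = 3, starfish = 1,
                                             holothurian = 0, scallop = 0),
                                  occlusion_prob = 0, seed = 4))
  expect_equal(nrow(sc$labels), 4)
  expect_equal(sort(unique(sc$labels$class_id)), c(0, 1))
  px <- yolo_to_corners(sc$labels, 256, 256)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(iou(as.numeric(px[i, c("x1", "y1", "x2", "y2")]),
                     as.numeric(px[j, c("x1", "y1", "x2", "y2")])), 0)
  }
})

test_that("every label back-projects onto its shape mask", {
  sc <- generate_scene(scene_spec(seed = 7))
  expect_gt(nrow(sc$labels), 0)
  for (i in seq_len(nrow(sc$labels))) {
    m <- sc$masks[[i]]
    expect_true(any(m))
    lb <- sc$labels[i, ]
    x1 <- round((lb$cx - lb$w / 2) * 256); x2 <- round((lb$cx + lb$w / 2) * 256)
    y1 <- round((lb$cy - lb$h / 2) * 256); y2 <- round((lb$cy + lb$h / 2) * 256)
    sub <- m[max(1, y1):min(256, y2 + 1), max(1, x1):min(256, x2 + 1)]
    expect_true(any(sub))
    # and the box is tight: no mask pixel outside it
    expect_equal(sum(m), sum(sub))
  }
})

test_that("randomized class counts follow their uniform ranges", {
  n <- 60
  cnt <- integer(n)
  for (i in seq_len(n)) {
    sc <- generate_scene(scene_spec(image_size = 96,
                                    counts = c(echinus = 2, starfish = 0,
                                               holothurian = 0, scallop = 0),
                                    randomize_counts = TRUE, occlusion_prob = 1,
                                    seed = 100 + i))
    cnt[i] <- nrow(sc$labels)
  }
  expect_true(all(cnt %in% 0:2))
  # mean of uniform {0,1,2} is 1, sd sqrt(2/3); allow 3 standard errors
  expect_lt(abs(mean(cnt) - 1), 3 * sqrt(2 / 3) / sqrt(n))
})

test_that("YOLO dataset writing and reading round-trips labels and splits", {
  dir <- file.path(tempdir(), "sd_ds")
  unlink(dir, recursive = TRUE)
  scenes <- lapply(1:10, function(i) {
    generate_scene(scene_spec(image_size = 96, seed = i,
                              counts = c(echinus = 1, starfish = 1,
                                         holothurian = 0, scallop = 1)))
  })
  write_yolo_dataset(scenes, dir)
  expect_length(list.files(file.path(dir, "images", "train")), 7)
  expect_length(list.files(file.path(dir, "images", "val")), 2)
  expect_length(list.files(file.path(dir, "images", "test")), 1)

  ds <- read_yolo_dataset(dir)
  expect_equal(ds$names, seadetect_classes())
  back <- ds$train[[1]]$labels
  orig <- scenes[[1]]$labels
  expect_equal(back$class_id, orig$class_id)
  expect_equal(back$cx, round(orig$cx, 6), tolerance = 1e-9)
  expect_equal(back$h, round(orig$h, 6), tolerance = 1e-9)
  expect_equal(dim(ds$train[[1]]$image), c(96, 96, 3))

  lf <- file.path(dir, "labels", "train", "scene_0001.txt")
  writeLines(c("0 0.5 0.5 0.1 0.1", "1 bad line here x"), lf)
  expect_error(read_yolo_dataset(dir), "line 2.*scene_0001")
  one <- seadetect:::parse_yolo_label_file(
    { tf <- tempfile(); writeLines("0 0.5 0.5 0.1 0.1", tf); tf })
  expect_equal(one$class_id, 0L)
  expect_equal(unlist(one[1, 2:5]), c(cx = 0.5, cy = 0.5, w = 0.1, h = 0.1))
})

test_that("mosaic composites preserve geometry and never invent labels", {
  solid <- lapply(1:4, function(i) {
    structure(list(image = array(0.3, c(64, 64, 3)),
                   labels = data.frame(class_id = integer(), cx = numeric(),
                                       cy = numeric(), w = numeric(),
                                       h = numeric())),
              class = "labeled_scene")
  })
  mz <- mosaic_augment(solid, 64L, seed = 1)
  expect_true(all(abs(mz$image - 0.3) < 1e-12))
  expect_equal(nrow(mz$labels), 0)
  expect_error(mosaic_augment(solid[1:3], 64L), "exactly 4")

  # center at the exact midpoint, equal sizes: quadrants equal source crops
  scenes <- lapply(1:4, function(i) {
    generate_scene(scene_spec(image_size = 64, seed = 10 + i,
                              counts = c(echinus = 1, starfish = 1,
                                         holothurian = 0, scallop = 0)))
  })
  mz <- mosaic_augment(scenes, 64L, center = c(32, 32))
  expect_equal(mz$image[1:32, 1:32, ], scenes[[1]]$image[33:64, 33:64, ])
  expect_equal(mz$image[1:32, 33:64, ], scenes[[2]]$image[33:64, 1:32, ])
  expect_equal(mz$image[33:64, 1:32, ], scenes[[3]]$image[1:32, 33:64, ])
  expect_equal(mz$image[33:64, 33:64, ], scenes[[4]]$image[1:32, 1:32, ])

  for (sd in 1:5) {
    mz <- mosaic_augment(scenes, 64L, seed = sd)
    expect_lte(nrow(mz$labels),
               sum(vapply(scenes, function(s) nrow(s$labels), 0)))
    if (nrow(mz$labels)) {
      expect_true(all(mz$labels$cx - mz$labels$w / 2 >= -1e-9))
      expect_true(all(mz$labels$cx + mz$labels$w / 2 <= 1 + 1e-9))
      expect_true(all(mz$labels$cy - mz$labels$h / 2 >= -1e-9))
      expect_true(all(mz$labels$cy + mz$labels$h / 2 <= 1 + 1e-9))
      expect_true(all(mz$labels$w * mz$labels$h * 64 * 64 >= 1))
    }
  }
})

test_that("an oracle detector scores perfectly on generated scenes", {
  scenes <- lapply(1:4, function(i) {
    generate_scene(scene_spec(image_size = 96, seed = 20 + i))
  })
  gts <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    yolo_to_corners(scenes[[i]]$labels, 96, 96, image = i)
  }))
  dets <- gts
  dets$confidence <- 1.0
  res <- evaluate_detections(dets, gts)
  expect_true(all(res$per_class$precision == 1))
  expect_true(all(res$per_class$recall == 1))
  expect_equal(res$map, 1.0)
})
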