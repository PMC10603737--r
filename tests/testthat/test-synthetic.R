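test_that("scene rendering is bit-reproducible under a fixed seed", {
  cfg <- small_scene_cfg(96)
  a <- render_scene(cfg, seed = 7)
  b <- render_scene(cfg, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  c <- render_scene(cfg, seed = 8)
  expect_false(identical(a$image, c$image))
})

test_that("degenerate count configuration yields exactly one label", {
  cfg <- scene_config(image_size = 96, count_mean = 1, count_range = c(1, 1))
  s <- render_scene(cfg, seed = 3)
  expect_equal(nrow(s$boxes), 1)
  expect_equal(s$meta$count, 1)
})

test_that("labels equal the tight bounding box of each rasterized ellipse", {
  cfg <- small_scene_cfg(128)
  s <- render_scene(cfg, seed = 11)
  S <- 128
  px <- yolo_to_corner(s$boxes, S, S)
  for (i in seq_along(s$meta$ellipses)) {
    e <- s$meta$ellipses[[i]]
    # independent rasterization: pixel centres inside the ellipse equation
    xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)
    ys <- matrix(rep(seq_len(S) - 0.5, S), S, S)
    u <- ((xs - e$cx) * cos(e$theta) + (ys - e$cy) * sin(e$theta)) / e$a
    v <- (-(xs - e$cx) * sin(e$theta) + (ys - e$cy) * cos(e$theta)) / e$b
    lit <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
    expect_equal(unname(px[i, ]),
                 c(min(lit[, 2]) - 1, min(lit[, 1]) - 1,
                   max(lit[, 2]), max(lit[, 1])))
  }
})

test_that("achieved animal counts track the configured mean", {
  cfg <- scene_config(image_size = 64, size_range = c(0.05, 0.08))
  counts <- vapply(1:200, function(i) {
    suppressWarnings(nrow(render_scene(cfg, seed = 1000 + i)$boxes))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 15), 1)
  expect_true(all(counts >= 5 & counts <= 25))
})

test_that("dataset generation writes images, labels and a faithful manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_scene_cfg(64)
  man <- generate_dataset(cfg, n_train = 6, n_test = 2, dir, seed = 5)
  expect_length(man$train, 6)
  expect_length(man$test, 2)
  stems <- c(unlist(man$train), unlist(man$test))
  expect_equal(anyDuplicated(stems), 0)
  expect_true(all(file.exists(file.path(dir, "images", paste0(stems, ".png")))))
  expect_true(all(file.exists(file.path(dir, "labels", paste0(stems, ".txt")))))
  man2 <- read_manifest(dir)
  expect_equal(unlist(man2$train), unlist(man$train))
  # refuses to clobber without force
  expect_error(generate_dataset(cfg, 1, 1, dir, seed = 5), "force")
})

test_that("train/test split ratio matches the emulated farm split", {
  # 86 / 14 mirrors a 6955 / 1115 split to within rounding
  expect_equal(round(100 * 6955 / 8070), 86)
  expect_equal(86 / (86 + 14), 6955 / 8070, tolerance = 0.01)
})

test_that("anchor clustering recovers box size structure", {
  # degenerate: all boxes identical -> every anchor at that size
  wh <- matrix(rep(c(20, 10), each = 30), ncol = 2)
  a <- kmeans_anchors(wh, k = 3, scales = 3, seed = 1)
  expect_true(all(abs(a[, 1] - 20) < 1e-9))
  expect_true(all(abs(a[, 2] - 10) < 1e-9))

  # two well-separated size clusters: centers inside each cluster's hull
  set.seed(2)
  small <- cbind(runif(40, 8, 12), runif(40, 8, 12))
  large <- cbind(runif(40, 40, 50), runif(40, 40, 50))
  a2 <- kmeans_anchors(rbind(small, large), k = 2, scales = 1, seed = 3)
  expect_true(all(a2[1, ] >= 8) && all(a2[1, ] <= 12))
  expect_true(all(a2[2, ] >= 40) && all(a2[2, ] <= 50))

  # sorted by area
  set.seed(4)
  wh3 <- cbind(runif(60, 5, 60), runif(60, 5, 60))
  a3 <- kmeans_anchors(wh3, k = 3, scales = 3, seed = 5)
  expect_true(all(diff(a3[, 1] * a3[, 2]) >= 0))
  expect_error(kmeans_anchors(wh3[1:5, ], k = 3, scales = 3), "at least")
})

test_that("the perfect oracle detector closes the loop through the metrics", {
  cfg <- small_scene_cfg(96)
  samples <- lapply(1:10, function(i) render_scene(cfg, seed = 100 + i))
  dets <- oracle_detector(samples, image_size = 96)
  gts <- do.call(rbind, lapply(samples, function(s) {
    g <- as.data.frame(yolo_to_corner(s$boxes, 96, 96))
    names(g) <- c("x1", "y1", "x2", "y2")
    g$class_id <- 0L; g$image <- s$id
    g
  }))
  rep <- evaluate_detections(dets, gts)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$map, 1)
  expect_equal(rep$counting_accuracy, 100)
})

test_that("injected drop rate shows up as the expected recall deficit", {
  cfg <- small_scene_cfg(96)
  samples <- lapply(1:25, function(i) render_scene(cfg, seed = 300 + i))
  n_obj <- sum(vapply(samples, function(s) nrow(s$boxes), numeric(1)))
  dets <- oracle_detector(samples, image_size = 96, drop_rate = 0.3, seed = 4)
  gts <- do.call(rbind, lapply(samples, function(s) {
    g <- as.data.frame(yolo_to_corner(s$boxes, 96, 96))
    names(g) <- c("x1", "y1", "x2", "y2")
    g$class_id <- 0L; g$image <- s$id
    g
  }))
  rep <- evaluate_detections(dets, gts)
  se <- sqrt(0.3 * 0.7 / n_obj)
  expect_lt(abs(rep$recall - 0.7), 3 * se)
  expect_equal(rep$precision, 1)  # no spurious boxes injected
})
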