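test_that("YOLO-TXT labels round-trip through write and read", {
  recs <- data.frame(class_id = c(0L, 0L, 1L),
                     cx = c(0.5, 0.25, 0.8), cy = c(0.5, 0.75, 0.1),
                     w = c(0.2, 0.1, 0.05), h = c(0.3, 0.2, 0.05))
  path <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(recs, path)
  back <- read_yolo_labels(path)
  expect_equal(back$class_id, recs$class_id)
  expect_equal(back$cx, recs$cx, tolerance = 1e-6)
  expect_equal(back$h, recs$h, tolerance = 1e-6)
  # deterministic byte output
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_yolo_labels(recs, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("label parsing validates lines and handles empty/detection files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), path)
  expect_equal(nrow(read_yolo_labels(path)), 0)

  writeLines(c("0 0.5 0.5 0.2 0.2", "0 0.1 bad 0.1 0.1"), path)
  expect_error(read_yolo_labels(path), "line 2")
  writeLines(c("0 0.5 0.5 0.2"), path)
  expect_error(read_yolo_labels(path), "line 1")

  # 6-field detection interchange carries a confidence column
  writeLines("0 0.5 0.5 0.2 0.2 0.875000", path)
  d <- read_yolo_labels(path)
  expect_equal(d$conf, 0.875)

  expect_error(write_yolo_labels(
    data.frame(class_id = 0L, cx = 1.4, cy = 0.5, w = 0.2, h = 0.2), path),
    "0,1")
})

test_that("normalized/pixel conversions are mutually inverse", {
  recs <- data.frame(class_id = 0L, cx = 0.5, cy = 0.25, w = 0.2, h = 0.1)
  px <- yolo_to_corner(recs, 320, 160)
  expect_equal(unname(px[1, ]), c(128, 32, 192, 48))
  back <- corner_to_yolo(px, 320, 160)
  expect_equal(back$cx, recs$cx)
  expect_equal(back$h, recs$h)
})

test_that("letterboxing pads symmetrically and maps boxes exactly", {
  img <- array(runif(320 * 640 * 3), dim = c(320, 640, 3))
  boxes <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.25, h = 0.5)
  lb <- letterbox(img, boxes, target = 320)
  expect_equal(dim(lb$image), c(320, 320, 3))
  expect_equal(lb$info$scale, 0.5)
  expect_equal(lb$info$pad_y, 80)   # 320x160 content, 80 px top and bottom
  expect_equal(lb$info$pad_x, 0)
  # padding rows are the uniform gray fill
  expect_true(all(lb$image[1:80, , ] == 114 / 255))
  # the box center maps through scale + offset
  expect_equal(lb$boxes$cx, 0.5)
  expect_equal(lb$boxes$cy, (160 * 0.5 + 80) / 320)
  expect_equal(lb$boxes$w, 0.25 * 640 * 0.5 / 320)

  # square image: pure resize, no padding
  sq <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  lb2 <- letterbox(sq, boxes, target = 128)
  expect_equal(lb2$info$pad_x + lb2$info$pad_y, 0)

  # inverse mapping restores original coordinates
  inv <- letterbox_invert_boxes(lb$boxes, lb$info)
  expect_equal(inv$cx, boxes$cx, tolerance = 1e-9)
  expect_equal(inv$cy, boxes$cy, tolerance = 1e-9)
  expect_equal(inv$w, boxes$w, tolerance = 1e-9)
})

test_that("images survive a PNG write/read round trip", {
  img <- array(runif(20 * 30 * 3), dim = c(20, 30, 3))
  path <- withr::local_tempfile(fileext = ".png")
  save_image(img, path)
  back <- load_image(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)  # 8-bit quantization only
})

test_that("augmentation is seeded, boxed within the frame, and optional", {
  sc <- small_scene_cfg(96)
  smp <- render_scene(sc, seed = 5)
  cfg_off <- augment_config(hsv = FALSE, flip = FALSE, affine = FALSE)
  same <- augment(smp, cfg_off, seed = 1)
  expect_identical(same$image, smp$image)
  expect_equal(same$boxes, smp$boxes)

  cfg_on <- augment_config()
  a1 <- augment(smp, cfg_on, seed = 9)
  a2 <- augment(smp, cfg_on, seed = 9)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$boxes, a2$boxes)
  a3 <- augment(smp, cfg_on, seed = 10)
  expect_false(identical(a1$image, a3$image))

  if (nrow(a1$boxes) > 0) {
    expect_true(all(a1$boxes$cx - a1$boxes$w / 2 >= -1e-9))
    expect_true(all(a1$boxes$cx + a1$boxes$w / 2 <= 1 + 1e-9))
    expect_true(all(a1$boxes$w > 0))
  }
  # count preserved up to the recorded clipping drops
  expect_equal(nrow(a1$boxes) + attr(a1, "dropped"), nrow(smp$boxes))
})

test_that("horizontal flip mirrors centers and keeps sizes", {
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  smp <- list(image = img,
              boxes = data.frame(class_id = 0L, cx = 0.3, cy = 0.4,
                                 w = 0.2, h = 0.1),
              id = "t")
  cfg <- augment_config(hsv = FALSE, flip = TRUE, flip_prob = 1, affine = FALSE)
  fl <- augment(smp, cfg, seed = 1)
  expect_equal(fl$boxes$cx, 0.7, tolerance = 1e-9)
  expect_equal(fl$boxes$w, 0.2)
  expect_equal(fl$boxes$h, 0.1)
  expect_identical(fl$image[, 32:1, ], img)
})

test_that("mosaic composes four tiles with clipped, in-frame boxes", {
  sc <- small_scene_cfg(96)
  pool <- lapply(2:4, function(s) render_scene(sc, seed = s))
  smp <- render_scene(sc, seed = 1)
  cfg <- augment_config(hsv = FALSE, flip = FALSE, affine = FALSE, mosaic = TRUE)
  m1 <- augment(smp, cfg, seed = 3, pool = pool)
  m2 <- augment(smp, cfg, seed = 3, pool = pool)
  expect_identical(m1$image, m2$image)
  expect_gt(nrow(m1$boxes), 0)
  expect_true(all(m1$boxes$cx + m1$boxes$w / 2 <= 1 + 1e-9))
  expect_true(all(m1$boxes$cy + m1$boxes$h / 2 <= 1 + 1e-9))
})
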