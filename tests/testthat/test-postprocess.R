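test_that("NMS suppresses duplicates greedily and keeps disjoint boxes", {
  d <- data.frame(x1 = c(0, 0), y1 = c(0, 0), x2 = c(10, 10), y2 = c(10, 10),
                  conf = c(0.9, 0.8), class_id = 0L)
  kept <- nms(d, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$conf, 0.9)

  d2 <- data.frame(x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60), y2 = c(10, 60),
                   conf = c(0.9, 0.8), class_id = 0L)
  expect_equal(nrow(nms(d2, 0.5)), 2)

  # suppression chain: b2 overlaps b1 (0.6), b3 overlaps b2 (0.6) but b1 only 1/3
  d3 <- data.frame(x1 = c(0, 2.5, 5), y1 = 0, x2 = c(10, 12.5, 15), y2 = 10,
                   conf = c(0.9, 0.8, 0.7), class_id = 0L)
  kept3 <- nms(d3, 0.5)
  expect_equal(kept3$conf, c(0.9, 0.7))
})

test_that("NMS equals the brute-force greedy oracle and is order independent", {
  set.seed(10)
  for (rep in 1:40) {
    d <- random_detections(sample(0:20, 1))
    if (nrow(d) == 0) next
    th <- runif(1, 0.2, 0.7)
    kept <- nms(d, th)
    oracle_idx <- nms_oracle(d, th)
    got_idx <- sort(match(
      do.call(paste, c(kept[c("x1", "y1", "x2", "y2", "conf")], sep = "_")),
      do.call(paste, c(d[c("x1", "y1", "x2", "y2", "conf")], sep = "_"))))
    expect_equal(got_idx, oracle_idx)
    # no kept pair overlaps above the threshold
    if (nrow(kept) > 1) {
      m <- iou_matrix(as.matrix(kept[, 1:4]), as.matrix(kept[, 1:4]))
      diag(m) <- 0
      expect_lte(max(m), th)
    }
    # permuting the input changes nothing
    perm <- sample(nrow(d))
    kept_p <- nms(d[perm, ], th)
    expect_equal(sort(kept_p$conf), sort(kept$conf))
  }
})

test_that("counting from detections applies the confidence threshold", {
  expect_equal(count_detections(detections_empty()), 0L)
  d <- random_detections(15); d$conf <- seq(0.5, 0.99, length.out = 15)
  expect_equal(count_detections(d, 0.25), 15)
  expect_equal(count_detections(d, 1 + 1e-9), 0)
})

test_that("counting accuracy handles the relative and exact modes", {
  expect_equal(counting_accuracy(c(10, 12), c(10, 12)), 100)
  expect_equal(counting_accuracy(c(15, 14), c(15, 16)), 93.75)
  expect_equal(counting_accuracy(c(0, 0), c(10, 12)), 0)
  expect_equal(counting_accuracy(c(15, 14), c(15, 16), mode = "exact"), 50)
  expect_error(counting_accuracy(c(1, 2), c(1, 2, 3)), "length")
  expect_error(counting_accuracy(0, 0), "positive")
})

test_that("matching follows the single-match greedy rule at the IoU threshold", {
  gt <- matrix(c(0, 0, 10, 10), 1, 4)
  d_hit <- data.frame(x1 = 1, y1 = 0, x2 = 11, y2 = 10, conf = 0.9, class_id = 0L)
  m <- match_detections(d_hit, gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  d_low <- data.frame(x1 = 7, y1 = 7, x2 = 17, y2 = 17, conf = 0.9, class_id = 0L)
  m <- match_detections(d_low, gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))

  # two detections on one ground truth: second one is a false positive
  d_two <- data.frame(x1 = c(0, 1), y1 = 0, x2 = c(10, 11), y2 = 10,
                      conf = c(0.9, 0.8), class_id = 0L)
  m <- match_detections(d_two, gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
})

test_that("match counts are conserved on random instances", {
  set.seed(12)
  for (rep in 1:30) {
    gts <- as.matrix(random_detections(sample(0:8, 1))[, 1:4])
    d <- random_detections(sample(0:12, 1))
    m <- match_detections(d, gts, 0.5)
    expect_equal(m$tp + m$fn, nrow(gts))
    expect_equal(m$tp + m$fp, nrow(d))
  }
})

test_that("precision/recall/F1 match their defining formulas and conventions", {
  p <- precision_recall_f1(list(tp = 8, fp = 2, fn = 2))
  expect_equal(unname(p), c(0.8, 0.8, 0.8))
  expect_equal(unname(precision_recall_f1(list(tp = 0, fp = 0, fn = 5))),
               c(0, 0, 0))
  # harmonic mean reproduces a reported F1 from its own P and R
  f1 <- 2 * 0.927 * 0.881 / (0.927 + 0.881)
  expect_equal(round(f1, 2), 0.90)
})

test_that("average precision integrates the monotone envelope", {
  expect_equal(average_precision(TRUE, 1), 1)
  expect_equal(average_precision(logical(0), 2), 0)
  # ranked TP, FP, TP over 2 ground truths
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_error(average_precision(TRUE, 0), "undefined")
})

test_that("average precision equals the threshold-enumeration oracle", {
  set.seed(13)
  for (rep in 1:60) {
    n <- sample(1:20, 1)
    n_gt <- sample(1:10, 1)
    tp <- runif(n) < 0.5
    if (sum(tp) > n_gt) tp[which(tp)[-seq_len(n_gt)]] <- FALSE
    conf <- round(runif(n), 2)  # deliberate ties
    ord <- order(-conf)
    expect_lt(abs(average_precision(tp[ord], n_gt, conf = conf[ord]) -
                  ap_oracle(conf, tp, n_gt)), 1e-9)
  }
})

test_that("101-point AP approximates the all-points integral", {
  set.seed(14)
  tp <- runif(30) < 0.6
  ap_all <- average_precision(tp, 20)
  ap_101 <- average_precision(tp, 20, mode = "101_point")
  expect_lt(abs(ap_all - ap_101), 0.05)
})

test_that("mAP averages class APs", {
  expect_equal(mean_ap(0.7), 0.7)
  expect_equal(mean_ap(c(0.8, 0.6)), 0.7)
  expect_equal(mean_ap(c(0.6, 0.8)), mean_ap(c(0.8, 0.6)))
  expect_error(mean_ap(numeric(0)))
})

test_that("relative improvement reproduces report arithmetic", {
  expect_equal(relative_improvement(95.6, 69.8), 36.96)
  expect_equal(relative_improvement(88.1, 84.3), 4.51)
  expect_equal(relative_improvement(50, 50), 0)
  expect_error(relative_improvement(10, 0), "positive")
})

test_that("evaluation stack is exact for a perfect detector and empty sets", {
  set.seed(15)
  gts <- do.call(rbind, lapply(1:4, function(i) {
    g <- random_detections(sample(3:8, 1))
    g$image <- paste0("img", i)
    g
  }))
  perfect <- gts; perfect$conf <- runif(nrow(perfect), 0.5, 1)
  rep <- evaluate_detections(perfect, gts)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f1, 1)
  expect_equal(rep$map, 1)
  expect_equal(rep$counting_accuracy, 100)

  rep0 <- evaluate_detections(detections_empty() |> transform(image = character(0)), gts)
  expect_equal(rep0$precision, 0)
  expect_equal(rep0$recall, 0)
  expect_equal(rep0$map, 0)
})

test_that("comparison tables carry relative improvements over the baseline", {
  mk <- function(ca, p, r, f1, map) list(counting_accuracy = ca, precision = p,
                                         recall = r, f1 = f1, map = map)
  reports <- list(base = mk(86.2, 0.910, 0.843, 0.87, 0.910),
                  full = mk(95.6, 0.927, 0.881, 0.90, 0.938))
  tab <- comparison_table(reports, baseline = "base")
  expect_equal(tab$recall_gain[tab$model == "full"],
               relative_improvement(88.1, 84.3))
  expect_true(is.na(tab$recall_gain[tab$model == "base"]))
  expect_equal(tab$counting_accuracy_gain[tab$model == "full"], 10.90)
})
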