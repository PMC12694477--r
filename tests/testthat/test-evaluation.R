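test_that("scale buckets use strict pixel-area boundaries", {
  expect_equal(classify_scale(c(0, 1023, 1024, 9215, 9216, 5e4)),
               c("small", "small", "medium", "medium", "large", "large"))
  expect_error(classify_scale(-1))
  # every area falls in exactly one bucket
  set.seed(1)
  a <- runif(500, 0, 2e4)
  expect_true(all(table(classify_scale(a)) >= 0))
  expect_equal(sum(table(factor(classify_scale(a),
                                levels = c("small", "medium", "large")))), 500)
})

test_that("protocol constants are fixed as specified", {
  p <- eval_protocol()
  expect_equal(p$confidence_threshold, 0.05)
  expect_equal(p$nms_threshold, 0.5)
  expect_equal(p$iou_thresholds, seq(0.5, 0.95, 0.05))
  expect_equal(p$max_dets, 100L)
})

test_that("greedy NMS suppresses overlapping same-class boxes", {
  b <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11), c(20, 20, 30, 30))
  keep <- nms(b, c(0.9, 0.8, 0.7), 0.5)
  expect_equal(sort(keep), c(1, 3))
  expect_equal(nms(b[1, , drop = FALSE], 0.5), 1L)
})

test_that("perfect and empty detectors give the protocol extremes", {
  gts <- data.frame(image_id = c(1, 1, 2), category_id = c(0, 1, 0),
                    x = c(10, 60, 30), y = c(10, 60, 30),
                    w = c(40, 30, 50), h = c(40, 30, 50))
  perfect <- cbind(gts, score = 1.0)
  r <- coco_ap(perfect, gts)
  expect_equal(r$AP, 100)
  expect_equal(r$AP50, 100)
  empty <- perfect[0, ]
  r0 <- coco_ap(empty, gts)
  expect_equal(r0$AP, 0)
  expect_equal(r0$n_det, 0L)
})

test_that("AP agrees with an independent protocol implementation", {
  worst <- 0
  for (seed in 1:50) {
    inst <- random_instance(seed)
    pkg <- coco_ap(inst$dets, inst$gts)$AP
    ora <- oracle_coco_ap(inst$dets, inst$gts)
    worst <- max(worst, abs(pkg - ora))
  }
  expect_lt(worst, 1e-6)
})

test_that("AP is monotone in IoU threshold and under box improvement", {
  set.seed(33)
  for (seed in c(3, 11, 27)) {
    inst <- random_instance(seed)
    r <- coco_ap(inst$dets, inst$gts)
    ap95 <- coco_ap(inst$dets, inst$gts,
                    eval_protocol(iou_thresholds = seq(0.5, 0.95, 0.05)))
    expect_gte(r$AP50 + 1e-9, r$AP75)
    # snapping every detection onto a ground-truth box never lowers AP
    snapped <- inst$dets
    for (i in seq_len(nrow(snapped))) {
      g <- inst$gts[inst$gts$image_id == snapped$image_id[i] &
                      inst$gts$category_id == snapped$category_id[i], , drop = FALSE]
      if (!nrow(g)) next
      iou <- iou_matrix(box_xywh_to_xyxy(as.matrix(snapped[i, c("x", "y", "w", "h")])),
                        box_xywh_to_xyxy(as.matrix(g[, c("x", "y", "w", "h")])))
      j <- which.max(iou[1, ])
      snapped[i, c("x", "y", "w", "h")] <- g[j, c("x", "y", "w", "h")]
    }
    expect_gte(coco_ap(snapped, inst$gts)$AP + 1e-9, r$AP)
  }
})

test_that("classes without ground truth are excluded from the mean", {
  gts <- data.frame(image_id = 1, category_id = 0, x = 10, y = 10, w = 40, h = 40)
  dets <- data.frame(image_id = 1, category_id = c(0, 5), score = c(0.9, 0.8),
                     x = c(10, 100), y = c(10, 100), w = c(40, 20), h = c(40, 20))
  r <- coco_ap(dets, gts)
  expect_equal(r$AP, 100)   # the stray class-5 detection has no GT pool
})

test_that("end-to-end evaluation is deterministic and respects thresholds", {
  m <- smoke_model()
  ds <- smoke_dataset()
  pro <- eval_protocol(input_side = 64)
  r1 <- evaluate_model(m, ds, pro, split = "val")
  r2 <- evaluate_model(m, ds, pro, split = "val")
  expect_identical(r1$AP, r2$AP)
  expect_identical(attr(r1, "skipped"), 0L)
  # raising the confidence threshold can only reduce scored detections
  img <- ds$samples[[1]]$image
  d_lo <- predict(m, img, protocol = eval_protocol(input_side = 64,
                                                  confidence_threshold = 0.05))
  d_hi <- predict(m, img, protocol = eval_protocol(input_side = 64,
                                                  confidence_threshold = 0.3))
  expect_lte(nrow(d_hi), nrow(d_lo))
})
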