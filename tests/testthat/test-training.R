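test_that("quality focal loss reproduces direct arithmetic", {
  expect_equal(quality_focal_loss(0.5, 1), 0.25 * (-log(0.5)), tolerance = 1e-9)
  expect_equal(quality_focal_loss(0.5, 1), 0.173287, tolerance = 1e-5)
  # the printed self-entropy form coincides at sigma = 0.5
  expect_equal(quality_focal_loss(0.5, 1, loss_config(qfl_form = "as_printed")),
               0.25 * 0.693147, tolerance = 1e-5)
  expect_equal(quality_focal_loss(0.7, 0.7), 0)
  set.seed(1)
  s <- runif(200, 1e-3, 1 - 1e-3); y <- runif(200)
  expect_true(all(quality_focal_loss(s, y) >= 0))
  # extreme scores are clipped rather than infinite
  expect_true(is.finite(quality_focal_loss(1, 0)))
  expect_true(is.finite(quality_focal_loss(0, 1)))
})

test_that("box loss reproduces the enclosing-box worked example", {
  expect_equal(box_loss(c(0.5, 0.5, 1, 1), c(10.5, 10.5, 1, 1)),
               103.966942, tolerance = 1e-6)
  # decomposition: L1 = 20, GIoU = -(121 - 2)/121
  g <- giou_pairwise(box_cxcywh_to_xyxy(c(0.5, 0.5, 1, 1)),
                     box_cxcywh_to_xyxy(c(10.5, 10.5, 1, 1)))
  expect_equal(g, -(121 - 2) / 121, tolerance = 1e-9)
  expect_equal(box_loss(c(0.3, 0.4, 0.2, 0.1), c(0.3, 0.4, 0.2, 0.1)), 0)
  # GIoU term bounded by its range
  set.seed(2)
  for (i in 1:50) {
    a <- c(runif(2), runif(2, 0.05, 0.5)); b <- c(runif(2), runif(2, 0.05, 0.5))
    term <- box_loss(a, b) - 5 * sum(abs(a - b))
    expect_gte(term, 0); expect_lte(term, 4 + 1e-9)
  }
})

test_that("adaptive noise scales derive from class frequencies", {
  a <- noise_scale(stage_class_counts())
  expect_equal(unname(a["VE"]), 1.419423, tolerance = 1e-6)
  expect_equal(unname(a["V1"]), 0.818373, tolerance = 1e-6)
  expect_equal(unname(a["R6-R7"]), 0.5)
  expect_true(all(a >= 0.5 & a < 1.5))
  # strictly decreasing in count
  ord <- order(stage_class_counts())
  expect_true(all(diff(a[ord]) < 0))
  expect_error(noise_scale(numeric(0)), "empty")
})

test_that("label perturbations stay within the adjacency window and clamp", {
  set.seed(3)
  d <- perturb_label(rep(4L, 1e5), 0.5) - 4L
  expect_true(all(d %in% -1:1))
  tab <- table(factor(d, levels = -1:1))
  expect_true(all(abs(tab - 1e5 / 3) < 3 * sqrt(1e5 * (1 / 3) * (2 / 3))))
  # wider window for rare classes, clamped at the scale ends
  dv <- perturb_label(rep(0L, 1e5), 1.419423)
  expect_true(all(dv >= 0 & dv <= 8))
  expect_true(all(dv <= 2))        # |shift| <= floor(2 * 1.419) = 2 before clamping
  d8 <- perturb_label(rep(8L, 1e4), 1.419423)
  expect_true(all(d8 >= 6 & d8 <= 8))
})

test_that("box perturbations respect the uniform support bound", {
  b <- c(0.5, 0.5, 0.3, 0.3)
  expect_equal(perturb_box(b, 0.9, eta = 0)[1, ], b)
  set.seed(4)
  big <- perturb_box(matrix(rep(b, each = 1e4), 1e4, 4, byrow = FALSE), 0.3, 1)
  dev <- abs(sweep(big, 2, b))
  expect_true(all(dev <= 0.3 + 1e-12))
  expect_gt(max(dev), 0.28)        # support is actually reached
})

test_that("denoising batches bind noisy copies to their sources under a block mask", {
  gts <- list(list(labels = c(0L, 7L),
                   boxes = rbind(c(0.3, 0.3, 0.2, 0.2), c(0.6, 0.6, 0.4, 0.4))),
              list(labels = 5L, boxes = rbind(c(0.5, 0.5, 0.3, 0.3))))
  set.seed(5)
  dn <- build_denoising_batch(gts, denoise_config(num_groups = 3), num_queries = 10)
  expect_equal(dn$n_dn, 6L)                       # 2 GTs x 3 groups per image
  expect_equal(length(dn$labels), 12L)
  expect_true(all(dn$labels >= 0 & dn$labels <= 8))
  M <- 16L
  # matching queries may never attend denoising keys, and vice versa
  expect_true(all(dn$mask[seq_len(6), 7:M]))
  expect_true(all(dn$mask[7:M, seq_len(6)]))
  expect_false(any(dn$mask[7:M, 7:M]))
  # groups are mutually isolated
  expect_true(all(dn$mask[3:4, 1:2]))
  expect_false(any(dn$mask[1:2, 1:2]))
  # queries stay attached to their image
  expect_equal(dn$image, rep(1:2, each = 6))
  # empty scene yields an empty batch
  e <- build_denoising_batch(list(list(labels = integer(0),
                                       boxes = matrix(0, 0, 4))))
  expect_equal(e$n_dn, 0L)
})

test_that("rare classes receive larger mean box perturbation than common ones", {
  a <- noise_scale(stage_class_counts())
  set.seed(6)
  b <- c(0.5, 0.5, 0.3, 0.3)
  rare <- replicate(1e4, mean(abs(perturb_box(b, a[["VE"]]) - b)))
  comm <- replicate(1e4, mean(abs(perturb_box(b, a[["R6-R7"]]) - b)))
  expect_gt(mean(rare), mean(comm))
})

test_that("the assignment solver matches exhaustive enumeration", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(1:3, 1); m <- sample(n:4, 1)
    cost <- matrix(rnorm(n * m), n, m)
    h <- hungarian(cost)
    bf <- brute_force_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), h)]), bf$cost, tolerance = 1e-12)
  }
})

test_that("detection matching is one-to-one and permutation invariant", {
  set.seed(8)
  probs <- matrix(runif(4 * 9, 0.01, 0.99), 4, 9)
  boxes <- cbind(runif(4, 0.2, 0.8), runif(4, 0.2, 0.8), 0.2, 0.2)
  gl <- c(1L, 4L)
  gb <- rbind(c(0.3, 0.3, 0.2, 0.2), c(0.7, 0.7, 0.2, 0.2))
  mt <- match_detections(probs, boxes, gl, gb)
  expect_equal(nrow(mt), 2L)
  expect_equal(anyDuplicated(mt$det), 0L)
  expect_equal(nrow(match_detections(probs[1, , drop = FALSE],
                                     boxes[1, , drop = FALSE], 0L,
                                     matrix(c(0.5, 0.5, 0.2, 0.2), 1))), 1L)
  # permuting detections leaves the matched total cost unchanged
  perm <- c(3, 1, 4, 2)
  mt2 <- match_detections(probs[perm, ], boxes[perm, ], gl, gb)
  expect_setequal(perm[mt2$det], mt$det)
})

test_that("learning-rate schedule implements warmup, decay and group multipliers", {
  sc <- schedule_config()
  expect_equal(lr_at(0, 1, sc), 2e-7)
  expect_equal(lr_at(500, 1, sc), 2e-4 * (0.001 + 0.999 * 0.5))
  expect_equal(lr_at(5000, 35, sc), 2e-5)
  expect_equal(lr_at(5000, 45, sc), 2e-6)
  expect_equal(lr_at(5000, 10, sc, "backbone"), 2e-5)
  expect_error(schedule_config(decay_epochs = c(30, 60)), "decay")
})

test_that("gradient clipping bounds the applied global norm", {
  ps <- soystage:::param_store()
  ps$arr <- list(a.w = matrix(0, 2, 2), b.w = matrix(0, 2, 2))
  leaves <- lapply(ps$arr, function(x) {
    nd <- new.env(); nd$value <- x; nd$grad <- matrix(10, 2, 2)
    class(nd) <- "adnode"; nd
  })
  opt <- soystage:::adamw_new(names(ps$arr))
  sc <- schedule_config()
  gn <- soystage:::adamw_step(ps, leaves, opt, lr = 1e-3, sc)
  expect_equal(gn, sqrt(8 * 100))
  applied <- sqrt(sum(unlist(opt$m)^2)) / 0.1     # m = 0.1 * clipped grad
  expect_lte(applied, sc$grad_clip_norm + 1e-9)
})

test_that("augmentation mirrors, rescales and drops boxes coherently", {
  set.seed(9)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  box <- matrix(c(10, 5, 20, 12), 1)
  # deterministic flip arithmetic on a width-512 canvas
  img512 <- array(0.5, c(16, 512, 3))
  flipped <- withr::with_seed(1, {
    repeat {
      a <- augment_sample(img512, matrix(c(10, 2, 20, 8), 1),
                          flip = TRUE, scale = FALSE, photometric = FALSE)
      if (a$image[1, 1, 1] == 0.5 && a$boxes[1, 1] != 10) break
      a <- NULL
    }
    a
  })
  expect_equal(flipped$boxes[1, 1], 512 - 30)
  # flipping twice restores boxes exactly
  b0 <- matrix(c(3, 4, 10, 9), 1)
  once <- 32 - b0[1] - b0[3]
  twice <- 32 - once - b0[3]
  expect_equal(twice, b0[1])
  # photometric-only pipeline leaves annotations bit-identical
  p <- augment_sample(img, box, flip = FALSE, scale = FALSE, photometric = TRUE)
  expect_identical(p$boxes, box)
  expect_true(all(p$image >= 0 & p$image <= 1))
  # scale keeps boxes inside the image and drops degenerate ones
  s <- augment_sample(img, matrix(c(0, 0, 0.5, 20), 1), flip = FALSE,
                      scale = TRUE, photometric = FALSE)
  expect_true(s$dropped == 1 || all(s$boxes[, 3:4] >= 1))
})
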