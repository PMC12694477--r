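test_that("split arithmetic follows the floor-then-remainder rule", {
  expect_equal(unname(split_counts(17204)), c(13763, 1720, 1721))
  expect_equal(unname(split_counts(100)), c(80, 10, 10))
  expect_equal(unname(split_counts(10)), c(8, 1, 1))
  set.seed(1)
  for (n in sample(1:5000, 25)) expect_equal(sum(split_counts(n)), n)
  expect_error(split_counts(10, c(0.5, 0.2, 0.2)))
})

test_that("stage sampling follows the reference distribution", {
  counts <- stage_class_counts()
  expect_equal(sum(counts), 17204)
  p_v1 <- counts[["V1"]] / sum(counts)
  expect_equal(p_v1, 0.15095, tolerance = 1e-4)
  set.seed(2)
  draws <- sample_stage(1e5)
  emp <- tabulate(draws + 1L, 9) / 1e5
  th <- counts / sum(counts)
  sigma <- sqrt(th * (1 - th) / 1e5)
  expect_true(all(abs(emp - th) < 3 * sigma + 1e-4))
  # chi-squared fidelity at alpha = 0.01 for n >= 5000
  set.seed(3)
  d2 <- sample_stage(5000)
  pval <- suppressWarnings(chisq.test(tabulate(d2 + 1L, 9), p = th)$p.value)
  expect_gt(pval, 0.01)
  # degenerate one-class distribution
  expect_true(all(sample_stage(50, c(0, 0, 1, 0, 0, 0, 0, 0, 0)) == 2L))
})

test_that("scene rendering is deterministic and annotations are valid", {
  spec <- scene_spec(side = 128)
  a <- withr::with_seed(7, render_scene(4L, spec))
  b <- withr::with_seed(7, render_scene(4L, spec))
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  expect_equal(a$labels, 4L)
  expect_true(all(a$image >= 0 & a$image <= 1))
  bx <- a$boxes[1, ]
  expect_true(bx[1] >= 0 && bx[2] >= 0 && bx[1] + bx[3] <= 128 &&
                bx[2] + bx[4] <= 128 && bx[3] > 0 && bx[4] > 0)
})

test_that("generated datasets are byte-reproducible with valid COCO structure", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(9, dir = d1, spec = scene_spec(side = 64), seed = 11)
  generate_dataset(9, dir = d2, spec = scene_spec(side = 64), seed = 11)
  f1 <- list.files(file.path(d1, "images"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "images"), full.names = TRUE)
  expect_equal(length(f1), 9L)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  coco <- read_coco(file.path(d1, "annotations", "instances_train.json"))
  expect_equal(nrow(coco$images), 7L)         # floor(0.9*... ) of 9 -> 7/0/2? no: 7,0,2
  expect_true(all(c("id", "image_id", "category_id", "x", "y", "w", "h") %in%
                    names(coco$annotations)))
  expect_equal(coco$categories$id, 0:8)
  expect_equal(coco$categories$name[1], "VE")
  ann <- coco$annotations
  expect_true(all(ann$category_id >= 0 & ann$category_id <= 8))
  expect_true(all(ann$w > 0 & ann$h > 0))
  expect_true(all(ann$x >= 0 & ann$y >= 0 & ann$x + ann$w <= 64 &
                    ann$y + ann$h <= 64))
})

test_that("object area grows with the phenological ordinal", {
  set.seed(13)
  spec <- scene_spec(side = 128, small_fraction = 0)
  stages <- sample_stage(300)
  areas <- numeric(0); labs <- integer(0)
  for (i in seq_along(stages)) {
    sc <- render_scene(stages[i], spec)
    if (nrow(sc$boxes)) {
      areas <- c(areas, sc$boxes[1, 3] * sc$boxes[1, 4])
      labs <- c(labs, sc$labels[1])
    }
  }
  rho <- cor(labs, areas, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("stage-conditional size contracts hold at the working resolution", {
  set.seed(14)
  spec <- scene_spec(side = 512, small_fraction = 0)
  r8 <- replicate(30, { s <- render_scene(8L, spec); s$boxes[1, 3] * s$boxes[1, 4] })
  expect_gte(mean(r8 >= 9216), 0.9)
  ve <- replicate(30, { s <- render_scene(0L, spec); s$boxes[1, 3] * s$boxes[1, 4] })
  expect_gte(mean(classify_scale(ve) == "medium"), 0.7)
  # the configured small fraction exercises the sub-1024 bucket
  set.seed(15)
  sm <- replicate(200, {
    s <- render_scene(2L, scene_spec(side = 512, small_fraction = 0.5))
    s$boxes[1, 3] * s$boxes[1, 4]
  })
  expect_gt(mean(sm < 1024), 0.1)
})

test_that("too few images for the class set warns", {
  expect_warning(generate_dataset(4, dir = NULL, seed = 1), "fewer images")
})
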