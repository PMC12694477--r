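test_that("variant specs resolve the reference stage channels", {
  b3 <- variant_spec("B3")
  expect_equal(unname(b3$stage_channels), c(32, 48, 136, 384))
  expect_equal(unname(variant_spec("B5")$stage_channels), c(40, 64, 176, 512))
  expect_equal(unname(variant_spec("B7")$stage_channels), c(48, 80, 224, 640))
  expect_error(variant_spec("B9"), "unknown")
})

test_that("compound scaling constraint and rounding rules hold", {
  sc <- scaling_config(phi = 1)
  expect_true(sc$alpha * sc$beta_w^2 * sc$gamma^2 >= 1.9)
  expect_error(scaling_config(alpha = 2.5), "must lie")
  expect_equal(round_filters(320, 1.2), 384L)
  expect_equal(round_filters(112, 1.2), 136L)  # 90% floor pushes up a notch
  expect_equal(round_repeats(4, 3.1), 13L)
})

test_that("builder validates stage selection", {
  expect_error(build_backbone("tiny", out_indices = integer(0)), "non-empty")
  expect_error(build_backbone("tiny", out_indices = c(1, 3)), "subset")
})

test_that("stride-1 equal-channel block with zero projection is the identity", {
  spec <- mbconv_spec(t = 6, k = 3, s = 1, in_channels = 8, out_channels = 8)
  set.seed(1)
  init <- mbconv_init(spec)
  init$P[["blk.proj.w"]][] <- 0
  x <- array(rnorm(8 * 6 * 6), c(8, 6, 6))
  out <- mbconv_block(x, spec, init)
  expect_equal(max(abs(out - x)), 0)
})

test_that("stride-2 blocks halve spatial dims with ceil rounding", {
  spec <- mbconv_spec(t = 6, k = 5, s = 2, in_channels = 8, out_channels = 12)
  set.seed(2)
  out <- mbconv_block(array(rnorm(8 * 7 * 9), c(8, 7, 9)), spec)
  expect_equal(dim(out), c(12, 4, 5))
  expect_error(mbconv_block(array(0, c(4, 6, 6)), spec), "channels")
})

test_that("squeeze-excitation gate matches a brute-force loop and is bounded", {
  set.seed(3)
  F <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  params <- list(fc1_w = matrix(rnorm(2), 1, 2), fc1_b = 0.1,
                 fc2_w = matrix(rnorm(2), 2, 1), fc2_b = c(-0.2, 0.3))
  got <- se_gate(F, r = 2, params = params)
  # direct elementwise computation
  z <- c(mean(F[1, , ]), mean(F[2, , ]))
  hid <- max(sum(params$fc1_w * z) + params$fc1_b, 0)
  gate <- 1 / (1 + exp(-(params$fc2_w * hid + params$fc2_b)))
  for (c in 1:2) for (i in 1:2) for (j in 1:2)
    expect_equal(got$out[c, i, j], F[c, i, j] * gate[c], tolerance = 1e-12)
  expect_true(all(got$gate > 0 & got$gate < 1))
  # constant channel input pools to that constant
  Fc <- array(rep(c(2, -1), 4), c(2, 2, 2))
  expect_equal(se_gate(Fc, 2)$pooled, c(2, -1))
  # zero FC weights give a gate of exactly one half
  zp <- list(fc1_w = matrix(0, 1, 2), fc1_b = 0, fc2_w = matrix(0, 2, 1),
             fc2_b = c(0, 0))
  expect_equal(se_gate(F, 2, zp)$gate, c(0.5, 0.5))
})

test_that("stage feature shapes follow ceil-mode stride arithmetic", {
  for (L in c(256L, 512L, 800L)) {
    s <- stage_sides(L)
    expect_equal(unname(s), as.integer(ceiling(L / c(4, 8, 16, 32))))
  }
  expect_equal(unname(stage_sides(512L)), c(128L, 64L, 32L, 16L))
  expect_equal(unname(stage_sides(1024L)), 2L * unname(stage_sides(512L)))
  m <- fixture("bb_tiny", function() build_backbone("tiny", out_indices = 2:5, seed = 3))
  fs <- extract_features(m, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(dim(fs[["2"]])[2:3], c(16, 16))
  expect_equal(dim(fs[["3"]])[2:3], c(8, 8))
  expect_equal(dim(fs[["5"]])[2:3], c(2, 2))
  expect_equal(attr(fs[["4"]], "stride"), 16L)
})

test_that("truncated parameter counts are exact, monotone and registry-consistent", {
  counts <- vapply(c("B3", "B5", "B7"), backbone_param_count, numeric(1))
  expect_true(counts["B3"] < counts["B5"] && counts["B5"] < counts["B7"])
  m3 <- fixture("bb_B3", function() build_backbone("B3", seed = 1))
  expect_equal(soystage:::param_count_prefix(m3$ps, "backbone."), counts[["B3"]])
  expect_true(backbone_param_count("tiny") < counts[["B3"]])
})

test_that("random-weight forward passes are finite for all variants", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  for (v in c("B3", "B5", "B7")) {
    m <- fixture(paste0("bb_", v), function() build_backbone(v, seed = 1))
    fs <- extract_features(m, img)
    expect_true(all(vapply(fs, function(f) all(is.finite(f)), logical(1))),
                info = v)
  }
})

test_that("checkpoint loading reports missing and unexpected entries", {
  m <- fixture("bb_tiny", function() build_backbone("tiny", out_indices = 2:5, seed = 3))
  w <- m$ps$arr[1:3]
  w$extra_tensor <- matrix(0, 2, 2)
  expect_warning(m2 <- load_backbone_weights(m, w), "missing")
  rep <- attr(m2, "report")
  expect_equal(sort(rep$loaded), sort(names(m$ps$arr)[1:3]))
  expect_true("extra_tensor" %in% rep$unexpected)
  bad <- list(`backbone.stem.w` = matrix(0, 1, 1))
  expect_error(load_backbone_weights(m, bad), "mismatch")
})
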