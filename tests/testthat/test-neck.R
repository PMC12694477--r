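test_that("mapping-conv parameter arithmetic is exact per variant", {
  b7 <- neck_config(c(`3` = 80, `4` = 224, `5` = 640))
  pc <- neck_param_count(b7)
  expect_identical(pc$mapping, (80 + 224 + 640) * 256)
  expect_identical(pc$mapping, 241664)
  b3 <- neck_config(c(`3` = 48, `4` = 136, `5` = 384))
  expect_identical(neck_param_count(b3)$mapping, 145408)
  # affine parameters: scale + shift per channel per normalized level
  expect_identical(pc$gn, 2L * 256L * 3L)
  expect_identical(pc$gn / 3L, 512)
  # registry agrees with the closed form
  nk <- build_neck(b7, seed = 1)
  expect_equal(soystage:::param_count_prefix(nk$ps, "neck."), pc$total)
})

test_that("channel mapping unifies channels and preserves spatial dims", {
  set.seed(4)
  feats <- list(`3` = array(rnorm(80 * 8 * 8), c(80, 8, 8)),
                `4` = array(rnorm(224 * 4 * 4), c(224, 4, 4)),
                `5` = array(rnorm(640 * 2 * 2), c(640, 2, 2)))
  nk <- build_neck(neck_config(c(`3` = 80, `4` = 224, `5` = 640)), seed = 2)
  pyr <- map_channels(feats, nk)
  expect_equal(vapply(pyr, function(p) dim(p)[1], numeric(1)),
               c(P3 = 256, P4 = 256, P5 = 256))
  expect_equal(dim(pyr$P3)[2:3], c(8, 8))
  feats_b3 <- list(`3` = array(rnorm(48 * 8 * 8), c(48, 8, 8)),
                   `4` = array(rnorm(136 * 4 * 4), c(136, 4, 4)),
                   `5` = array(rnorm(384 * 2 * 2), c(384, 2, 2)))
  nk3 <- build_neck(neck_config(c(`3` = 48, `4` = 136, `5` = 384)), seed = 2)
  expect_equal(length(map_channels(feats_b3, nk3)), 3L)
  expect_error(map_channels(feats_b3, nk), "mismatch")
})

test_that("group normalization matches two-pass moments and handles degenerate input", {
  cfg <- neck_config(c(`3` = 80, `4` = 224, `5` = 640))
  expect_identical(cfg$out_channels %/% cfg$num_groups, 8L)
  set.seed(5)
  F <- array(rnorm(16 * 3 * 3), c(16, 3, 3))
  out <- group_normalize(F, G = 4)
  # brute-force per-group moments
  for (g in 1:4) {
    vals <- out[((g - 1) * 4 + 1):(g * 4), , ]
    m <- sum(vals) / length(vals)
    v <- sum((vals - m)^2) / length(vals)
    expect_lt(abs(m), 1e-4)
    expect_lt(abs(v - 1), 1e-3)
  }
  # pre-affine moments against an independent two-pass computation
  raw <- F[1:4, , ]
  mu <- mean(raw); va <- mean((raw - mu)^2)
  manual <- (raw - mu) / sqrt(va + 1e-5)
  expect_equal(out[1:4, , ], manual, tolerance = 1e-5)
  # constant input collapses to the affine shift
  beta <- rnorm(16)
  outc <- group_normalize(array(7, c(16, 3, 3)), G = 4, beta = beta)
  for (c in 1:16) expect_equal(unname(outc[c, , ]), matrix(beta[c], 3, 3))
  expect_error(group_normalize(F, G = 5), "divisible")
})

test_that("pyramid extension halves the side with channel preservation", {
  nk <- fixture("neck32", function()
    build_neck(neck_config(c(`3` = 32, `4` = 32, `5` = 32), out_channels = 32,
                           num_groups = 8), seed = 3))
  set.seed(6)
  p6 <- extend_pyramid(array(rnorm(32 * 16 * 16), c(32, 16, 16)), nk)
  expect_equal(dim(p6), c(32, 8, 8))
  p6b <- extend_pyramid(array(rnorm(32 * 15 * 15), c(32, 15, 15)), nk)
  expect_equal(dim(p6b), c(32, 8, 8))  # pad-1 stride-2 arithmetic
})

test_that("mapping FLOPs follow the closed form per level", {
  cfg <- neck_config(c(`3` = 80, `4` = 224, `5` = 640))
  fl <- neck_mapping_flops(cfg, sides = c(`3` = 64, `4` = 32, `5` = 16))
  expect_equal(unname(fl), c(80 * 256 * 64^2, 224 * 256 * 32^2, 640 * 256 * 16^2))
})
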