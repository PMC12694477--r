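test_that("convolution MACs follow the closed form", {
  ps <- soystage:::param_store()
  m <- soystage:::ly_conv(ps, "c", cin = 16, cout = 32, k = 3, stride = 2)
  # C_in * k^2 * C_out * H_out * W_out for a 40x40 input
  expect_equal(soystage:::ly_macs(m, 40, 40), 16 * 9 * 32 * 20 * 20)
  lin <- soystage:::ly_linear(ps, "l", 64, 128)
  expect_equal(soystage:::ly_macs(lin, L = 10), 64 * 128 * 10)
})

test_that("profile components are additive and registry-exact", {
  model <- fixture("model_small", function() soystage_model("small"))
  pr <- count_params(model)
  expect_equal(sum(pr$breakdown$params), pr$total)
  expect_equal(pr$params_backbone, backbone_param_count("B3"))
  expect_equal(pr$total - pr$params_backbone, neck_head_params(model))
  fl <- count_flops(model, 256)
  expect_equal(sum(fl$breakdown$macs), fl$total)
  # neck mapping cross-check against the closed form (all variants)
  for (v in c("B3", "B5", "B7")) {
    ch <- variant_spec(v)$stage_channels[c("3", "4", "5")]
    cfg <- neck_config(ch)
    expect_equal(neck_param_count(cfg)$mapping, sum(ch * 256))
  }
})

test_that("profiler neck FLOPs match the per-level closed form", {
  model <- fixture("model_small", function() soystage_model("small"))
  side <- 256L
  nf <- soystage:::neck_flops(model, side)
  sides <- stage_sides(side, 3:5)
  cfg <- model$neck$cfg
  manual <- sum(cfg$in_channels * 256 * sides^2) +
    256^2 * 9 * soystage:::conv_out_side(sides[["5"]], 3L, 2L, 1L)^2
  expect_equal(nf$macs, manual)
})

test_that("conv FLOPs scale quadratically with input side", {
  model <- fixture("model_small", function() soystage_model("small"))
  f512 <- soystage:::backbone_flops(model$backbone$layout, 512)$macs
  f256 <- soystage:::backbone_flops(model$backbone$layout, 256)$macs
  expect_lt(abs(f512 / f256 - 4), 0.2)   # within 5% of 4x (padding effects)
})

test_that("the efficiency score reproduces direct arithmetic and is monotone", {
  s <- efficiency_score(73.9, 70.5e6, 24.4e9)
  expect_equal(s$raw, 73.9 / (0.2 * 0.705 + 0.8 * 2.44), tolerance = 1e-9)
  expect_equal(s$raw, 35.31, tolerance = 1e-2)
  # self-normalization
  cfg <- efficiency_config(baseline = list(ap = 73.9, params = 70.5e6,
                                           flops = 24.4e9))
  expect_equal(efficiency_score(73.9, 70.5e6, 24.4e9, cfg)$normalized, 1.0)
  # monotonicity
  expect_gt(efficiency_score(80, 70.5e6, 24.4e9)$raw, s$raw)
  expect_lt(efficiency_score(73.9, 90e6, 24.4e9)$raw, s$raw)
  expect_lt(efficiency_score(73.9, 70.5e6, 30e9)$raw, s$raw)
  expect_error(efficiency_config(w_p = 0.5, w_f = 0.8))
})

test_that("degenerate parameter-only weighting ranks by AP per parameter", {
  cfg <- efficiency_config(w_p = 1, w_f = 0)
  models <- list(a = list(ap = 70, p = 50e6, f = 20e9),
                 b = list(ap = 60, p = 20e6, f = 40e9),
                 c = list(ap = 75, p = 80e6, f = 10e9))
  sc <- vapply(models, function(m) efficiency_score(m$ap, m$p, m$f, cfg)$raw,
               numeric(1))
  ratio <- vapply(models, function(m) m$ap / m$p, numeric(1))
  expect_equal(order(sc), order(ratio))
})
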