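test_that("task-aligned feature split matches the closed forms", {
  Q <- matrix(c(0, 1, -2, 0.3), 2, 2)
  ta <- task_aligned_features(Q, TRUE)
  expect_equal(ta$F_cls, Q + 0.1 * tanh(Q))
  expect_equal(ta$F_reg, Q + 0.1 * plogis(Q))
  expect_equal(task_aligned_features(matrix(0), TRUE)$F_cls[1], 0)
  expect_equal(task_aligned_features(matrix(0), TRUE)$F_reg[1], 0.05)
  expect_equal(task_aligned_features(matrix(1), TRUE)$F_cls[1], 1.076159,
               tolerance = 1e-6)
  expect_equal(task_aligned_features(matrix(1), TRUE)$F_reg[1], 1.073106,
               tolerance = 1e-6)
  # ablation identity and bounded perturbation
  off <- task_aligned_features(Q, FALSE)
  expect_identical(off$F_cls, Q)
  expect_identical(off$F_reg, Q)
  set.seed(1)
  Qr <- matrix(rnorm(200, 0, 3), 20, 10)
  on <- task_aligned_features(Qr, TRUE)
  expect_true(all(abs(on$F_cls - Qr) <= 0.1))
  expect_true(all(abs(on$F_reg - Qr) <= 0.1))
})

test_that("a zero-depth encoder is the identity stack and lengths add up", {
  hd0 <- build_head(head_config(num_encoder_layers = 0, num_decoder_layers = 1,
                                embed_dim = 32, num_queries = 4, ffn_dim = 64,
                                num_heads = 2, sampling_points = 2,
                                mlp_hidden = 16, num_levels = 4), seed = 5)
  pyr <- tiny_pyramid()
  mem <- encode(pyr, hd0)
  flat <- do.call(cbind, lapply(pyr, function(a) matrix(a, 32)))
  expect_equal(mem$memory, flat)
  expect_equal(mem$length, 256 + 64 + 16 + 4)
  # the working-resolution pyramid gives the documented sequence length
  pyr512 <- tiny_pyramid(sides = c(64L, 32L, 16L, 8L))
  expect_equal(encode(pyr512, hd0)$length, 64^2 + 32^2 + 16^2 + 8^2)
  expect_equal(64^2 + 32^2 + 16^2 + 8^2, 5440)
  expect_error(encode(list(), hd0), "empty")
})

test_that("encoder outputs stay finite over repeated random initializations", {
  pyr <- tiny_pyramid(sides = c(8L, 4L, 2L, 1L))
  for (s in 1:20) {
    hd <- build_head(head_config(num_encoder_layers = 2, num_decoder_layers = 1,
                                 embed_dim = 32, num_queries = 4, ffn_dim = 64,
                                 num_heads = 2, sampling_points = 2,
                                 mlp_hidden = 16, num_levels = 4), seed = s)
    expect_true(all(is.finite(encode(pyr, hd)$memory)))
  }
})

test_that("decoder refines references within the unit box per layer", {
  hd <- tiny_head(enc = 1, dec = 3)
  mem <- encode(tiny_pyramid(), hd)
  qs <- decode(mem, hd)
  expect_length(qs, 3L)
  for (l in seq_along(qs)) {
    expect_true(all(qs[[l]]$ref_boxes >= 0 & qs[[l]]$ref_boxes <= 1))
    expect_equal(dim(qs[[l]]$logits), c(9L, 10L))
  }
  hd1 <- tiny_head(enc = 1, dec = 1)
  expect_length(decode(encode(tiny_pyramid(), hd1), hd1), 1L)
})

test_that("prediction MLPs use the configured narrow hidden width", {
  cfg <- head_config()
  expect_identical(cfg$mlp_hidden, 128L)
  expect_lt(cfg$mlp_hidden, cfg$embed_dim)
  hd <- tiny_head(enc = 1, dec = 1)
  # zero-weight predictors give identical logits for all queries
  for (nm in grep("dec1\\.cls\\.fc", names(hd$ps$arr), value = TRUE))
    hd$ps$arr[[nm]][] <- 0
  Q <- matrix(rnorm(32 * 10), 32, 10)
  refs <- matrix(0.5, 10, 4)
  pred <- head_predict(Q, Q, hd, refs)
  expect_equal(dim(pred$logits), c(10L, 9L))
  expect_true(all(apply(pred$logits, 2, function(col) max(abs(col - col[1]))) == 0))
  expect_true(all(pred$scores > 0 & pred$scores < 1))
})

test_that("query order permutes predictions equivariantly", {
  hd <- tiny_head(enc = 1, dec = 1)
  set.seed(8)
  Q <- matrix(rnorm(32 * 10), 32, 10)
  refs <- matrix(runif(40, 0.2, 0.8), 10, 4)
  perm <- sample(10)
  a <- head_predict(Q, Q, hd, refs)
  b <- head_predict(Q[, perm], Q[, perm], hd, refs[perm, ])
  expect_equal(b$logits, a$logits[perm, ])
  expect_equal(b$boxes, a$boxes[perm, ])
})

test_that("the encoder/decoder depth grid instantiates and runs", {
  pyr <- tiny_pyramid(sides = c(8L, 4L, 2L, 1L))
  for (enc in 2:4) for (dec in c(1L, 4L)) {
    hd <- build_head(head_config(num_encoder_layers = enc,
                                 num_decoder_layers = dec, embed_dim = 32,
                                 num_queries = 6, ffn_dim = 64, num_heads = 2,
                                 sampling_points = 2, mlp_hidden = 16,
                                 num_levels = 4), seed = enc * 10 + dec)
    out <- decode(encode(pyr, hd), hd)
    expect_length(out, dec)
    expect_true(all(is.finite(out[[dec]]$logits)))
  }
})

test_that("head configuration validates divisibility", {
  expect_error(head_config(embed_dim = 30, num_heads = 4), "divisible")
})
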