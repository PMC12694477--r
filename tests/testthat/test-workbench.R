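test_that("presets pair backbones with head depths as published", {
  m <- fixture("model_small", function() soystage_model("small"))
  expect_equal(m$backbone$variant$name, "B3")
  expect_equal(m$head$cfg$num_encoder_layers, 2L)
  expect_equal(m$head$cfg$num_decoder_layers, 1L)
  cfgM <- soystage:::.presets$medium
  expect_equal(c(cfgM$variant, cfgM$num_encoder_layers, cfgM$num_decoder_layers),
               c("B5", 3, 1))
  cfgL <- soystage:::.presets$large
  expect_equal(c(cfgL$variant, cfgL$num_encoder_layers, cfgL$num_decoder_layers),
               c("B7", 3, 3))
})

test_that("model construction is reproducible from the master seed", {
  a <- soystage_model("smoke", seed = 7)
  b <- soystage_model("smoke", seed = 7)
  expect_identical(a$ps$arr, b$ps$arr)
  c <- soystage_model("smoke", seed = 8)
  expect_false(identical(a$ps$arr, c$ps$arr))
})

test_that("configurations round-trip through YAML", {
  cfg <- run_config("large", list(num_decoder_layers = 2L,
                                  out_indices = c(2L, 3L, 4L, 5L),
                                  task_alignment = FALSE),
                    schedule = schedule_config(base_lr = 1e-4),
                    protocol = eval_protocol(confidence_threshold = 0.1))
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  cfg2 <- load_config(path)
  expect_equal(cfg2$preset, "large")
  expect_equal(cfg2$overrides$num_decoder_layers, 2L)
  expect_equal(cfg2$overrides$out_indices, c(2L, 3L, 4L, 5L))
  expect_false(cfg2$overrides$task_alignment)
  expect_equal(cfg2$schedule$base_lr, 1e-4)
  expect_equal(cfg2$protocol$confidence_threshold, 0.1)
  expect_error(run_config("small", list(bogus = 1)), "unknown override")
})

test_that("short same-seed training runs produce identical loss curves", {
  ds <- smoke_dataset()
  sc <- schedule_config(base_lr = 1e-3, warmup_iters = 10, batch_size = 4,
                        epochs = 5, decay_epochs = c(4, 5))
  r1 <- run_train(soystage_model("smoke", seed = 3), ds, schedule = sc,
                  max_iters = 3, denoise = TRUE, seed = 55)
  r2 <- run_train(soystage_model("smoke", seed = 3), ds, schedule = sc,
                  max_iters = 3, denoise = TRUE, seed = 55)
  expect_identical(r1$log$loss, r2$log$loss)
  expect_true(all(is.finite(r1$log$loss)))
})

test_that("the ablation harness emits the component and depth grids with profiles", {
  ab <- fixture("ablation_small", function()
    run_ablation("small", depth_grid = data.frame(enc = 2, dec = 1)))
  comp <- ab[ab$kind == "components", ]
  expect_equal(nrow(comp), 4L)
  expect_equal(nrow(unique(comp[, c("task_alignment", "adaptive_noise")])), 4L)
  stg <- ab[ab$kind == "stages", ]
  expect_equal(sort(stg$levels), c(3L, 4L))
  # profiling columns are filled even without training
  expect_true(all(!is.na(ab$params_M)))
  expect_true(all(!is.na(ab$gflops)))
  expect_true(all(is.na(ab$AP)))
  # the 4-level variant costs more than the 3-level one
  expect_gt(stg$gflops[stg$levels == 4], stg$gflops[stg$levels == 3])
})

test_that("stage-4 pyramid mismatch between model and config is rejected", {
  cfg <- run_config("smoke", list(out_indices = c(2L, 3L, 4L, 5L)))
  # config_model builds a 5-level head for 4 backbone stages; consistent
  m <- soystage:::config_model(cfg)
  expect_equal(m$head$cfg$num_levels, 5L)
})

test_that("a short smoke run reduces the training loss", {
  ds <- smoke_dataset()
  m <- soystage_model("smoke", seed = 21)
  sc <- schedule_config(base_lr = 2e-3, warmup_iters = 5, batch_size = 8,
                        epochs = 30, decay_epochs = c(25, 28))
  res <- run_train(m, ds, schedule = sc, max_iters = 15, denoise = FALSE,
                   seed = 21)
  expect_lt(mean(tail(res$log$loss, 3)), mean(head(res$log$loss, 3)))
})
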