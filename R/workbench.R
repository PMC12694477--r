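# Run configuration, YAML round-trip, profiling runs and the ablation
# harness tying the modules together.

#' Resolve a run configuration
#'
#' Presets pair backbone and head depths (small: B3 with 2 encoder / 1
#' decoder blocks; medium: B5, 3/1; large: B7, 3/3; smoke: miniature), with
#' overrides for the ablation surface: head depths, task alignment, adaptive
#' noise, backbone stages.
#'
#' @param preset model preset.
#' @param overrides named list of overrides (num_encoder_layers,
#'   num_decoder_layers, task_alignment, adaptive_noise, out_indices,
#'   num_queries, seed).
#' @param schedule a [schedule_config()].
#' @param protocol an [eval_protocol()].
#' @return a `run_config` list.
#' @export
run_config <- function(preset = "small", overrides = list(),
                       schedule = schedule_config(),
                       protocol = eval_protocol()) {
  allowed <- c("num_encoder_layers", "num_decoder_layers", "task_alignment",
               "adaptive_noise", "out_indices", "num_queries", "seed")
  bad <- setdiff(names(overrides), allowed)
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  structure(list(preset = preset, overrides = overrides,
                 schedule = schedule, protocol = protocol),
            class = "run_config")
}

config_model <- function(cfg) {
  ov <- cfg$overrides
  soystage_model(cfg$preset,
                 out_indices = ov$out_indices %||% c(3L, 4L, 5L),
                 task_alignment = ov$task_alignment %||% TRUE,
                 adaptive_noise = ov$adaptive_noise %||% TRUE,
                 num_encoder_layers = ov$num_encoder_layers,
                 num_decoder_layers = ov$num_decoder_layers,
                 num_queries = ov$num_queries,
                 seed = ov$seed %||% 115045267)
}

#' Save / load a run configuration as YAML
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(list(preset = cfg$preset, overrides = cfg$overrides,
                        schedule = unclass(cfg$schedule),
                        protocol = unclass(cfg$protocol)), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- do.call(schedule_config, y$schedule[names(y$schedule) %in%
                                              names(formals(schedule_config))])
  pr <- do.call(eval_protocol, y$protocol[names(y$protocol) %in%
                                            names(formals(eval_protocol))])
  ov <- y$overrides
  if (!is.null(ov$out_indices)) ov$out_indices <- as.integer(ov$out_indices)
  run_config(y$preset, ov %||% list(), sc, pr)
}

#' Profile a configuration: parameters, FLOPs and efficiency score
#'
#' Random weights suffice; the profile is analytic. The report includes the
#' baseline triple used for score normalization.
#'
#' @param cfg a [run_config()] (or preset name).
#' @param input_side profiling resolution.
#' @param ap optional AP (percent) to score; NA skips the efficiency score.
#' @param eff an [efficiency_config()].
#' @return a `run_profile` list.
#' @export
run_profile <- function(cfg, input_side = 512L, ap = NA_real_,
                        eff = efficiency_config()) {
  if (is.character(cfg)) cfg <- run_config(cfg)
  model <- config_model(cfg)
  pr <- count_params(model)
  fl <- count_flops(model, input_side)
  score <- if (!is.na(ap))
    efficiency_score(ap, pr$total, fl$total, eff)
  else list(raw = NA_real_, normalized = NA_real_)
  structure(list(preset = cfg$preset, overrides = cfg$overrides,
                 params = pr, flops = fl,
                 params_total_M = round(pr$total / 1e6, 2),
                 params_backbone_M = round(pr$params_backbone / 1e6, 2),
                 params_neck_head_M = round((pr$total - pr$params_backbone) / 1e6, 2),
                 gflops = round(fl$total / 1e9, 1),
                 efficiency = score, baseline = eff$baseline),
            class = "run_profile")
}

#' @export
print.run_profile <- function(x, ...) {
  cat(sprintf("%s: %.2f M params (backbone %.2f, neck+head %.2f), %.1f GFLOPs\n",
              x$preset, x$params_total_M, x$params_backbone_M,
              x$params_neck_head_M, x$gflops))
  if (!is.na(x$efficiency$raw))
    cat(sprintf("  efficiency score %.2f raw, %.2fx vs baseline (AP %.1f, %.1f M, %.1f G)\n",
                x$efficiency$raw, x$efficiency$normalized, x$baseline$ap,
                x$baseline$params / 1e6, x$baseline$flops / 1e9))
  invisible(x)
}

#' Train a configuration end to end
#'
#' Thin wrapper resolving the configuration to a model and calling
#' [run_train()] on the dataset.
#'
#' @param cfg a [run_config()].
#' @param dataset dataset directory or in-memory dataset.
#' @param ... passed to [run_train()].
#' @export
run_train_config <- function(cfg, dataset, ...) {
  model <- config_model(cfg)
  nlv <- length(cfg$overrides$out_indices %||% c(3L, 4L, 5L)) + 1L
  if (model$head$cfg$num_levels != nlv)
    stop("pyramid level mismatch between backbone stages and head")
  run_train(model, dataset, schedule = cfg$schedule, ...)
}

#' Ablation harness
#'
#' Sweeps the component grid (task alignment x adaptive noise), the backbone
#' stage depth (3- vs 4-level pyramid) and the encoder/decoder depth grid,
#' emitting one row per configuration with profiling columns (parameters by
#' component, GFLOPs, efficiency score). With `profile_only = TRUE` (the
#' default) no training is performed and AP columns are NA; supplying a
#' `train_fn(model, config)` returning an `ap_report` fills them.
#'
#' @param preset model preset to sweep.
#' @param components include the 2x2 task-alignment / adaptive-noise grid.
#' @param stage_grid include out_indices (3,4,5) vs (2,3,4,5).
#' @param depth_grid data.frame with columns enc, dec (defaults to the
#'   published depth grid for the preset).
#' @param input_side profiling resolution.
#' @param profile_only skip training.
#' @param train_fn optional function(model, overrides) -> `ap_report`.
#' @param eff an [efficiency_config()].
#' @return data.frame, one row per configuration.
#' @export
run_ablation <- function(preset = "large", components = TRUE,
                         stage_grid = TRUE, depth_grid = NULL,
                         input_side = 512L, profile_only = TRUE,
                         train_fn = NULL, eff = efficiency_config()) {
  if (is.null(depth_grid)) {
    depth_grid <- if (preset == "large") {
      g <- expand.grid(dec = 1:4, enc = 2:4)[, c("enc", "dec")]
      g[order(g$enc, g$dec), ]
    } else expand.grid(enc = 2:3, dec = 1:2)
  }
  jobs <- list()
  base <- .presets[[preset]]
  if (components) {
    for (ta in c(TRUE, FALSE)) for (an in c(TRUE, FALSE))
      jobs[[length(jobs) + 1L]] <- list(kind = "components",
                                        task_alignment = ta, adaptive_noise = an,
                                        enc = base$num_encoder_layers,
                                        dec = base$num_decoder_layers,
                                        out_indices = c(3L, 4L, 5L))
  }
  if (stage_grid) {
    for (oi in list(c(3L, 4L, 5L), c(2L, 3L, 4L, 5L)))
      jobs[[length(jobs) + 1L]] <- list(kind = "stages", task_alignment = TRUE,
                                        adaptive_noise = TRUE,
                                        enc = base$num_encoder_layers,
                                        dec = base$num_decoder_layers,
                                        out_indices = oi)
  }
  for (r in seq_len(nrow(depth_grid)))
    jobs[[length(jobs) + 1L]] <- list(kind = "depth", task_alignment = TRUE,
                                      adaptive_noise = TRUE,
                                      enc = depth_grid$enc[r], dec = depth_grid$dec[r],
                                      out_indices = c(3L, 4L, 5L))
  rows <- lapply(jobs, function(j) {
    res <- tryCatch({
      model <- soystage_model(preset, out_indices = j$out_indices,
                              task_alignment = j$task_alignment,
                              adaptive_noise = j$adaptive_noise,
                              num_encoder_layers = j$enc,
                              num_decoder_layers = j$dec)
      pr <- count_params(model)
      fl <- count_flops(model, input_side)
      ap <- NA_real_
      if (!profile_only && !is.null(train_fn))
        ap <- train_fn(model, j)$AP
      sc <- if (!is.na(ap)) efficiency_score(ap, pr$total, fl$total, eff)
      else list(raw = NA_real_, normalized = NA_real_)
      data.frame(kind = j$kind, enc = j$enc, dec = j$dec,
                 task_alignment = j$task_alignment,
                 adaptive_noise = j$adaptive_noise,
                 levels = length(j$out_indices),
                 AP = ap,
                 params_M = round(pr$total / 1e6, 2),
                 backbone_M = round(pr$params_backbone / 1e6, 2),
                 neck_head_M = round((pr$total - pr$params_backbone) / 1e6, 2),
                 gflops = round(fl$total / 1e9, 1),
                 eff_raw = sc$raw, eff_norm = sc$normalized)
    }, error = function(e) {
      message("skipping infeasible configuration: ", conditionMessage(e))
      NULL
    })
    res
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
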