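# The user-facing detector object: backbone + neck + head assembled from a
# preset, with predict/print/summary methods.

.presets <- list(
  small = list(variant = "B3", num_encoder_layers = 2L, num_decoder_layers = 1L,
               embed_dim = 256L, num_heads = 8L, ffn_dim = 1024L,
               num_queries = 300L, sampling_points = 4L, mlp_hidden = 128L,
               neck_out = 256L, neck_groups = 32L, input_side = 512L),
  medium = list(variant = "B5", num_encoder_layers = 3L, num_decoder_layers = 1L,
                embed_dim = 256L, num_heads = 8L, ffn_dim = 1024L,
                num_queries = 300L, sampling_points = 4L, mlp_hidden = 128L,
                neck_out = 256L, neck_groups = 32L, input_side = 512L),
  large = list(variant = "B7", num_encoder_layers = 3L, num_decoder_layers = 3L,
               embed_dim = 256L, num_heads = 8L, ffn_dim = 1024L,
               num_queries = 300L, sampling_points = 4L, mlp_hidden = 128L,
               neck_out = 256L, neck_groups = 32L, input_side = 512L),
  smoke = list(variant = "tiny", num_encoder_layers = 1L, num_decoder_layers = 1L,
               embed_dim = 32L, num_heads = 2L, ffn_dim = 64L,
               num_queries = 12L, sampling_points = 2L, mlp_hidden = 16L,
               neck_out = 32L, neck_groups = 8L, input_side = 64L)
)

#' Construct a growth-stage detector
#'
#' Assembles the truncated compound-scaled backbone, channel-mapper neck and
#' encoder-decoder detection head for one of the presets:
#' small (B3 backbone, 2 encoder / 1 decoder blocks),
#' medium (B5, 3/1), large (B7, 3/3), or smoke (a miniature configuration
#' for CPU tests and training demonstrations).
#'
#' @param preset one of "small", "medium", "large", "smoke".
#' @param out_indices backbone stages feeding the neck (default 3:5; 2:5
#'   adds the stride-4 stage for the 4-level ablation).
#' @param task_alignment enable the task-aligned predictor split.
#' @param adaptive_noise scale denoising perturbations by inverse class
#'   frequency (FALSE uses a fixed unit scale).
#' @param num_encoder_layers,num_decoder_layers optional depth overrides.
#' @param num_queries optional query-count override.
#' @param seed master seed for weight initialization (default the fixed
#'   experiment seed 115045267).
#' @return a `soystage_model`.
#' @export
soystage_model <- function(preset = c("small", "medium", "large", "smoke"),
                           out_indices = c(3L, 4L, 5L), task_alignment = TRUE,
                           adaptive_noise = TRUE, num_encoder_layers = NULL,
                           num_decoder_layers = NULL, num_queries = NULL,
                           seed = 115045267) {
  preset <- match.arg(preset)
  p <- .presets[[preset]]
  if (!is.null(num_encoder_layers)) p$num_encoder_layers <- as.integer(num_encoder_layers)
  if (!is.null(num_decoder_layers)) p$num_decoder_layers <- as.integer(num_decoder_layers)
  if (!is.null(num_queries)) p$num_queries <- as.integer(num_queries)
  out_indices <- sort(unique(as.integer(out_indices)))
  backbone <- build_backbone(p$variant, out_indices, seed = derive_seed(seed, "backbone"))
  ch <- backbone$variant$stage_channels[as.character(out_indices)]
  ncfg <- neck_config(stats::setNames(as.integer(ch), as.character(out_indices)),
                      out_channels = p$neck_out, num_groups = p$neck_groups)
  neck <- build_neck(ncfg, seed = derive_seed(seed, "neck"))
  num_levels <- length(out_indices) + ncfg$num_extra_levels
  hcfg <- head_config(num_encoder_layers = p$num_encoder_layers,
                      num_decoder_layers = p$num_decoder_layers,
                      embed_dim = p$embed_dim, num_queries = p$num_queries,
                      ffn_dim = p$ffn_dim, num_heads = p$num_heads,
                      sampling_points = p$sampling_points,
                      mlp_hidden = p$mlp_hidden,
                      task_alignment = task_alignment, num_levels = num_levels)
  head <- build_head(hcfg, seed = derive_seed(seed, "head"))
  # merge all parameters into one shared store
  ps <- param_store()
  ps$arr <- c(backbone$ps$arr, neck$ps$arr, head$ps$arr)
  backbone$ps <- ps; neck$ps <- ps; head$ps <- ps
  structure(list(preset = preset, backbone = backbone, neck = neck,
                 head = head, ps = ps,
                 cfg = list(input_side = p$input_side,
                            task_alignment = task_alignment,
                            adaptive_noise = adaptive_noise,
                            out_indices = out_indices),
                 seed = seed),
            class = "soystage_model")
}

# shared forward: images as (3, S*S*N) matrix -> head outputs
model_forward <- function(P, model, x, side, N, dn = NULL) {
  old <- set_buffer_store(model$ps)
  on.exit(set_buffer_store(old))
  feats <- backbone_forward(P, model$backbone, x, side, side, N)
  lv <- neck_forward(P, model$neck, feats, N)
  head_forward(P, model$head, lv, N, dn = dn)
}

#' Detect growth stages in an image
#'
#' Resizes to the working resolution, runs the full forward pass, applies
#' the confidence threshold, class-wise NMS and the top-k cap from the
#' protocol, and returns detections in the original image coordinates.
#'
#' @param object a `soystage_model`.
#' @param image (H, W, 3) array in [0, 1].
#' @param protocol an [eval_protocol()]; the model's working resolution is
#'   used for the forward pass.
#' @param ... unused.
#' @return data.frame with category_id (0-based stage ordinal), score and
#'   absolute (x, y, w, h).
#' @export
predict.soystage_model <- function(object, image,
                                   protocol = eval_protocol(input_side = object$cfg$input_side),
                                   ...) {
  side <- object$cfg$input_side
  H0 <- dim(image)[1]; W0 <- dim(image)[2]
  img <- if (H0 != side || W0 != side) resize_image(image, side, side) else image
  x <- image_to_feature(img)
  out <- model_forward(object$ps$arr, object, x, side, 1L)
  last <- out$layers[[length(out$layers)]]
  logits <- vof(last$logits)                      # (ncls, nq)
  boxes <- vof(last$boxes)                        # (4, nq) normalized cxcywh
  scores <- 1 / (1 + exp(-logits))
  ncls <- nrow(scores); nq <- ncol(scores)
  df <- data.frame(category_id = rep(seq_len(ncls) - 1L, nq),
                   query = rep(seq_len(nq), each = ncls),
                   score = as.vector(scores))
  df <- df[df$score >= protocol$confidence_threshold, , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(category_id = integer(0), score = numeric(0),
                      x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0)))
  }
  b <- t(boxes[, df$query, drop = FALSE])
  abs_b <- cbind((b[, 1] - b[, 3] / 2) * W0, (b[, 2] - b[, 4] / 2) * H0,
                 b[, 3] * W0, b[, 4] * H0)
  keep <- logical(nrow(df))
  for (cl in unique(df$category_id)) {
    ii <- which(df$category_id == cl)
    kk <- nms(box_xywh_to_xyxy(abs_b[ii, , drop = FALSE]), df$score[ii],
              protocol$nms_threshold)
    keep[ii[kk]] <- TRUE
  }
  df <- df[keep, , drop = FALSE]; abs_b <- abs_b[keep, , drop = FALSE]
  ord <- order(df$score, decreasing = TRUE)
  if (length(ord) > protocol$max_dets) ord <- ord[seq_len(protocol$max_dets)]
  data.frame(category_id = df$category_id[ord], score = df$score[ord],
             x = abs_b[ord, 1], y = abs_b[ord, 2],
             w = abs_b[ord, 3], h = abs_b[ord, 4])
}

#' Display detections over an image
#'
#' Runs the detector on the image, overlays the top-scoring boxes and draws
#' the result on the current graphics device; the annotated array is
#' returned invisibly (useful headless via [draw_boxes()] + `png::writePNG`).
#'
#' @param x a `soystage_model`.
#' @param image (H, W, 3) array in [0, 1].
#' @param max_boxes boxes to draw, in score order.
#' @param ... passed to [predict.soystage_model()].
#' @export
plot.soystage_model <- function(x, image, max_boxes = 3L, ...) {
  d <- utils::head(predict(x, image, ...), max_boxes)
  img <- if (nrow(d))
    draw_boxes(image, as.matrix(d[, c("x", "y", "w", "h")])) else image
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, dim(img)[2]), c(dim(img)[1], 0), asp = 1)
  graphics::rasterImage(grDevices::as.raster(img), 0, dim(img)[1], dim(img)[2], 0)
  invisible(img)
}

#' @export
print.soystage_model <- function(x, ...) {
  pr <- count_params(x)
  cat(sprintf("Growth-stage detector (preset '%s')\n", x$preset))
  cat(sprintf("  backbone %s (stages %s): %.2f M params\n",
              x$backbone$variant$name,
              paste(x$cfg$out_indices, collapse = ","),
              pr$params_backbone / 1e6))
  cat(sprintf("  head: %d encoder / %d decoder blocks, %d queries\n",
              x$head$cfg$num_encoder_layers, x$head$cfg$num_decoder_layers,
              x$head$cfg$num_queries))
  cat(sprintf("  neck+head: %.2f M params; total %.2f M\n",
              (pr$total - pr$params_backbone) / 1e6, pr$total / 1e6))
  invisible(x)
}

#' @export
summary.soystage_model <- function(object, input_side = object$cfg$input_side, ...) {
  pr <- count_params(object)
  fl <- count_flops(object, input_side)
  out <- list(params = pr, flops = fl, preset = object$preset)
  class(out) <- "summary.soystage_model"
  out
}

#' @export
print.summary.soystage_model <- function(x, ...) {
  cat(sprintf("Preset '%s'\n", x$preset))
  print(x$params)
  print(x$flops)
  invisible(x)
}
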