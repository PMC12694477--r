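# End-to-end training: set-prediction losses over all decoder layers plus the
# encoder proposal stage, denoising reconstruction losses, AdamW with warmup /
# multi-step decay and global gradient clipping.

# classification + box losses for one prediction set against per-image GTs.
# logits/boxes are tape nodes over columns laid out per image; cols_per_image
# gives each image's matching-query columns.
set_loss <- function(logits, boxes, cols_per_image, gts, lcfg) {
  lv <- vof(logits); bv <- vof(boxes)
  ncls <- nrow(lv)
  allcols <- unlist(cols_per_image)
  Y <- matrix(0, ncls, length(allcols))
  matched_cols <- integer(0)
  matched_gt <- NULL
  off <- 0L
  for (n in seq_along(cols_per_image)) {
    cols <- cols_per_image[[n]]
    g <- gts[[n]]
    if (length(g$labels)) {
      probs <- t(stats::plogis(lv[, cols, drop = FALSE]))
      bx <- t(bv[, cols, drop = FALSE])
      mt <- match_detections(probs, bx, g$labels, g$boxes)
      pb <- bx[mt$det, , drop = FALSE]
      iou <- giou_pairwise(box_cxcywh_to_xyxy(pb), box_cxcywh_to_xyxy(g$boxes))
      iou <- pmax(pmin(iou, 1), 0)      # IoU-aware quality in [0, 1]
      Y[cbind(g$labels + 1L, off + mt$det)] <- iou
      matched_cols <- c(matched_cols, cols[mt$det])
      matched_gt <- rbind(matched_gt, g$boxes)
    }
    off <- off + length(cols)
  }
  npos <- max(1, if (is.null(matched_gt)) 0 else nrow(matched_gt))
  sig <- ad_sigmoid(ad_cols(logits, allcols))
  cls <- ad_mul(ad_sum(ad_qfl(sig, Y, lcfg$qfl_beta)), 1 / npos)
  if (!is.null(matched_gt)) {
    pred <- ad_cols(boxes, matched_cols)
    tgt <- t(matched_gt)
    l1 <- ad_mul(ad_sum(ad_abs(ad_sub(pred, tgt))), lcfg$lambda_l1 / npos)
    gl <- ad_mul(ad_sum(ad_giou_loss(pred, tgt)), lcfg$lambda_giou / npos)
  } else {
    l1 <- 0; gl <- 0
  }
  list(cls = cls, l1 = l1, giou = gl)
}

# denoising reconstruction loss: each non-padded noise query is bound to its
# source ground truth (no matching)
dn_loss <- function(logits, boxes, out, dn, gts, lcfg) {
  lv <- vof(logits); bv <- vof(boxes)
  ncls <- nrow(lv)
  M <- out$M; N <- out$N; dn_n <- out$n_dn
  cols <- integer(0); tgt_lab <- integer(0); tgt_box <- NULL
  for (q in seq_along(dn$labels)) {
    if (dn$pad[q]) next
    n <- dn$image[q]
    within <- q - (n - 1L) * dn_n
    col <- (n - 1L) * M + within
    g <- gts[[n]]
    cols <- c(cols, col)
    tgt_lab <- c(tgt_lab, g$labels[dn$gt_index[q]])
    tgt_box <- rbind(tgt_box, g$boxes[dn$gt_index[q], ])
  }
  if (!length(cols)) return(list(cls = 0, l1 = 0, giou = 0))
  npos <- length(cols)
  pb <- t(bv[, cols, drop = FALSE])
  iou <- pmax(pmin(giou_pairwise(box_cxcywh_to_xyxy(pb),
                                 box_cxcywh_to_xyxy(tgt_box)), 1), 0)
  Y <- matrix(0, ncls, npos)
  Y[cbind(tgt_lab + 1L, seq_len(npos))] <- iou
  sig <- ad_sigmoid(ad_cols(logits, cols))
  cls <- ad_mul(ad_sum(ad_qfl(sig, Y, lcfg$qfl_beta)), 1 / npos)
  pred <- ad_cols(boxes, cols)
  l1 <- ad_mul(ad_sum(ad_abs(ad_sub(pred, t(tgt_box)))), lcfg$lambda_l1 / npos)
  gl <- ad_mul(ad_sum(ad_giou_loss(pred, t(tgt_box))), lcfg$lambda_giou / npos)
  list(cls = cls, l1 = l1, giou = gl)
}

# one optimization step over a batch of samples (images already at the
# model's working resolution); returns loss components and gradient norm
train_step <- function(model, samples, opt, lr, sched, lcfg = loss_config(),
                       dncfg = NULL, aux_losses = TRUE) {
  side <- model$cfg$input_side
  N <- length(samples)
  x <- do.call(cbind, lapply(samples, function(s) image_to_feature(s$image)))
  gts <- lapply(samples, function(s) {
    if (!nrow(s$boxes)) return(list(labels = integer(0), boxes = matrix(0, 0, 4)))
    b <- cbind(s$boxes[, 1] + s$boxes[, 3] / 2, s$boxes[, 2] + s$boxes[, 4] / 2,
               s$boxes[, 3], s$boxes[, 4]) / side
    list(labels = as.integer(s$labels), boxes = b)
  })
  dn <- NULL
  if (!is.null(dncfg) && any(vapply(gts, function(g) length(g$labels) > 0, logical(1)))) {
    if (!model$cfg$adaptive_noise)
      dncfg$class_counts <- rep(1, length(dncfg$class_counts))  # alpha = 0.5 fixed
    dn <- build_denoising_batch(gts, dncfg, model$head$cfg$num_queries)
  }
  ad_tape_start()
  P <- params_as_leaves(model$ps)
  out <- model_forward(P, model, x, side, N, dn = dn)
  M <- out$M; nq <- out$num_queries; dn_n <- out$n_dn
  cols_match <- lapply(seq_len(N), function(n) (n - 1L) * M + dn_n + seq_len(nq))
  layer_ids <- if (aux_losses) seq_along(out$layers) else length(out$layers)
  total <- NULL
  parts <- c(cls = 0, l1 = 0, giou = 0, dn = 0)
  addl <- function(total, l) {
    t2 <- ad_add(ad_add(l$cls, l$l1), l$giou)
    if (is.null(total)) t2 else ad_add(total, t2)
  }
  for (li in layer_ids) {
    l <- set_loss(out$layers[[li]]$logits, out$layers[[li]]$boxes,
                  cols_match, gts, lcfg)
    total <- addl(total, l)
    parts["cls"] <- parts["cls"] + as.numeric(vof(l$cls))
    parts["l1"] <- parts["l1"] + as.numeric(vof(l$l1))
    parts["giou"] <- parts["giou"] + as.numeric(vof(l$giou))
    if (!is.null(dn) && dn$n_dn > 0L) {
      ld <- dn_loss(out$layers[[li]]$logits, out$layers[[li]]$boxes, out, dn, gts, lcfg)
      total <- addl(total, ld)
      parts["dn"] <- parts["dn"] +
        as.numeric(vof(ld$cls)) + as.numeric(vof(ld$l1)) + as.numeric(vof(ld$giou))
    }
  }
  # encoder proposal supervision (the selected top-k act as a stage-0 layer)
  enc_logits <- ad_cols(out$enc$cls, out$sel)
  enc_boxes <- ad_cols(out$enc$boxes, out$sel)
  cols_enc <- lapply(seq_len(N), function(n) (n - 1L) * nq + seq_len(nq))
  le <- set_loss(enc_logits, enc_boxes, cols_enc, gts, lcfg)
  total <- addl(total, le)
  parts["cls"] <- parts["cls"] + as.numeric(vof(le$cls))
  ad_backward(total)
  gn <- adamw_step(model$ps, P, opt, lr, sched)
  loss_val <- as.numeric(vof(total))
  ad_tape_stop()
  list(loss = loss_val, parts = parts, grad_norm = gn)
}

#' Train a detector on a COCO-format dataset
#'
#' Reproducible mini-batch training with linear warmup, multi-step decay,
#' AdamW, global gradient clipping and (optionally) denoising query groups
#' and data augmentation. Validation runs every `validate_every` epochs and
#' the best parameter snapshot (by validation AP) is kept.
#'
#' @param model a `soystage_model`.
#' @param dataset a directory produced by [generate_dataset()] or the
#'   in-memory dataset it returns.
#' @param schedule a [schedule_config()].
#' @param max_iters stop after this many iterations (overrides epochs).
#' @param augment apply the augmentation pipeline.
#' @param denoise enable denoising query training.
#' @param validate_every validation period in epochs (NULL disables).
#' @param checkpoint_path optional RDS path for the best parameters.
#' @param seed RNG seed for batching/augmentation/denoising.
#' @param verbose print progress lines.
#' @return list with the trained `model`, a `log` data.frame (iteration,
#'   epoch, loss components, lr, grad norm) and `val_history`.
#' @export
run_train <- function(model, dataset, schedule = schedule_config(),
                      max_iters = NULL, augment = FALSE, denoise = TRUE,
                      validate_every = NULL, checkpoint_path = NULL,
                      seed = model$seed, verbose = FALSE) {
  samples <- dataset_samples(dataset, "train", model$cfg$input_side)
  if (!length(samples)) stop("training split is empty")
  set.seed(derive_seed(seed, "train"))
  n <- length(samples)
  bs <- min(schedule$batch_size, n)
  iters_per_epoch <- max(1L, n %/% bs)
  total_iters <- max_iters %||% (schedule$epochs * iters_per_epoch)
  opt <- adamw_new(names(model$ps$arr))
  dncfg <- if (denoise) denoise_config() else NULL
  log <- vector("list", total_iters)
  best <- list(ap = -Inf, params = NULL)
  val_history <- list()
  for (it in seq_len(total_iters)) {
    epoch <- 1L + (it - 1L) %/% iters_per_epoch
    idx <- sample.int(n, bs)
    batch <- lapply(samples[idx], function(s) {
      if (!augment) return(s)
      a <- augment_sample(s$image, s$boxes)
      img <- if (any(dim(a$image)[1:2] != model$cfg$input_side))
        resize_image(a$image, model$cfg$input_side, model$cfg$input_side) else a$image
      sc <- model$cfg$input_side / dim(a$image)[1]
      list(image = img,
           boxes = if (nrow(a$boxes)) a$boxes * sc else a$boxes,
           labels = s$labels[seq_len(nrow(a$boxes))])
    })
    lr <- lr_at(it - 1L, epoch, schedule)
    st <- train_step(model, batch, opt, lr, schedule, dncfg = dncfg)
    log[[it]] <- data.frame(iteration = it, epoch = epoch, loss = st$loss,
                            cls = unname(st$parts["cls"]), l1 = unname(st$parts["l1"]),
                            giou = unname(st$parts["giou"]), dn = unname(st$parts["dn"]),
                            lr = lr, grad_norm = st$grad_norm, row.names = NULL)
    if (verbose && (it %% 25L == 0L || it == 1L))
      message(sprintf("iter %d/%d epoch %d loss %.4f lr %.2e",
                      it, total_iters, epoch, st$loss, lr))
    if (!is.null(validate_every) && it %% (validate_every * iters_per_epoch) == 0L) {
      refresh_bn_stats(model, samples[seq_len(min(n, 16L))])
      vr <- evaluate_model(model, dataset,
                           eval_protocol(input_side = model$cfg$input_side),
                           split = "val")
      val_history[[length(val_history) + 1L]] <-
        data.frame(iteration = it, AP = vr$AP)
      if (!is.na(vr$AP) && vr$AP > best$ap) {
        best$ap <- vr$AP
        best$params <- model$ps$arr
        if (!is.null(checkpoint_path))
          saveRDS(list(params = model$ps$arr, iteration = it, ap = vr$AP),
                  checkpoint_path)
      }
    }
  }
  if (!is.null(best$params)) model$ps$arr <- best$params
  refresh_bn_stats(model, samples[seq_len(min(n, 16L))])
  list(model = model, log = do.call(rbind, log),
       val_history = if (length(val_history)) do.call(rbind, val_history))
}

#' Refresh batch-norm running statistics with an exact pass
#'
#' Recomputes the normalization statistics from a forward pass over the given
#' samples (momentum 1), removing the lag of the momentum-averaged estimates
#' after the final weight updates.
#'
#' @param model a `soystage_model`.
#' @param samples list of samples at the working resolution (e.g. from
#'   [dataset_samples()]).
#' @export
refresh_bn_stats <- function(model, samples) {
  side <- model$cfg$input_side
  x <- do.call(cbind, lapply(samples, function(s) image_to_feature(s$image)))
  .ad$bn_precise <- TRUE
  on.exit(.ad$bn_precise <- NULL)
  invisible(model_forward(model$ps$arr, model, x, side, length(samples)))
}

#' Materialize a dataset split as training samples
#'
#' Loads a split's images and annotations and rescales them to the working
#' resolution; each sample holds the image array, absolute (x, y, w, h) boxes
#' and 0-based labels.
#'
#' @param dataset directory or in-memory dataset from [generate_dataset()].
#' @param split "train", "val" or "test".
#' @param side working resolution.
#' @export
dataset_samples <- function(dataset, split, side) {
  if (is.character(dataset)) {
    coco <- read_coco(file.path(dataset, "annotations",
                                paste0("instances_", split, ".json")))
    imgdir <- file.path(dataset, "images")
    getimg <- function(fn) png::readPNG(file.path(imgdir, fn))
  } else {
    coco <- read_coco(dataset$splits[[split]])
    getimg <- function(fn) {
      i <- as.integer(sub("img_0*([0-9]+)\\.png", "\\1", fn))
      dataset$samples[[i]]$image
    }
  }
  lapply(seq_len(nrow(coco$images)), function(r) {
    info <- coco$images[r, ]
    img <- getimg(info$file_name)
    sc <- side / info$width
    ann <- coco$annotations[coco$annotations$image_id == info$id, , drop = FALSE]
    if (dim(img)[1] != side)
      img <- resize_image(img, side, side)
    list(image = img,
         boxes = as.matrix(ann[, c("x", "y", "w", "h")]) * sc,
         labels = ann$category_id)
  })
}
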