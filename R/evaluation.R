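# COCO-protocol detection evaluation: AP averaged over IoU thresholds
# 0.50:0.05:0.95 with 101-point precision interpolation, scale buckets by
# bounding-box area, fixed confidence/NMS thresholds and top-100 detections.

#' Evaluation protocol constants
#'
#' @param input_side evaluation resolution (512).
#' @param confidence_threshold minimum kept score (0.05).
#' @param nms_threshold class-wise NMS IoU threshold (0.5).
#' @param iou_thresholds AP thresholds (0.50 to 0.95, step 0.05).
#' @param max_dets detections kept per image (100).
#' @export
eval_protocol <- function(input_side = 512L, confidence_threshold = 0.05,
                          nms_threshold = 0.5,
                          iou_thresholds = seq(0.5, 0.95, by = 0.05),
                          max_dets = 100L) {
  stopifnot(!is.unsorted(iou_thresholds), length(iou_thresholds) == 10L)
  structure(list(input_side = as.integer(input_side),
                 confidence_threshold = confidence_threshold,
                 nms_threshold = nms_threshold,
                 iou_thresholds = iou_thresholds,
                 max_dets = as.integer(max_dets)),
            class = "eval_protocol")
}

# scale bucket boundaries in pixels^2: 32^2 and 96^2
.area_small <- 1024
.area_medium <- 9216

#' Classify object scale from bounding-box area
#'
#' small: area < 1024 px^2; medium: 1024 <= area < 9216; large: area >= 9216.
#' @param area numeric vector of areas (pixels^2).
#' @return character vector in {"small", "medium", "large"}.
#' @export
classify_scale <- function(area) {
  stopifnot(all(area >= 0))
  ifelse(area < .area_small, "small",
         ifelse(area < .area_medium, "medium", "large"))
}

#' Greedy non-maximum suppression
#'
#' @param boxes n x 4 (x1, y1, x2, y2).
#' @param scores numeric vector.
#' @param thr IoU threshold.
#' @return indices of kept boxes (score order).
#' @export
nms <- function(boxes, scores, thr = 0.5) {
  boxes <- rbind2m(boxes)
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1]
    iou <- iou_matrix(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])[1, ]
    ord <- rest[iou <= thr]
  }
  keep
}

# per-image greedy matching of ranked detections to GTs at one IoU threshold;
# returns list(dt_match, dt_ignore) given gt ignore flags (gts sorted so that
# non-ignored come first)
.match_image <- function(iou, gt_ig, thr) {
  nd <- nrow(iou); ng <- ncol(iou)
  gt_taken <- rep(FALSE, ng)
  dt_match <- rep(0L, nd); dt_ig <- rep(FALSE, nd)
  for (d in seq_len(nd)) {
    best <- thr - 1e-10; m <- 0L
    for (g in seq_len(ng)) {
      if (gt_taken[g]) next
      if (m > 0L && !gt_ig[m] && gt_ig[g]) break
      if (iou[d, g] < best) next
      best <- iou[d, g]; m <- g
    }
    if (m > 0L) {
      gt_taken[m] <- TRUE
      dt_match[d] <- m
      dt_ig[d] <- gt_ig[m]
    }
  }
  list(match = dt_match, ignore = dt_ig)
}

#' COCO average precision over a detection set
#'
#' Implements the standard protocol: per class and IoU threshold, detections
#' are greedily matched image-by-image in score order; precision is
#' interpolated monotonically and sampled at 101 recall points; classes with
#' no ground truth are excluded from the mean. Scale-bucketed variants
#' evaluate with out-of-bucket ground truths (and their matched or
#' out-of-bucket unmatched detections) ignored.
#'
#' @param detections data.frame with image_id, category_id, score, x, y, w, h.
#' @param ground_truths data.frame with image_id, category_id, x, y, w, h.
#' @param protocol an [eval_protocol()].
#' @return an `ap_report` list: AP, AP50, AP75, AP_S, AP_M, AP_L (percent),
#'   per-class APs, and bucket counts.
#' @export
coco_ap <- function(detections, ground_truths, protocol = eval_protocol()) {
  Tn <- protocol$iou_thresholds
  rec_thrs <- seq(0, 1, by = 0.01)
  classes <- sort(unique(ground_truths$category_id))
  areas <- list(all = c(0, Inf), small = c(0, .area_small),
                medium = c(.area_small, .area_medium),
                large = c(.area_medium, Inf))
  # precision[t, r, class, area]
  prec <- array(NA_real_, c(length(Tn), length(rec_thrs), length(classes), length(areas)))
  gt_area <- ground_truths$w * ground_truths$h
  dt_area <- if (nrow(detections)) detections$w * detections$h else numeric(0)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    gtc <- ground_truths[ground_truths$category_id == cl, , drop = FALSE]
    gac <- gt_area[ground_truths$category_id == cl]
    dtc <- detections[detections$category_id == cl, , drop = FALSE]
    dac <- dt_area[detections$category_id == cl]
    for (ai in seq_along(areas)) {
      rng <- areas[[ai]]
      ev <- list()
      for (img in unique(c(gtc$image_id, dtc$image_id))) {
        g <- gtc[gtc$image_id == img, , drop = FALSE]
        ga <- gac[gtc$image_id == img]
        d <- dtc[dtc$image_id == img, , drop = FALSE]
        da <- dac[dtc$image_id == img]
        ord <- order(d$score, decreasing = TRUE)
        if (length(ord) > protocol$max_dets) ord <- ord[seq_len(protocol$max_dets)]
        d <- d[ord, , drop = FALSE]; da <- da[ord]
        g_ig <- !(ga >= rng[1] & ga < rng[2])
        gord <- order(g_ig)
        g <- g[gord, , drop = FALSE]; g_ig <- g_ig[gord]
        iou <- if (nrow(d) && nrow(g))
          iou_matrix(box_xywh_to_xyxy(as.matrix(d[, c("x", "y", "w", "h")])),
                     box_xywh_to_xyxy(as.matrix(g[, c("x", "y", "w", "h")])))
        else matrix(0, nrow(d), nrow(g))
        ev[[length(ev) + 1L]] <- list(scores = d$score, iou = iou, g_ig = g_ig,
                                      d_out = !(da >= rng[1] & da < rng[2]))
      }
      npig <- sum(vapply(ev, function(e) sum(!e$g_ig), numeric(1)))
      if (npig == 0) next
      for (ti in seq_along(Tn)) {
        scores <- numeric(0); tp <- logical(0); ig <- logical(0)
        for (e in ev) {
          mm <- .match_image(e$iou, e$g_ig, Tn[ti])
          d_ig <- mm$ignore | (mm$match == 0L & e$d_out)
          scores <- c(scores, e$scores)
          tp <- c(tp, mm$match > 0L & !d_ig)
          ig <- c(ig, d_ig)
        }
        ord <- order(scores, decreasing = TRUE)
        tp <- tp[ord]; ig <- ig[ord]
        tp <- tp[!ig]
        ctp <- cumsum(tp); cfp <- cumsum(!tp)
        rc <- ctp / npig
        pr <- ctp / pmax(ctp + cfp, 1e-12)
        # monotone interpolation from the right
        if (length(pr)) for (i in rev(seq_len(length(pr) - 1L)))
          if (pr[i] < pr[i + 1L]) pr[i] <- pr[i + 1L]
        q <- rep(0, length(rec_thrs))
        if (length(rc)) {
          pos <- findInterval(rec_thrs, rc, left.open = TRUE) + 1L
          ok <- pos <= length(pr)
          q[ok] <- pr[pos[ok]]
        }
        prec[ti, , ci, ai] <- q
      }
    }
  }
  mean_ap <- function(ti = NULL, ai = 1L) {
    x <- prec[if (is.null(ti)) seq_along(Tn) else ti, , , ai, drop = FALSE]
    if (all(is.na(x))) return(NA_real_)
    100 * mean(x, na.rm = TRUE)
  }
  per_class <- vapply(seq_along(classes), function(ci) {
    x <- prec[, , ci, 1L]
    if (all(is.na(x))) NA_real_ else 100 * mean(x, na.rm = TRUE)
  }, numeric(1))
  names(per_class) <- as.character(classes)
  buckets <- table(factor(classify_scale(gt_area),
                          levels = c("small", "medium", "large")))
  structure(list(AP = mean_ap(), AP50 = mean_ap(which(abs(Tn - 0.5) < 1e-9)),
                 AP75 = mean_ap(which(abs(Tn - 0.75) < 1e-9)),
                 AP_S = mean_ap(ai = 2L), AP_M = mean_ap(ai = 3L),
                 AP_L = mean_ap(ai = 4L), per_class = per_class,
                 bucket_counts = buckets, n_gt = nrow(ground_truths),
                 n_det = nrow(detections)),
            class = "ap_report")
}

#' @export
print.ap_report <- function(x, digits = 1, ...) {
  cat(sprintf("AP %.1f | AP50 %.1f | AP75 %.1f | AP_S %s | AP_M %s | AP_L %s (%%)\n",
              x$AP, x$AP50, x$AP75,
              ifelse(is.na(x$AP_S), "-", sprintf("%.1f", x$AP_S)),
              ifelse(is.na(x$AP_M), "-", sprintf("%.1f", x$AP_M)),
              ifelse(is.na(x$AP_L), "-", sprintf("%.1f", x$AP_L))))
  invisible(x)
}

#' Evaluate a detector on a COCO-format dataset
#'
#' Pipeline per the fixed protocol: resize to the evaluation side, forward
#' pass, confidence threshold 0.05, class-wise NMS at 0.5, keep the top 100
#' detections, then COCO AP. Corrupt images are skipped with a warning and
#' counted in the report.
#'
#' @param model a `soystage_model`.
#' @param dataset either a directory produced by [generate_dataset()] plus a
#'   `split`, or an in-memory dataset list from [generate_dataset()].
#' @param protocol an [eval_protocol()].
#' @param split which annotation split to use.
#' @return an `ap_report` with attribute "skipped" (corrupt image count).
#' @export
evaluate_model <- function(model, dataset, protocol = eval_protocol(),
                           split = "val") {
  if (is.character(dataset)) {
    coco <- read_coco(file.path(dataset, "annotations",
                                paste0("instances_", split, ".json")))
    get_image <- function(fn) png::readPNG(file.path(dataset, "images", fn))
  } else {
    coco <- read_coco(dataset$splits[[split]])
    get_image <- function(fn) {
      i <- as.integer(sub("img_0*([0-9]+)\\.png", "\\1", fn))
      dataset$samples[[i]]$image
    }
  }
  dets <- list(); skipped <- 0L
  for (r in seq_len(nrow(coco$images))) {
    info <- coco$images[r, ]
    img <- tryCatch(get_image(info$file_name), error = function(e) NULL)
    if (is.null(img) || length(dim(img)) < 3) {
      warning("skipping unreadable image ", info$file_name)
      skipped <- skipped + 1L
      next
    }
    d <- predict(model, img, protocol = protocol)
    if (nrow(d)) {
      d$image_id <- info$id
      dets[[length(dets) + 1L]] <- d
    }
  }
  dets <- if (length(dets)) do.call(rbind, dets)
  else data.frame(image_id = integer(0), category_id = integer(0),
                  score = numeric(0), x = numeric(0), y = numeric(0),
                  w = numeric(0), h = numeric(0))
  rep <- coco_ap(dets, coco$annotations, protocol)
  attr(rep, "skipped") <- skipped
  rep
}
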