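# Shared small utilities: box geometry, seeds, image helpers.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All random streams in the package (weight init, denoising, augmentation,
#' scene generation) are derived from one master seed via named substreams so
#' that components can be re-run independently without correlating draws.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) %% 1000000007 * 31 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# --- bounding boxes ---------------------------------------------------------
# Internal convention: normalized (cx, cy, w, h) in [0,1]. COCO I/O uses
# absolute top-left (x, y, w, h). Geometry helpers work on (x1,y1,x2,y2).

#' Convert boxes between common conventions
#'
#' @param b numeric matrix with one box per row (or a length-4 vector).
#' @name box_convert
#' @return matrix of converted boxes.
#' @export
box_cxcywh_to_xyxy <- function(b) {
  b <- rbind2m(b)
  cbind(b[, 1] - b[, 3] / 2, b[, 2] - b[, 4] / 2,
        b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

#' @rdname box_convert
#' @export
box_xyxy_to_cxcywh <- function(b) {
  b <- rbind2m(b)
  cbind((b[, 1] + b[, 3]) / 2, (b[, 2] + b[, 4]) / 2,
        b[, 3] - b[, 1], b[, 4] - b[, 2])
}

#' @rdname box_convert
#' @export
box_xywh_to_xyxy <- function(b) {
  b <- rbind2m(b)
  cbind(b[, 1], b[, 2], b[, 1] + b[, 3], b[, 2] + b[, 4])
}

#' @rdname box_convert
#' @export
box_xyxy_to_xywh <- function(b) {
  b <- rbind2m(b)
  cbind(b[, 1], b[, 2], b[, 3] - b[, 1], b[, 4] - b[, 2])
}

rbind2m <- function(b) {
  if (is.null(dim(b))) matrix(b, nrow = 1) else as.matrix(b)
}

#' Pairwise intersection-over-union of two box sets
#'
#' @param a,b matrices of boxes in (x1,y1,x2,y2) rows.
#' @return an nrow(a) x nrow(b) IoU matrix.
#' @export
iou_matrix <- function(a, b) {
  a <- rbind2m(a); b <- rbind2m(b)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  area_a <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  area_b <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  for (j in seq_len(m)) {
    ix <- pmax(0, pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1]))
    iy <- pmax(0, pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2]))
    inter <- ix * iy
    out[, j] <- inter / pmax(area_a + area_b[j] - inter, 1e-12)
  }
  out
}

#' Generalized IoU between paired boxes
#'
#' GIoU = IoU − |C \\ (A ∪ B)| / |C| with C the smallest enclosing box;
#' ranges over (−1, 1], equals 1 only for identical boxes.
#'
#' @param a,b matrices of paired boxes in (x1,y1,x2,y2) rows.
#' @param eps area guard for degenerate boxes.
#' @return numeric vector of GIoU values.
#' @export
giou_pairwise <- function(a, b, eps = 1e-9) {
  a <- rbind2m(a); b <- rbind2m(b)
  area_a <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  area_b <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  ix <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  iy <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- ix * iy
  union <- area_a + area_b - inter
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  enc <- pmax(cw * ch, eps)
  inter / pmax(union, eps) - (enc - union) / enc
}

inverse_sigmoid <- function(p, eps = 1e-5) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# --- images -----------------------------------------------------------------
# Images travel as (H, W, 3) arrays in [0, 1] (the png package layout).

imagenet_mean <- c(0.485, 0.456, 0.406)
imagenet_std <- c(0.229, 0.224, 0.225)

# (H, W, 3) [0,1] -> normalized channel-major matrix (3, H*W) with H fastest
image_to_feature <- function(img, mean = imagenet_mean, std = imagenet_std) {
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- matrix(0, 3, H * W)
  for (c in 1:3) out[c, ] <- (as.vector(img[, , c]) - mean[c]) / std[c]
  out
}

#' Bilinear image resize
#'
#' @param img (H, W, 3) array in [0, 1].
#' @param out_h,out_w output dimensions in pixels.
#' @return resized (out_h, out_w, 3) array.
#' @export
resize_image <- function(img, out_h, out_w) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ys <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(xs), 1), W); x1 <- pmin(x0 + 1, W)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) {
    ch <- img[, , c]
    a <- ch[y0, x0, drop = FALSE]; b <- ch[y0, x1, drop = FALSE]
    d <- ch[y1, x0, drop = FALSE]; e <- ch[y1, x1, drop = FALSE]
    top <- a * outer(rep(1, out_h), 1 - fx) + b * outer(rep(1, out_h), fx)
    bot <- d * outer(rep(1, out_h), 1 - fx) + e * outer(rep(1, out_h), fx)
    out[, , c] <- top * outer(1 - fy, rep(1, out_w)) + bot * outer(fy, rep(1, out_w))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
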