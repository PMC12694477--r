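# Procedural synthetic greenhouse scenes: one (or a few) soybean plants per
# image, drawn as simple 2-D glyph compositions whose structure and size are
# conditioned on the ordinal growth stage, with COCO-format annotations.
# The goal is pipeline exercise with class-conditional structure (stage
# frequencies, stage-correlated object size, varied backgrounds/lighting),
# not photorealism.

#' The nine ordinal growth-stage classes
#'
#' Reference per-class image counts follow the source dataset distribution
#' (17,204 images total; one annotated plant per image).
#'
#' @return data.frame with index (0-based ordinal), name, count, description.
#' @export
stage_classes <- function() {
  data.frame(
    index = 0:8,
    name = c("VE", "VC", "V1", "V2", "V3+", "R1-R2", "R3-R5", "R6-R7", "R8"),
    count = c(307, 844, 2597, 1035, 2909, 2195, 2220, 3810, 1287),
    description = c("Emergence", "Cotyledon stage", "First trifoliate leaf",
                    "Second trifoliate leaf", "Third trifoliate leaf",
                    "Flowering stages", "Pod formation to seed fill",
                    "Beginning maturity to physiological maturity",
                    "Full maturity"),
    stringsAsFactors = FALSE)
}

#' Reference per-class image counts
#' @export
stage_class_counts <- function() {
  sc <- stage_classes()
  stats::setNames(sc$count, sc$name)
}

#' Sample growth stages from a class distribution
#'
#' @param n number of draws.
#' @param distribution per-class weights (defaults to the reference counts).
#' @return integer vector of 0-based stage ordinals.
#' @export
sample_stage <- function(n, distribution = stage_class_counts()) {
  p <- distribution / sum(distribution)
  sample(0:(length(p) - 1L), n, replace = TRUE, prob = p)
}

#' Scene specification for the synthetic generator
#'
#' @param side canvas side in pixels (512 matches the working resolution).
#' @param plants_per_image plants drawn per scene (default 1, matching the
#'   single-plant capture setting; >1 available for robustness tests).
#' @param small_fraction fraction of scenes drawn miniature so the sub-1024
#'   px^2 scale bucket is exercised (default 0.02).
#' @param lighting_jitter multiplicative brightness jitter range.
#' @export
scene_spec <- function(side = 512L, plants_per_image = 1L,
                       small_fraction = 0.02, lighting_jitter = 0.25) {
  stopifnot(side >= 32, plants_per_image >= 1, small_fraction >= 0,
            small_fraction <= 1)
  structure(list(side = as.integer(side),
                 plants_per_image = as.integer(plants_per_image),
                 small_fraction = small_fraction,
                 lighting_jitter = lighting_jitter),
            class = "scene_spec")
}

# draw an ellipse into mask/color accumulators (matrices are side x side)
.ellipse_mask <- function(xx, yy, cx, cy, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  u <- (xx - cx) * ct + (yy - cy) * st
  v <- -(xx - cx) * st + (yy - cy) * ct
  (u / a)^2 + (v / b)^2 <= 1
}

#' Render a synthetic plant scene
#'
#' Glyph structure follows phenology: leaf-cluster count grows through the
#' vegetative ordinals, flowering stages add blossom dots, podding stages add
#' elongated pod glyphs, and the maturity stages ramp the palette from green
#' to brown. The bounding box is computed from the rendered mask, and object
#' area correlates with the ordinal (early stages medium-bucket, reproductive
#' stages mostly large).
#'
#' @param stage 0-based stage ordinal (or vector of length plants_per_image).
#' @param spec a [scene_spec()].
#' @return list with `image` (side x side x 3 in [0,1]), `boxes`
#'   (n x 4 absolute x, y, w, h), `labels` (0-based ordinals).
#' @export
render_scene <- function(stage, spec = scene_spec()) {
  S <- spec$side
  stages <- rep_len(stage, spec$plants_per_image)
  xx <- matrix(rep(seq_len(S), each = S), S, S)   # column (x) index
  yy <- matrix(rep(seq_len(S), S), S, S)          # row (y) index
  # background: soil / bench tones with a vertical gradient and speckle
  base <- c(stats::runif(1, 0.32, 0.52), stats::runif(1, 0.26, 0.44),
            stats::runif(1, 0.16, 0.34))
  grad <- stats::runif(1, -0.1, 0.1)
  img <- array(0, c(S, S, 3))
  for (c in 1:3)
    img[, , c] <- base[c] + grad * (yy / S - 0.5) +
      matrix(stats::rnorm(S * S, 0, 0.02), S, S)
  boxes <- NULL; labels <- integer(0)
  for (pi in seq_along(stages)) {
    o <- stages[pi]
    mini <- stats::runif(1) < spec$small_fraction
    # target box side as a fraction of the canvas, growing with the ordinal
    frac <- if (mini) stats::runif(1, 0.03, 0.055)
            else (0.20 + 0.047 * o) * stats::runif(1, 0.85, 1.15)
    half <- max(4, frac * S / 2)
    ok <- FALSE
    for (try in 1:10) {
      cx <- stats::runif(1, half + 2, S - half - 2)
      cy <- stats::runif(1, half + 2, S - half - 2)
      if (cx > 1 && cx < S && cy > 1 && cy < S) { ok <- TRUE; break }
    }
    if (!ok) next
    mask <- matrix(FALSE, S, S)
    ramp <- if (o == 7) 0.45 else if (o == 8) 0.85 else 0
    leafcol <- (1 - ramp) * c(0.18, 0.55, 0.16) + ramp * c(0.45, 0.33, 0.12)
    stemcol <- (1 - ramp) * c(0.25, 0.42, 0.15) + ramp * c(0.42, 0.30, 0.12)
    paint <- function(m, col, jit = 0.06) {
      col <- pmin(pmax(col + stats::rnorm(3, 0, jit), 0), 1)
      for (c in 1:3) img[, , c][m] <<- col[c]
      mask <<- mask | m
    }
    # stem
    paint(.ellipse_mask(xx, yy, cx, cy + half * 0.2, half * 0.08, half * 0.75, 0),
          stemcol)
    # leaf clusters: sprout for VE, growing rosette afterwards
    nleaf <- if (o == 0) 1L else min(2L + o, 8L)
    la <- half * (if (o == 0) 0.45 else 0.52)
    for (l in seq_len(nleaf)) {
      ang <- 2 * pi * l / nleaf + stats::runif(1, -0.4, 0.4)
      r <- half * stats::runif(1, 0.25, 0.62)
      paint(.ellipse_mask(xx, yy, cx + r * cos(ang), cy - half * 0.15 + r * sin(ang) * 0.8,
                          la * stats::runif(1, 0.7, 1), la * stats::runif(1, 0.45, 0.7),
                          ang), leafcol)
    }
    if (o == 5) {                       # flowering: blossom dots
      for (f in seq_len(sample(3:6, 1)))
        paint(.ellipse_mask(xx, yy, cx + stats::runif(1, -half, half) * 0.6,
                            cy + stats::runif(1, -half, half) * 0.6,
                            half * 0.08, half * 0.08, 0),
              c(0.95, 0.92, 0.75), jit = 0.02)
    }
    if (o %in% 6:8) {                   # pods: elongated glyphs
      podcol <- (1 - ramp) * c(0.25, 0.5, 0.2) + ramp * c(0.4, 0.28, 0.1)
      for (f in seq_len(sample(3:7, 1)))
        paint(.ellipse_mask(xx, yy, cx + stats::runif(1, -half, half) * 0.55,
                            cy + stats::runif(1, -half, half) * 0.55,
                            half * 0.22, half * 0.07, stats::runif(1, 0, pi)),
              podcol)
    }
    if (!any(mask)) next
    cols <- range(which(apply(mask, 2, any)))
    rows <- range(which(apply(mask, 1, any)))
    boxes <- rbind(boxes, c(cols[1] - 1, rows[1] - 1,
                            cols[2] - cols[1] + 1, rows[2] - rows[1] + 1))
    labels <- c(labels, o)
  }
  light <- 1 + stats::runif(1, -spec$lighting_jitter, spec$lighting_jitter)
  img <- pmin(pmax(img * light, 0), 1)
  list(image = img, boxes = if (is.null(boxes)) matrix(0, 0, 4) else boxes,
       labels = labels)
}

#' Train/val/test split sizes under the floor-then-remainder rule
#'
#' train = floor(r1 n), val = floor(r2 n), test = the remainder, so the three
#' parts always sum to n.
#'
#' @param n total image count.
#' @param ratios length-3 ratios summing to 1.
#' @return named integer vector (train, val, test).
#' @export
split_counts <- function(n, ratios = c(0.8, 0.1, 0.1)) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9)
  tr <- floor(ratios[1] * n)
  va <- floor(ratios[2] * n)
  c(train = as.integer(tr), val = as.integer(va), test = as.integer(n - tr - va))
}

#' Generate a synthetic COCO-format dataset
#'
#' Draws a growth stage per image from the class distribution, renders the
#' scene, and writes PNG images plus three COCO JSON annotation files
#' (train/val/test, floor-then-remainder split). Categories are ordered
#' VE through R8 with 0-based contiguous ids; boxes are absolute top-left
#' (x, y, w, h) pixels.
#'
#' @param n_images total images.
#' @param dir output directory (created); NULL keeps the dataset in memory.
#' @param distribution per-class weights.
#' @param spec a [scene_spec()].
#' @param seed master seed; scenes derive per-image substreams.
#' @param split_ratios train/val/test ratios.
#' @return (invisibly) a list with per-split COCO structures and, for
#'   in-memory datasets, the rendered samples.
#' @export
generate_dataset <- function(n_images, dir = NULL,
                             distribution = stage_class_counts(),
                             spec = scene_spec(), seed = 1L,
                             split_ratios = c(0.8, 0.1, 0.1)) {
  if (n_images < length(distribution))
    warning("fewer images than classes; some classes will be absent")
  stages <- with_seed(derive_seed(seed, "stages"),
                      sample_stage(n_images, distribution))
  keep <- is.null(dir)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
  }
  cats <- lapply(seq_len(nrow(stage_classes())), function(i)
    list(id = stage_classes()$index[i], name = stage_classes()$name[i],
         supercategory = "soybean"))
  images <- vector("list", n_images)
  anns <- list()
  samples <- if (keep) vector("list", n_images) else NULL
  aid <- 0L
  for (i in seq_len(n_images)) {
    sc <- with_seed(derive_seed(seed, paste0("scene", i)),
                    render_scene(stages[i], spec))
    fn <- sprintf("img_%06d.png", i)
    if (!is.null(dir))
      png::writePNG(sc$image, file.path(dir, "images", fn))
    if (keep) samples[[i]] <- sc
    images[[i]] <- list(id = i, file_name = fn,
                        width = spec$side, height = spec$side)
    for (j in seq_len(nrow(sc$boxes))) {
      aid <- aid + 1L
      anns[[aid]] <- list(id = aid, image_id = i,
                          category_id = sc$labels[j],
                          bbox = as.numeric(sc$boxes[j, ]),
                          area = sc$boxes[j, 3] * sc$boxes[j, 4],
                          iscrowd = 0L)
    }
  }
  ord <- with_seed(derive_seed(seed, "split"), sample.int(n_images))
  cnt <- split_counts(n_images, split_ratios)
  idx <- list(train = ord[seq_len(cnt["train"])],
              val = ord[cnt["train"] + seq_len(cnt["val"])],
              test = ord[cnt["train"] + cnt["val"] + seq_len(cnt["test"])])
  splits <- lapply(idx, function(ii) {
    list(images = images[sort(ii)],
         annotations = Filter(function(a) a$image_id %in% ii, anns),
         categories = cats)
  })
  if (!is.null(dir)) {
    for (s in names(splits))
      jsonlite::write_json(splits[[s]],
                           file.path(dir, "annotations", paste0("instances_", s, ".json")),
                           auto_unbox = TRUE, digits = NA)
  }
  invisible(list(splits = splits, stages = stages, samples = samples,
                 spec = spec, dir = dir))
}

#' Read a COCO annotation file into flat data frames
#'
#' @param path JSON file path (or an already-parsed list).
#' @return list with `images`, `annotations` (bbox columns x,y,w,h) and
#'   `categories` data frames.
#' @export
read_coco <- function(path) {
  j <- if (is.character(path)) jsonlite::read_json(path) else path
  imgs <- do.call(rbind, lapply(j$images, function(x)
    data.frame(id = x$id, file_name = x$file_name, width = x$width,
               height = x$height, stringsAsFactors = FALSE)))
  anns <- if (length(j$annotations))
    do.call(rbind, lapply(j$annotations, function(a)
      data.frame(id = a$id, image_id = a$image_id, category_id = a$category_id,
                 x = a$bbox[[1]], y = a$bbox[[2]], w = a$bbox[[3]],
                 h = a$bbox[[4]], area = a$area %||% (a$bbox[[3]] * a$bbox[[4]]),
                 iscrowd = a$iscrowd %||% 0L)))
  else data.frame(id = integer(0), image_id = integer(0), category_id = integer(0),
                  x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
                  area = numeric(0), iscrowd = integer(0))
  cats <- do.call(rbind, lapply(j$categories, function(x)
    data.frame(id = x$id, name = x$name, stringsAsFactors = FALSE)))
  list(images = imgs, annotations = anns, categories = cats)
}

#' Overlay detection boxes on an image (simple utility renderer)
#'
#' @param image (H, W, 3) array.
#' @param boxes n x 4 absolute (x, y, w, h).
#' @param color RGB triple in [0,1].
#' @param thickness outline width in pixels.
#' @return image array with box outlines drawn.
#' @export
draw_boxes <- function(image, boxes, color = c(1, 0, 0), thickness = 2L) {
  boxes <- rbind2m(boxes)
  H <- dim(image)[1]; W <- dim(image)[2]
  for (i in seq_len(nrow(boxes))) {
    x1 <- max(1L, round(boxes[i, 1])); y1 <- max(1L, round(boxes[i, 2]))
    x2 <- min(W, round(boxes[i, 1] + boxes[i, 3]))
    y2 <- min(H, round(boxes[i, 2] + boxes[i, 4]))
    for (t in seq_len(thickness) - 1L) {
      ys <- c(pmin(pmax(y1 + t, 1), H), pmin(pmax(y2 - t, 1), H))
      xs <- c(pmin(pmax(x1 + t, 1), W), pmin(pmax(x2 - t, 1), W))
      for (c in 1:3) {
        image[ys, x1:x2, c] <- color[c]
        image[y1:y2, xs, c] <- color[c]
      }
    }
  }
  image
}
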