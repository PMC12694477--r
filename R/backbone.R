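# Compound-scaled inverted-bottleneck backbone (EfficientNet family),
# truncated for detection: stem + seven MBConv stages. The conventional final
# 1x1 expansion conv is NOT part of the backbone proper (the truncation that
# makes the published per-variant parameter counts exact); it can be retained
# as a separate checkpoint-compatibility component so classification
# checkpoints load without surgery.

#' Compound scaling configuration
#'
#' Depth, width and resolution scale as alpha^phi, beta^phi, gamma^phi with
#' the constraint alpha * beta^2 * gamma^2 ~ 2 so FLOPs grow ~2^phi.
#'
#' @param phi compound coefficient.
#' @param alpha,beta_w,gamma depth/width/resolution bases (defaults are the
#'   canonical grid-search values 1.2 / 1.1 / 1.15).
#' @return a `scaling_config` list with resolved depth/width multipliers.
#' @export
scaling_config <- function(phi = 0, alpha = 1.2, beta_w = 1.1, gamma = 1.15) {
  stopifnot(alpha >= 1, beta_w >= 1, gamma >= 1)
  prod <- alpha * beta_w^2 * gamma^2
  if (prod < 1.9 || prod > 2.1)
    stop("alpha * beta_w^2 * gamma^2 must lie in [1.9, 2.1]; got ", round(prod, 4))
  structure(list(phi = phi, alpha = alpha, beta_w = beta_w, gamma = gamma,
                 depth = alpha^phi, width = beta_w^phi, resolution = gamma^phi),
            class = "scaling_config")
}

# canonical width/depth multipliers and native resolutions per variant
.variant_table <- list(
  B3 = list(width = 1.2, depth = 1.4, resolution = 300,
            stage_channels = c(`2` = 32, `3` = 48, `4` = 136, `5` = 384),
            expected_params_M = 10.1),
  B5 = list(width = 1.6, depth = 2.2, resolution = 456,
            stage_channels = c(`2` = 40, `3` = 64, `4` = 176, `5` = 512),
            expected_params_M = 27.29),
  B7 = list(width = 2.0, depth = 3.1, resolution = 600,
            stage_channels = c(`2` = 48, `3` = 80, `4` = 224, `5` = 640),
            expected_params_M = 62.14),
  # miniature configuration for CPU smoke runs and unit tests
  tiny = list(width = 0.25, depth = 0.30, resolution = 128,
              stage_channels = NULL, expected_params_M = NA)
)

# base (phi = 0) stage layout: expansion, kernel, stride, channels, repeats
.base_stages <- data.frame(
  t = c(1, 6, 6, 6, 6, 6, 6),
  k = c(3, 3, 5, 3, 5, 5, 3),
  s = c(1, 2, 2, 2, 1, 2, 1),
  c = c(16, 24, 40, 80, 112, 192, 320),
  n = c(1, 2, 2, 3, 3, 4, 1))
.base_stem <- 32
.base_head <- 1280

# detection stage index (stride 4/8/16/32) -> canonical MBConv stage
.stage_map <- c(`2` = 2L, `3` = 3L, `4` = 5L, `5` = 7L)

#' Width rounding used by compound scaling
#'
#' Filters scale by the width multiplier, snap to the nearest multiple of 8,
#' and never drop below 90% of the unrounded value.
#' @param c base channel count.
#' @param w width multiplier.
#' @param divisor snapping divisor.
#' @export
round_filters <- function(c, w, divisor = 8L) {
  v <- c * w
  new <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (new < 0.9 * v) new <- new + divisor
  as.integer(new)
}

#' Depth rounding used by compound scaling
#' @param n base repeat count.
#' @param d depth multiplier.
#' @export
round_repeats <- function(n, d) as.integer(ceiling(d * n))

#' Backbone variant specification
#'
#' Resolves a named variant (B3 / B5 / B7 / tiny) to its width/depth
#' multipliers, per-stage channels at the detection strides 4/8/16/32, and
#' total truncated parameter count.
#'
#' @param name one of "B3", "B5", "B7", "tiny".
#' @return a `variant_spec` list.
#' @export
variant_spec <- function(name) {
  if (inherits(name, "variant_spec")) return(name)
  vt <- .variant_table[[name]]
  if (is.null(vt)) stop("unknown backbone variant: ", name)
  w <- vt$width; d <- vt$depth
  ch <- vapply(names(.stage_map), function(si)
    round_filters(.base_stages$c[.stage_map[[si]]], w), integer(1))
  names(ch) <- names(.stage_map)
  if (!is.null(vt$stage_channels) && !all(ch == vt$stage_channels))
    stop("stage channels for ", name, " do not match the reference table")
  structure(list(name = name, width = w, depth = d, resolution = vt$resolution,
                 stage_channels = ch, expected_params_M = vt$expected_params_M),
            class = "variant_spec")
}

#' MBConv block specification
#'
#' @param t expansion ratio (>= 1).
#' @param k depthwise kernel size, 3 or 5.
#' @param s stride, 1 or 2.
#' @param in_channels,out_channels channel counts.
#' @param se_reduction squeeze-and-excitation reduction ratio (default 4);
#'   the squeeze width is computed from the block input channels.
#' @return an `mbconv_spec` list; the residual path is active iff s = 1 and
#'   in_channels = out_channels.
#' @export
mbconv_spec <- function(t, k, s, in_channels, out_channels, se_reduction = 4) {
  stopifnot(t >= 1, k %in% c(3L, 5L), s %in% c(1L, 2L),
            in_channels >= 1, out_channels >= 1, se_reduction >= 1)
  structure(list(t = t, k = as.integer(k), s = as.integer(s),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 se_reduction = se_reduction,
                 residual = s == 1L && in_channels == out_channels),
            class = "mbconv_spec")
}

# squeeze width: block input channels / reduction, rounded up, floor of 1
se_width <- function(cin, r) max(1L, as.integer(ceiling(cin / r)))

# expand the variant into a flat list of block specs with stage labels
backbone_blocks <- function(variant) {
  v <- variant_spec(variant)
  blocks <- list()
  cin <- round_filters(.base_stem, v$width)
  for (st in seq_len(7L)) {
    b <- .base_stages[st, ]
    cout <- round_filters(b$c, v$width)
    reps <- round_repeats(b$n, v$depth)
    for (r in seq_len(reps)) {
      blocks[[length(blocks) + 1L]] <- list(
        stage = st, rep = r,
        spec = mbconv_spec(b$t, b$k, if (r == 1L) b$s else 1L,
                           if (r == 1L) cin else cout, cout))
    }
    cin <- cout
  }
  list(stem_channels = round_filters(.base_stem, v$width),
       head_channels = round_filters(.base_head, v$width),
       blocks = blocks, variant = v)
}

# register parameters for one MBConv block; returns layer metadata list
mbconv_layers <- function(ps, prefix, spec) {
  cexp <- as.integer(spec$in_channels * spec$t)
  se <- se_width(spec$in_channels, spec$se_reduction)
  m <- list(spec = spec, cexp = cexp, se = se)
  if (spec$t > 1) {
    m$expand <- ly_conv(ps, paste0(prefix, ".expand"), spec$in_channels, cexp, 1L)
    m$expand_bn <- ly_bn(ps, paste0(prefix, ".expand_bn"), cexp)
  }
  m$dw <- ly_dwconv(ps, paste0(prefix, ".dw"), cexp, spec$k, spec$s)
  m$dw_bn <- ly_bn(ps, paste0(prefix, ".dw_bn"), cexp)
  m$se_fc1 <- ly_linear(ps, paste0(prefix, ".se_fc1"), cexp, se, bias = TRUE)
  m$se_fc2 <- ly_linear(ps, paste0(prefix, ".se_fc2"), se, cexp, bias = TRUE)
  m$proj <- ly_conv(ps, paste0(prefix, ".proj"), cexp, spec$out_channels, 1L)
  m$proj_bn <- ly_bn(ps, paste0(prefix, ".proj_bn"), spec$out_channels)
  m
}

mbconv_forward <- function(P, m, x, H, W, N) {
  spec <- m$spec
  h <- x
  if (spec$t > 1) {
    h <- f_conv(P, m$expand, h, H, W, N)$x
    h <- ad_silu(f_bn(P, m$expand_bn, h))
  }
  dw <- f_dwconv(P, m$dw, h, H, W, N)
  h <- ad_silu(f_bn(P, m$dw_bn, dw$x))
  Ho <- dw$H; Wo <- dw$W
  # squeeze-and-excitation gate
  z <- ad_gap(h, m$cexp, Ho * Wo, N)
  s <- ad_sigmoid(f_linear(P, m$se_fc2, ad_relu(f_linear(P, m$se_fc1, z))))
  h <- ad_mul(h, ad_rep_spatial(s, m$cexp, Ho * Wo, N))
  h <- f_bn(P, m$proj_bn, f_conv(P, m$proj, h, Ho, Wo, N)$x)
  if (spec$residual) h <- ad_add(h, x)
  list(x = h, H = Ho, W = Wo)
}

#' Build a multi-scale backbone
#'
#' @param variant "B3", "B5", "B7", "tiny" or a `variant_spec`.
#' @param out_indices detection stages to expose, subset of 2:5
#'   (strides 4/8/16/32).
#' @param include_head_conv keep the classification-side final 1x1 expansion
#'   conv as a checkpoint-compatibility component (never run during detection
#'   and excluded from the backbone parameter count).
#' @param seed optional seed for weight initialization.
#' @return a `backbone_model` with a parameter store and block metadata.
#' @export
build_backbone <- function(variant, out_indices = c(3L, 4L, 5L),
                           include_head_conv = TRUE, seed = NULL) {
  out_indices <- sort(unique(as.integer(out_indices)))
  if (length(out_indices) == 0L) stop("out_indices must be non-empty")
  if (!all(out_indices %in% 2:5)) stop("out_indices must be a subset of {2,3,4,5}")
  bb <- backbone_blocks(variant)
  build <- function() {
    ps <- param_store()
    metas <- list(
      stem = ly_conv(ps, "backbone.stem", 3L, bb$stem_channels, 3L, 2L),
      stem_bn = ly_bn(ps, "backbone.stem_bn", bb$stem_channels))
    metas$blocks <- lapply(seq_along(bb$blocks), function(i) {
      blk <- bb$blocks[[i]]
      mbconv_layers(ps, sprintf("backbone.s%d.b%d", blk$stage, blk$rep), blk$spec)
    })
    if (include_head_conv) {
      metas$head_conv <- ly_conv(ps, "compat.head_conv",
                                 bb$blocks[[length(bb$blocks)]]$spec$out_channels,
                                 bb$head_channels, 1L)
      metas$head_bn <- ly_bn(ps, "compat.head_bn", bb$head_channels)
    }
    list(ps = ps, metas = metas)
  }
  built <- if (is.null(seed)) build() else with_seed(seed, build())
  # canonical stage of the last block feeding each detection stage
  last_of_stage <- vapply(1:7, function(st)
    max(which(vapply(bb$blocks, function(b) b$stage == st, logical(1)))), integer(1))
  structure(list(ps = built$ps, metas = built$metas, layout = bb,
                 out_indices = out_indices,
                 tap_blocks = last_of_stage[.stage_map[as.character(out_indices)]],
                 variant = bb$variant),
            class = "backbone_model")
}

# forward over a batch laid out (3, H*W*N); returns features at out_indices
backbone_forward <- function(P, model, x, H, W, N) {
  metas <- model$metas
  st <- f_conv(P, metas$stem, x, H, W, N)
  h <- ad_silu(f_bn(P, metas$stem_bn, st$x))
  H <- st$H; W <- st$W
  taps <- model$tap_blocks
  feats <- list()
  for (i in seq_along(metas$blocks)) {
    r <- mbconv_forward(P, metas$blocks[[i]], h, H, W, N)
    h <- r$x; H <- r$H; W <- r$W
    hit <- which(taps == i)
    if (length(hit))
      feats[[as.character(model$out_indices[hit])]] <-
        list(x = h, H = H, W = W,
             C = model$layout$blocks[[i]]$spec$out_channels)
  }
  feats
}

#' Apply a single MBConv block to a feature tensor
#'
#' Functional form of the inverted-bottleneck block: 1x1 expansion, depthwise
#' conv, squeeze-and-excitation gate, 1x1 projection, with a residual iff the
#' stride is 1 and channel counts match.
#'
#' @param F_in (C, H, W) array with C = spec$in_channels.
#' @param spec an [mbconv_spec()].
#' @param params optional parameter list from [mbconv_init()]; random if NULL.
#' @return (C_out, H', W') array.
#' @export
mbconv_block <- function(F_in, spec, params = NULL) {
  d <- dim(F_in)
  if (d[1] != spec$in_channels)
    stop("input has ", d[1], " channels but spec expects ", spec$in_channels)
  if (is.null(params)) params <- mbconv_init(spec)
  ps <- param_store(); ps$arr <- params$arrays
  out <- mbconv_forward(params$P, params$meta, matrix(F_in, d[1], d[2] * d[3]),
                        d[2], d[3], 1L)
  array(vof(out$x), c(spec$out_channels, out$H, out$W))
}

#' Initialize parameters for a standalone MBConv block
#' @param spec an [mbconv_spec()].
#' @return a list with `P` (named arrays, modifiable) and layer metadata.
#' @export
mbconv_init <- function(spec) {
  ps <- param_store()
  meta <- mbconv_layers(ps, "blk", spec)
  list(P = ps$arr, meta = meta, arrays = ps$arr)
}

#' Squeeze-and-excitation channel gate
#'
#' Global average pool, bottleneck FC (width C / r, rounded up), ReLU, FC
#' back to C, sigmoid; input is rescaled channel-wise by the gate in (0, 1).
#'
#' @param F (C, H, W) array.
#' @param r reduction ratio.
#' @param params optional list with fc1_w, fc1_b, fc2_w, fc2_b.
#' @return list with `out` (gated tensor), `gate` (C vector) and `pooled`.
#' @export
se_gate <- function(F, r = 4, params = NULL) {
  C <- dim(F)[1]; H <- dim(F)[2]; W <- dim(F)[3]
  se <- se_width(C, r)
  if (is.null(params))
    params <- list(fc1_w = kaiming(se, C, C), fc1_b = rep(0, se),
                   fc2_w = kaiming(C, se, se), fc2_b = rep(0, C))
  z <- rowMeans(matrix(F, C, H * W))
  gate <- as.vector(1 / (1 + exp(-(params$fc2_w %*% pmax(params$fc1_w %*% z + params$fc1_b, 0) + params$fc2_b))))
  list(out = array(as.vector(F) * rep(gate, H * W), dim(F)), gate = gate, pooled = z)
}

#' Extract multi-scale stage features from an image
#'
#' @param model a `backbone_model` from [build_backbone()].
#' @param image (H, W, 3) array in [0, 1]; normalized internally.
#' @param mean,std per-channel normalization constants.
#' @return named list over requested stages; each entry holds the (C, H, W)
#'   feature array and its stride.
#' @export
extract_features <- function(model, image, mean = imagenet_mean, std = imagenet_std) {
  H <- dim(image)[1]; W <- dim(image)[2]
  old <- set_buffer_store(model$ps)
  on.exit(set_buffer_store(old))
  x <- image_to_feature(image, mean, std)
  feats <- backbone_forward(model$ps$arr, model, x, H, W, 1L)
  out <- lapply(names(feats), function(si) {
    f <- feats[[si]]
    structure(array(vof(f$x), c(f$C, f$H, f$W)), stride = 2L^as.integer(si))
  })
  names(out) <- names(feats)
  out
}

#' Expected feature-map sides for a square input
#'
#' Stride arithmetic with ceil-mode downsampling: stage i (stride 2^i) has
#' side ceiling(L / 2^i).
#' @param L input side in pixels.
#' @param stages detection stage indices.
#' @export
stage_sides <- function(L, stages = 2:5) {
  v <- vapply(stages, function(i) as.integer(ceiling(L / 2^i)), integer(1))
  names(v) <- as.character(stages)
  v
}

#' Closed-form trainable parameter count of the truncated backbone
#'
#' Counts the stem and the seven inverted-bottleneck stages only (no final
#' expansion conv, no classifier), matching the per-variant reference counts.
#'
#' @param variant variant name or spec.
#' @return exact integer parameter count.
#' @export
backbone_param_count <- function(variant) {
  bb <- backbone_blocks(variant)
  total <- 9 * 3 * bb$stem_channels + 2 * bb$stem_channels
  for (blk in bb$blocks) {
    s <- blk$spec
    cexp <- s$in_channels * s$t
    se <- se_width(s$in_channels, s$se_reduction)
    p <- 0
    if (s$t > 1) p <- p + s$in_channels * cexp + 2 * cexp
    p <- p + s$k^2 * cexp + 2 * cexp
    p <- p + cexp * se + se + se * cexp + cexp
    p <- p + cexp * s$out_channels + 2 * s$out_channels
    total <- total + p
  }
  total
}

#' Load backbone weights from a named list with strict mismatch reporting
#'
#' Intended for classification-pretrained checkpoints converted to a named R
#' list. Names follow the package convention ("backbone.s3.b1.dw.w", ...).
#' Entries for the truncated classification head ("compat.*", classifier) are
#' reported rather than silently dropped.
#'
#' @param model a `backbone_model`.
#' @param weights named list of arrays.
#' @param strict error on shape mismatches (dimension conflicts always error).
#' @return the model, invisibly; a report is attached as attribute "report".
#' @export
load_backbone_weights <- function(model, weights, strict = TRUE) {
  have <- names(model$ps$arr)
  got <- names(weights)
  missing <- setdiff(have, got)
  unexpected <- setdiff(got, have)
  loaded <- character(0)
  for (nm in intersect(have, got)) {
    cur <- model$ps$arr[[nm]]; new <- weights[[nm]]
    if (length(cur) != length(new))
      stop("shape mismatch for ", nm, ": have ", length(cur), ", got ", length(new))
    dim(new) <- dim(cur)
    model$ps$arr[[nm]] <- new
    loaded <- c(loaded, nm)
  }
  if (strict && length(missing))
    warning("missing weights for: ", paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5) else "")
  attr(model, "report") <- list(loaded = loaded, missing = missing, unexpected = unexpected)
  invisible(model)
}

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf("Truncated compound-scaled backbone %s: %d blocks, stages {%s}, %.2f M params\n",
              x$variant$name, length(x$layout$blocks),
              paste(x$out_indices, collapse = ","),
              backbone_param_count(x$variant) / 1e6))
  invisible(x)
}
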