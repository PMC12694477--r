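# Channel-mapper neck: per-level 1x1 projection of backbone stage features to
# a unified channel width, group normalization, and extra stride-2 pyramid
# levels. No lateral/top-down fusion by design.

#' Neck configuration
#'
#' @param in_channels named integer vector of input channels per backbone
#'   stage (names are stage indices, e.g. c(`3` = 48, `4` = 136, `5` = 384)).
#' @param out_channels unified channel width (default 256).
#' @param num_groups group-normalization groups (default 32); out_channels
#'   must be divisible by num_groups.
#' @param num_extra_levels extra stride-2 levels appended after the last
#'   mapped level (default 1, giving P6 from P5).
#' @return a `neck_config` list.
#' @export
neck_config <- function(in_channels, out_channels = 256L, num_groups = 32L,
                        num_extra_levels = 1L) {
  stopifnot(length(in_channels) >= 1, out_channels %% num_groups == 0,
            num_extra_levels >= 0)
  if (is.null(names(in_channels)))
    names(in_channels) <- as.character(seq(3, length.out = length(in_channels)))
  structure(list(in_channels = in_channels,
                 out_channels = as.integer(out_channels),
                 num_groups = as.integer(num_groups),
                 num_extra_levels = as.integer(num_extra_levels),
                 p6_kernel = 3L, eps = 1e-5),
            class = "neck_config")
}

#' Build the channel-mapper neck
#'
#' @param cfg a [neck_config()].
#' @param seed optional init seed.
#' @return a `neck_model` holding parameters and layer metadata.
#' @export
build_neck <- function(cfg, seed = NULL) {
  build <- function() {
    ps <- param_store()
    maps <- list(); gns <- list()
    for (i in seq_along(cfg$in_channels)) {
      st <- names(cfg$in_channels)[i]
      # mapping convs carry no bias: a norm layer follows, and the closed-form
      # parameter count sum(C_i * C_out) is then exact
      maps[[st]] <- ly_conv(ps, paste0("neck.map", st), cfg$in_channels[[i]],
                            cfg$out_channels, 1L, bias = FALSE)
      gns[[st]] <- ly_gn(ps, paste0("neck.gn", st), cfg$out_channels, cfg$num_groups)
    }
    extra <- list()
    for (e in seq_len(cfg$num_extra_levels)) {
      extra[[e]] <- list(
        conv = ly_conv(ps, paste0("neck.extra", e, ".conv"), cfg$out_channels,
                       cfg$out_channels, cfg$p6_kernel, 2L, bias = FALSE),
        gn = ly_gn(ps, paste0("neck.extra", e, ".gn"), cfg$out_channels, cfg$num_groups))
    }
    list(ps = ps, maps = maps, gns = gns, extra = extra)
  }
  b <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(ps = b$ps, maps = b$maps, gns = b$gns, extra = b$extra, cfg = cfg),
            class = "neck_model")
}

# batch forward: feats is the backbone_forward() output; returns pyramid
# levels in ascending stride order, each list(x, H, W, C, stride)
neck_forward <- function(P, neck, feats, N) {
  cfg <- neck$cfg
  lv <- list()
  for (st in names(cfg$in_channels)) {
    f <- feats[[st]]
    if (is.null(f)) stop("backbone did not provide stage ", st)
    if (f$C != cfg$in_channels[[st]])
      stop("stage ", st, " has ", f$C, " channels; neck expects ", cfg$in_channels[[st]])
    h <- f_conv(P, neck$maps[[st]], f$x, f$H, f$W, N)$x
    h <- f_gn(P, neck$gns[[st]], h, f$H * f$W, N, cfg$eps)
    lv[[length(lv) + 1L]] <- list(x = h, H = f$H, W = f$W, C = cfg$out_channels,
                                  stride = 2L^as.integer(st))
  }
  for (e in seq_along(neck$extra)) {
    top <- lv[[length(lv)]]
    r <- f_conv(P, neck$extra[[e]]$conv, top$x, top$H, top$W, N)
    h <- f_gn(P, neck$extra[[e]]$gn, r$x, r$H * r$W, N, cfg$eps)
    lv[[length(lv) + 1L]] <- list(x = h, H = r$H, W = r$W, C = cfg$out_channels,
                                  stride = top$stride * 2L)
  }
  lv
}

#' Project backbone stage features to the unified pyramid levels
#'
#' Applies the per-level 1x1 mapping conv and group normalization (no extra
#' levels; see [extend_pyramid()]).
#'
#' @param features named list of (C, H, W) stage feature arrays.
#' @param neck a `neck_model` (or a [neck_config()], in which case a neck is
#'   built with random weights).
#' @return named list of mapped (C_out, H, W) arrays.
#' @export
map_channels <- function(features, neck) {
  if (inherits(neck, "neck_config")) neck <- build_neck(neck)
  P <- neck$ps$arr
  feats <- lapply(features, function(a)
    list(x = matrix(a, dim(a)[1], dim(a)[2] * dim(a)[3]),
         H = dim(a)[2], W = dim(a)[3], C = dim(a)[1]))
  cfg0 <- neck$cfg
  out <- list()
  for (st in names(cfg0$in_channels)) {
    f <- feats[[st]]
    if (is.null(f)) stop("missing stage ", st)
    if (f$C != cfg0$in_channels[[st]])
      stop("stage ", st, ": channel mismatch")
    h <- f_conv(P, neck$maps[[st]], f$x, f$H, f$W, 1L)$x
    h <- f_gn(P, neck$gns[[st]], h, f$H * f$W, 1L, cfg0$eps)
    out[[paste0("P", st)]] <- array(vof(h), c(cfg0$out_channels, f$H, f$W))
  }
  out
}

#' Group normalization of a feature tensor
#'
#' Channels are split into G groups; each group is standardized over its
#' channels and all spatial positions, then an affine transform is applied.
#'
#' @param F (C, H, W) array.
#' @param G number of groups; C must be divisible by G.
#' @param gamma,beta per-channel affine parameters (default identity).
#' @param eps variance guard.
#' @return normalized (C, H, W) array.
#' @export
group_normalize <- function(F, G, gamma = NULL, beta = NULL, eps = 1e-5) {
  C <- dim(F)[1]; H <- dim(F)[2]; W <- dim(F)[3]
  if (C %% G != 0) stop("channel count ", C, " not divisible by ", G, " groups")
  gamma <- gamma %||% rep(1, C)
  beta <- beta %||% rep(0, C)
  x <- matrix(F, C, H * W)
  xh <- ad_gn_core(x, C, H * W, 1L, as.integer(G), eps)
  array(xh * gamma + beta, c(C, H, W))
}

#' Extend the pyramid with a stride-2 level
#'
#' 3x3 stride-2 pad-1 convolution (channel-preserving) followed by group
#' normalization; the added level has half the spatial side (ceil).
#'
#' @param P5 (C_out, H, W) array, the current top pyramid level.
#' @param neck a `neck_model`.
#' @param level which extra level to apply (default 1).
#' @return (C_out, ceil(H/2), ceil(W/2)) array.
#' @export
extend_pyramid <- function(P5, neck, level = 1L) {
  cfg <- neck$cfg
  stopifnot(dim(P5)[1] == cfg$out_channels)
  P <- neck$ps$arr
  H <- dim(P5)[2]; W <- dim(P5)[3]
  r <- f_conv(P, neck$extra[[level]]$conv, matrix(P5, cfg$out_channels, H * W), H, W, 1L)
  h <- f_gn(P, neck$extra[[level]]$gn, r$x, r$H * r$W, 1L, cfg$eps)
  array(vof(h), c(cfg$out_channels, r$H, r$W))
}

#' Closed-form neck parameter count
#'
#' @param cfg a [neck_config()].
#' @return list with `mapping` (bias-free 1x1 convs, sum C_i x C_out),
#'   `gn` (2 x C_out per normalized level), `extra` (stride-2 convs + GN)
#'   and `total`.
#' @export
neck_param_count <- function(cfg) {
  mapping <- sum(cfg$in_channels * cfg$out_channels)
  gn <- 2L * cfg$out_channels * length(cfg$in_channels)
  extra <- cfg$num_extra_levels *
    (cfg$out_channels * cfg$out_channels * cfg$p6_kernel^2 + 2L * cfg$out_channels)
  list(mapping = mapping, gn = gn, extra = extra, total = mapping + gn + extra)
}

#' Closed-form mapping FLOPs per level
#'
#' One MAC per weight-input product: C_i x C_out x H_i x W_i for level i.
#' @param cfg a [neck_config()].
#' @param sides named integer vector of feature sides per stage.
#' @return numeric vector of per-level MAC counts.
#' @export
neck_mapping_flops <- function(cfg, sides) {
  vapply(names(cfg$in_channels), function(st)
    cfg$in_channels[[st]] * cfg$out_channels * as.numeric(sides[[st]])^2, numeric(1))
}
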