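# Analytic parameter and FLOP accounting plus the weighted efficiency score.
# FLOPs follow the one-MAC-equals-one-FLOP convention: convolution, linear
# and attention multiply-accumulates are counted from layer shapes at a given
# input size; element-wise work (activations, normalizations, gating) is
# tallied separately and excluded from the headline figure.

#' Count trainable parameters of a model by component
#'
#' @param model a `soystage_model` (or any object with a parameter store
#'   `ps` and name-prefixed parameters).
#' @return a `model_profile` with a per-component breakdown; the reported
#'   backbone figure covers the truncated feature stages (stem + MBConv
#'   stages); the retained checkpoint-compatibility conv is its own row and,
#'   following the deployment accounting, counts toward the non-backbone
#'   remainder returned by `neck_head_params()`.
#' @export
count_params <- function(model) {
  ps <- model$ps
  comp <- c(backbone = "backbone.", compat = "compat.", neck = "neck.",
            head = "head.")
  rows <- data.frame(component = names(comp),
                     params = vapply(comp, function(p)
                       param_count_prefix(ps, p), numeric(1)))
  total <- sum(rows$params)
  structure(list(breakdown = rows, total = total,
                 params_backbone = rows$params[rows$component == "backbone"],
                 params_neck = rows$params[rows$component == "neck"],
                 params_head = rows$params[rows$component == "head"],
                 params_compat = rows$params[rows$component == "compat"]),
            class = "model_profile")
}

#' Combined neck + head parameter count (deployment accounting)
#'
#' Everything outside the truncated backbone: neck, detection head, and the
#' retained checkpoint-compatibility conv.
#' @param model a `soystage_model`.
#' @export
neck_head_params <- function(model) {
  pr <- count_params(model)
  pr$total - pr$params_backbone
}

#' Report a parameter count in millions
#' @param x parameter count.
#' @param digits decimals (2 by default).
#' @export
params_millions <- function(x, digits = 2) round(x / 1e6, digits)

# MAC count of the backbone feature stages at a square input side
backbone_flops <- function(layout, side) {
  H <- side; W <- side
  ew <- 0  # elementwise tally
  stem_c <- layout$stem_channels
  Ho <- conv_out_side(H, 3L, 2L, 1L); Wo <- conv_out_side(W, 3L, 2L, 1L)
  macs <- 9 * 3 * stem_c * Ho * Wo
  ew <- ew + 3 * stem_c * Ho * Wo          # BN + swish sites
  H <- Ho; W <- Wo
  for (blk in layout$blocks) {
    s <- blk$spec
    cexp <- s$in_channels * s$t
    se <- se_width(s$in_channels, s$se_reduction)
    if (s$t > 1) {
      macs <- macs + s$in_channels * cexp * H * W
      ew <- ew + 3 * cexp * H * W
    }
    Ho <- conv_out_side(H, s$k, s$s, (s$k - 1L) %/% 2L)
    Wo <- conv_out_side(W, s$k, s$s, (s$k - 1L) %/% 2L)
    macs <- macs + s$k^2 * cexp * Ho * Wo
    ew <- ew + 3 * cexp * Ho * Wo
    macs <- macs + 2 * cexp * se             # SE bottleneck FCs
    ew <- ew + 2 * cexp * Ho * Wo            # gate sigmoid + rescale
    macs <- macs + cexp * s$out_channels * Ho * Wo
    ew <- ew + 2 * s$out_channels * Ho * Wo
    H <- Ho; W <- Wo
  }
  list(macs = macs, elementwise = ew)
}

# pyramid token sides at a given input for the configured stages + extras
pyramid_shapes <- function(model, side) {
  stages <- model$backbone$out_indices
  sides <- stage_sides(side, stages)
  lv <- lapply(seq_along(stages), function(i)
    list(H = sides[[i]], W = sides[[i]]))
  for (e in seq_len(model$neck$cfg$num_extra_levels)) {
    top <- lv[[length(lv)]]
    lv[[length(lv) + 1L]] <- list(H = conv_out_side(top$H, 3L, 2L, 1L),
                                  W = conv_out_side(top$W, 3L, 2L, 1L))
  }
  lv
}

neck_flops <- function(model, side) {
  cfg <- model$neck$cfg
  sides <- stage_sides(side, as.integer(names(cfg$in_channels)))
  macs <- sum(neck_mapping_flops(cfg, sides))
  ew <- sum(vapply(sides, function(s) 2 * cfg$out_channels * s^2, numeric(1)))
  top <- unname(sides[length(sides)])
  for (e in seq_len(cfg$num_extra_levels)) {
    nh <- conv_out_side(top, 3L, 2L, 1L)
    macs <- macs + cfg$out_channels^2 * 9 * nh^2
    ew <- ew + 2 * cfg$out_channels * nh^2
    top <- nh
  }
  list(macs = macs, elementwise = ew)
}

head_flops <- function(model, side) {
  cfg <- model$head$cfg
  D <- cfg$embed_dim; Hn <- cfg$num_heads; Pn <- cfg$sampling_points
  Lv <- cfg$num_levels; Dh <- D %/% Hn
  lv <- pyramid_shapes(model, side)
  Ltot <- sum(vapply(lv, function(s) s$H * s$W, numeric(1)))
  HLP <- Hn * Lv * Pn
  deform <- function(Lq, Lval) {
    D^2 * Lval +                      # value projection
      D^2 * Lq +                      # output projection
      D * 2 * HLP * Lq +              # sampling offsets
      D * HLP * Lq +                  # attention weights
      HLP * Dh * 5 * Lq               # bilinear sampling + weighting
  }
  enc_layer <- deform(Ltot, Ltot) + 2 * D * cfg$ffn_dim * Ltot
  twostage <- D^2 * Ltot + D * cfg$num_classes * Ltot +
    (2 * D^2 + 4 * D) * Ltot
  M <- cfg$num_queries
  self_attn <- 3 * D^2 * M + 2 * M^2 * D + D^2 * M
  dec_layer <- self_attn + deform(M, Ltot) + 2 * D * cfg$ffn_dim * M +
    (D * cfg$mlp_hidden + cfg$mlp_hidden * cfg$num_classes +
       D * cfg$mlp_hidden + cfg$mlp_hidden * 4) * M
  macs <- cfg$num_encoder_layers * enc_layer + twostage +
    cfg$num_decoder_layers * dec_layer
  ew <- (cfg$num_encoder_layers * 4 + cfg$num_decoder_layers * 6) * D * Ltot
  list(macs = macs, elementwise = ew)
}

#' Count forward-pass FLOPs (MAC convention) at a square input
#'
#' @param model a `soystage_model`.
#' @param input_side input resolution (default 512).
#' @return a `flop_profile`: per-component MACs, headline total, and the
#'   separately-tallied element-wise operation count.
#' @export
count_flops <- function(model, input_side = 512L) {
  bb <- backbone_flops(model$backbone$layout, input_side)
  nk <- neck_flops(model, input_side)
  hd <- head_flops(model, input_side)
  rows <- data.frame(
    component = c("backbone", "neck", "head"),
    macs = c(bb$macs, nk$macs, hd$macs),
    elementwise = c(bb$elementwise, nk$elementwise, hd$elementwise))
  structure(list(breakdown = rows, total = sum(rows$macs),
                 elementwise = sum(rows$elementwise),
                 input_side = input_side,
                 gflops = sum(rows$macs) / 1e9),
            class = "flop_profile")
}

#' @export
print.flop_profile <- function(x, ...) {
  cat(sprintf("Forward cost at %d^2 input: %.1f GFLOPs (MAC convention)\n",
              x$input_side, x$gflops))
  for (i in seq_len(nrow(x$breakdown)))
    cat(sprintf("  %-9s %8.2f G\n", x$breakdown$component[i],
                x$breakdown$macs[i] / 1e9))
  cat(sprintf("  elementwise (excluded): %.2f G ops\n", x$elementwise / 1e9))
  invisible(x)
}

#' @export
print.model_profile <- function(x, ...) {
  cat(sprintf("Trainable parameters: %.2f M total\n", x$total / 1e6))
  for (i in seq_len(nrow(x$breakdown)))
    cat(sprintf("  %-9s %8.2f M\n", x$breakdown$component[i],
                x$breakdown$params[i] / 1e6))
  cat(sprintf("  neck+head (deployment accounting): %.2f M\n",
              (x$total - x$params_backbone) / 1e6))
  invisible(x)
}

#' Efficiency-score configuration
#'
#' @param w_p,w_f parameter / FLOP weights (0.2 / 0.8, summing to 1).
#' @param params_norm,flops_norm scaling denominators (100 M params, 10 G
#'   FLOPs).
#' @param baseline reference (ap, params, flops) triple used for score
#'   normalization; defaults to the strongest transformer baseline the
#'   detector is compared against (74.7 AP, 63.5 M, 102.5 G).
#' @export
efficiency_config <- function(w_p = 0.2, w_f = 0.8, params_norm = 1e8,
                              flops_norm = 1e10,
                              baseline = list(ap = 74.7, params = 63.5e6,
                                              flops = 102.5e9)) {
  stopifnot(abs(w_p + w_f - 1) < 1e-9)
  structure(list(w_p = w_p, w_f = w_f, params_norm = params_norm,
                 flops_norm = flops_norm, baseline = baseline),
            class = "efficiency_config")
}

#' Weighted accuracy-per-cost efficiency score
#'
#' raw = AP / (w_p * params / 100M + w_f * FLOPs / 10G); the normalized value
#' divides by the baseline model's raw score so 1.0 means baseline-equivalent
#' efficiency.
#'
#' @param ap average precision in percent (0, 100].
#' @param params trainable parameter count.
#' @param flops forward FLOPs (MAC convention).
#' @param cfg an [efficiency_config()].
#' @return list with `raw` and `normalized`.
#' @export
efficiency_score <- function(ap, params, flops, cfg = efficiency_config()) {
  stopifnot(ap > 0, ap <= 100, params > 0, flops > 0)
  denom <- function(p, f) cfg$w_p * p / cfg$params_norm + cfg$w_f * f / cfg$flops_norm
  raw <- ap / denom(params, flops)
  base <- cfg$baseline$ap / denom(cfg$baseline$params, cfg$baseline$flops)
  list(raw = raw, normalized = raw / base)
}
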