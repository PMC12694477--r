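# Encoder-decoder detection head: multi-scale deformable self-attention over
# the flattened feature pyramid, a query decoder with iterative reference-box
# refinement in inverse-sigmoid space, task-aligned classification /
# localization predictors, and optional denoising query groups isolated by an
# attention mask.

#' Detection head configuration
#'
#' @param num_encoder_layers deformable encoder blocks (small preset 2,
#'   medium/large 3; 0 gives the degenerate identity stack).
#' @param num_decoder_layers decoder blocks (small/medium 1, large 3).
#' @param embed_dim token width (256 in the full model).
#' @param num_queries learned object queries (300).
#' @param ffn_dim feed-forward width (1024).
#' @param num_heads attention heads (8); embed_dim must be divisible.
#' @param sampling_points deformable sampling points per level (4).
#' @param mlp_hidden hidden width of the prediction MLPs (128, deliberately
#'   reduced from the embed width for parameter economy).
#' @param task_alignment enable the task-aligned feature split
#'   F_cls = Q + 0.1 tanh(Q), F_reg = Q + 0.1 sigmoid(Q).
#' @param num_classes number of growth-stage classes (9).
#' @param num_levels pyramid levels consumed (4: P3-P6 by default).
#' @return a `head_config` list.
#' @export
head_config <- function(num_encoder_layers = 3L, num_decoder_layers = 3L,
                        embed_dim = 256L, num_queries = 300L, ffn_dim = 1024L,
                        num_heads = 8L, sampling_points = 4L, mlp_hidden = 128L,
                        task_alignment = TRUE, num_classes = 9L, num_levels = 4L) {
  if (embed_dim %% num_heads != 0 || embed_dim %% 4 != 0)
    stop("embed_dim must be divisible by num_heads and by 4")
  stopifnot(num_encoder_layers >= 0, num_decoder_layers >= 1, num_queries >= 1)
  structure(list(num_encoder_layers = as.integer(num_encoder_layers),
                 num_decoder_layers = as.integer(num_decoder_layers),
                 embed_dim = as.integer(embed_dim),
                 num_queries = as.integer(num_queries),
                 ffn_dim = as.integer(ffn_dim), num_heads = as.integer(num_heads),
                 sampling_points = as.integer(sampling_points),
                 mlp_hidden = as.integer(mlp_hidden),
                 task_alignment = isTRUE(task_alignment),
                 num_classes = as.integer(num_classes),
                 num_levels = as.integer(num_levels)),
            class = "head_config")
}

# register one multi-scale deformable attention block
deform_attn_layers <- function(ps, prefix, cfg) {
  D <- cfg$embed_dim; HLP <- cfg$num_heads * cfg$num_levels * cfg$sampling_points
  offs <- ly_linear(ps, paste0(prefix, ".offs"), D, 2L * HLP, zero = TRUE)
  # offset bias: per-head compass directions so initial samples spread out
  th <- 2 * pi * (seq_len(cfg$num_heads) - 1) / cfg$num_heads
  bias <- numeric(2L * HLP)
  i <- 0L
  for (h in seq_len(cfg$num_heads)) for (l in seq_len(cfg$num_levels))
    for (p in seq_len(cfg$sampling_points)) {
      bias[i + 1L] <- cos(th[h]) * p; bias[i + 2L] <- sin(th[h]) * p
      i <- i + 2L
    }
  ps$arr[[paste0(prefix, ".offs.b")]] <- bias * 0.5
  wts <- ly_linear(ps, paste0(prefix, ".wts"), D, HLP, zero = TRUE)
  list(offs = offs, wts = wts,
       value = ly_linear(ps, paste0(prefix, ".value"), D, D),
       out = ly_linear(ps, paste0(prefix, ".out"), D, D))
}

mlp_layers <- function(ps, prefix, dims) {
  lapply(seq_len(length(dims) - 1L), function(i)
    ly_linear(ps, paste0(prefix, ".fc", i), dims[i], dims[i + 1L]))
}

f_mlp <- function(P, metas, x, act = ad_relu) {
  n <- length(metas)
  for (i in seq_len(n)) {
    x <- f_linear(P, metas[[i]], x)
    if (i < n) x <- act(x)
  }
  x
}

#' Build the detection head
#'
#' @param cfg a [head_config()].
#' @param seed optional init seed.
#' @return a `head_model` with parameter store and layer metadata.
#' @export
build_head <- function(cfg, seed = NULL) {
  build <- function() {
    ps <- param_store()
    D <- cfg$embed_dim
    p_add(ps, "head.level_embed.w", matrix(stats::rnorm(D * cfg$num_levels, 0, 0.02),
                                           D, cfg$num_levels))
    enc <- lapply(seq_len(cfg$num_encoder_layers), function(l) {
      pre <- sprintf("head.enc%d", l)
      list(attn = deform_attn_layers(ps, paste0(pre, ".attn"), cfg),
           ln1 = ly_ln(ps, paste0(pre, ".ln1"), D),
           ffn1 = ly_linear(ps, paste0(pre, ".ffn1"), D, cfg$ffn_dim),
           ffn2 = ly_linear(ps, paste0(pre, ".ffn2"), cfg$ffn_dim, D),
           ln2 = ly_ln(ps, paste0(pre, ".ln2"), D))
    })
    twostage <- list(
      memtrans = ly_linear(ps, "head.memtrans", D, D),
      memtrans_ln = ly_ln(ps, "head.memtrans_ln", D),
      enc_cls = ly_linear(ps, "head.enc_cls", D, cfg$num_classes),
      enc_box = mlp_layers(ps, "head.enc_box", c(D, D, D, 4L)))
    query_embed <- ly_embed(ps, "head.query_embed", cfg$num_queries, D)
    label_embed <- ly_embed(ps, "head.label_embed", cfg$num_classes, D)
    dec <- lapply(seq_len(cfg$num_decoder_layers), function(l) {
      pre <- sprintf("head.dec%d", l)
      list(qkv = ly_linear(ps, paste0(pre, ".self_qkv"), D, 3L * D),
           self_out = ly_linear(ps, paste0(pre, ".self_out"), D, D),
           ln1 = ly_ln(ps, paste0(pre, ".ln1"), D),
           attn = deform_attn_layers(ps, paste0(pre, ".cross"), cfg),
           ln2 = ly_ln(ps, paste0(pre, ".ln2"), D),
           ffn1 = ly_linear(ps, paste0(pre, ".ffn1"), D, cfg$ffn_dim),
           ffn2 = ly_linear(ps, paste0(pre, ".ffn2"), cfg$ffn_dim, D),
           ln3 = ly_ln(ps, paste0(pre, ".ln3"), D),
           cls = mlp_layers(ps, paste0(pre, ".cls"), c(D, cfg$mlp_hidden, cfg$num_classes)),
           reg = mlp_layers(ps, paste0(pre, ".reg"), c(D, cfg$mlp_hidden, 4L)))
    })
    list(ps = ps, enc = enc, twostage = twostage, query_embed = query_embed,
         label_embed = label_embed, dec = dec)
  }
  b <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(c(b, list(cfg = cfg)), class = "head_model")
}

# sine positional embedding of normalized 2-d coordinates -> (D, L)
sine_pos_embed <- function(xy, D, temperature = 10000) {
  half <- D %/% 2L; quarter <- half %/% 2L
  freqs <- temperature^(-(seq_len(quarter) - 1) / quarter)
  emb1 <- function(v) {
    a <- outer(freqs, v * 2 * pi)
    m <- matrix(0, half, length(v))
    m[seq(1, half, 2), ] <- sin(a)
    m[seq(2, half, 2), ] <- cos(a)
    m
  }
  rbind(emb1(xy[1, ]), emb1(xy[2, ]))
}

# normalized token-center coordinates for a level grid, H fastest
level_token_centers <- function(H, W) {
  y <- rep.int((seq_len(H) - 0.5) / H, W)
  x <- rep(((seq_len(W) - 0.5) / W), each = H)
  rbind(x, y)
}

# Flatten pyramid levels (image-major within level) into per-image blocks of
# stacked levels. Returns gather/scatter index vectors and bookkeeping.
seq_layout <- function(lv_shapes, N) {
  Ls <- vapply(lv_shapes, function(s) s$H * s$W, numeric(1))
  Ltot <- sum(Ls)
  starts_lvl <- cumsum(c(0, Ls))            # within an image block
  # order of the concatenated per-level matrices: level blocks of size HW*N
  lvl_offsets <- cumsum(c(0, Ls * N))
  gather <- integer(Ltot * N)
  pos <- 0L
  for (n in seq_len(N)) for (l in seq_along(Ls)) {
    idx <- lvl_offsets[l] + (n - 1L) * Ls[l] + seq_len(Ls[l])
    gather[pos + seq_len(Ls[l])] <- idx
    pos <- pos + Ls[l]
  }
  list(Ls = Ls, Ltot = Ltot, starts_lvl = starts_lvl, gather = gather)
}

# multi-scale deformable attention.
# query (D, S) where S spans per-image blocks; ref_xy (2, S) plain, normalized;
# ref_wh optional (2, S) for box-modulated offsets; values: per-level list of
# head-projected matrices (D, HW*N) in image-major layout.
ms_deform_attn <- function(P, metas, query, values, lv_shapes, ref_xy, N, cfg,
                           ref_wh = NULL) {
  D <- cfg$embed_dim; Hn <- cfg$num_heads; Lv <- length(lv_shapes)
  Pn <- cfg$sampling_points; Dh <- D %/% Hn
  S <- ncol(vof(query)); Sq <- S %/% N
  off <- f_linear(P, metas$offs, query)               # (2*H*Lv*P, S)
  wts <- f_linear(P, metas$wts, query)                # (H*Lv*P, S)
  wts <- ad_reshape(wts, c(Lv * Pn, Hn * S))
  wts <- ad_softmax_cols(wts)
  wts <- ad_reshape(wts, c(Hn * Lv * Pn, S))
  img_of <- rep(seq_len(N), each = Sq)
  heads <- vector("list", Hn)
  row0 <- function(h, l, p) ((h - 1L) * Lv * Pn + (l - 1L) * Pn + (p - 1L))
  for (h in seq_len(Hn)) {
    acc <- NULL
    vrows <- ((h - 1L) * Dh + 1L):(h * Dh)
    for (l in seq_len(Lv)) {
      Hl <- lv_shapes[[l]]$H; Wl <- lv_shapes[[l]]$W
      vl <- ad_rows(values[[l]], vrows)
      for (p in seq_len(Pn)) {
        r <- row0(h, l, p)
        ox <- ad_rows(off, 2L * r + 1L)
        oy <- ad_rows(off, 2L * r + 2L)
        if (is.null(ref_wh)) {
          sx <- ad_add(ad_mul(ox, 1 / Wl), matrix(ref_xy[1, ], 1))
          sy <- ad_add(ad_mul(oy, 1 / Hl), matrix(ref_xy[2, ], 1))
        } else {
          sx <- ad_add(ad_mul(ox, matrix(ref_wh[1, ] / (2 * Pn), 1)), matrix(ref_xy[1, ], 1))
          sy <- ad_add(ad_mul(oy, matrix(ref_wh[2, ] / (2 * Pn), 1)), matrix(ref_xy[2, ], 1))
        }
        # to pixel coordinates, clamped inside the level
        px <- ad_clamp(ad_sub(ad_mul(sx, Wl), 0.5), 0, Wl - 1)
        py <- ad_clamp(ad_sub(ad_mul(sy, Hl), 0.5), 0, Hl - 1)
        x0 <- pmin(floor(vof(px)), Wl - 2); x0 <- pmax(x0, 0)
        y0 <- pmin(floor(vof(py)), Hl - 2); y0 <- pmax(y0, 0)
        fx <- ad_sub(px, x0); fy <- ad_sub(py, y0)
        base <- (img_of - 1L) * Hl * Wl
        i00 <- as.integer(base + y0 + 1L + x0 * Hl)
        i01 <- if (Wl >= 2L) as.integer(i00 + Hl) else i00    # x0+1
        i10 <- if (Hl >= 2L) i00 + 1L else i00                # y0+1
        i11 <- if (Hl >= 2L) i01 + 1L else i01
        fx1 <- ad_sub(1, fx); fy1 <- ad_sub(1, fy)
        samp <- ad_add(
          ad_add(ad_mul_rowvec(ad_cols(vl, i00), ad_rowvec(ad_mul(fx1, fy1))),
                 ad_mul_rowvec(ad_cols(vl, i01), ad_rowvec(ad_mul(fx, fy1)))),
          ad_add(ad_mul_rowvec(ad_cols(vl, i10), ad_rowvec(ad_mul(fx1, fy))),
                 ad_mul_rowvec(ad_cols(vl, i11), ad_rowvec(ad_mul(fx, fy)))))
        term <- ad_mul_rowvec(samp, ad_rowvec(ad_rows(wts, r + 1L)))
        acc <- if (is.null(acc)) term else ad_add(acc, term)
      }
    }
    heads[[h]] <- acc
  }
  f_linear(P, metas$out, ad_rbind_list(heads))
}

# flatten a (1, S) row-matrix node/array to a length-S vector semantics
ad_rowvec <- function(x) ad_reshape(x, NULL)

# reshape helper accepting NULL dims (drop to vector)
# (ad_reshape handles dims = NULL via dim<- semantics)

# standard multi-head self-attention on one image's queries with optional
# additive mask (M x M, TRUE = blocked); q/k get positional embeddings
self_attention <- function(P, layer, x, posq, N, M, cfg, mask = NULL) {
  D <- cfg$embed_dim; Hn <- cfg$num_heads; Dh <- D %/% Hn
  qkv_in <- ad_add(x, posq)
  qkv <- f_linear(P, layer$qkv, qkv_in)
  q <- ad_rows(qkv, 1:D)
  k <- ad_rows(qkv, (D + 1L):(2L * D))
  v0 <- ad_rows(f_linear(P, layer$qkv, x), (2L * D + 1L):(3L * D))
  penalty <- if (!is.null(mask)) -1e9 * mask else NULL
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    colsn <- ((n - 1L) * M + 1L):(n * M)
    hh <- vector("list", Hn)
    for (h in seq_len(Hn)) {
      rows <- ((h - 1L) * Dh + 1L):(h * Dh)
      qh <- ad_rows(ad_cols(q, colsn), rows)
      kh <- ad_rows(ad_cols(k, colsn), rows)
      vh <- ad_rows(ad_cols(v0, colsn), rows)
      sc <- ad_mul(ad_matmul(ad_t(kh), qh), 1 / sqrt(Dh))   # (keys, queries)
      if (!is.null(penalty)) sc <- ad_add(sc, penalty)
      hh[[h]] <- ad_matmul(vh, ad_softmax_cols(sc))
    }
    outs[[n]] <- ad_rbind_list(hh)
  }
  f_linear(P, layer$self_out, ad_cbind_list(outs))
}

#' Task-aligned feature split for the two prediction branches
#'
#' With alignment enabled the classification branch sees
#' Q + 0.1 tanh(Q) and the regression branch Q + 0.1 sigmoid(Q); both
#' perturbations are bounded by 0.1 elementwise. Disabled, both branches
#' receive Q unchanged.
#'
#' @param Q query feature array or matrix.
#' @param enabled logical.
#' @return list with `F_cls` and `F_reg`.
#' @export
task_aligned_features <- function(Q, enabled = TRUE) {
  if (!enabled) return(list(F_cls = Q, F_reg = Q))
  if (ad_is_node(Q))
    list(F_cls = ad_add(Q, ad_mul(ad_tanh(Q), 0.1)),
         F_reg = ad_add(Q, ad_mul(ad_sigmoid(Q), 0.1)))
  else
    list(F_cls = Q + 0.1 * tanh(Q), F_reg = Q + 0.1 * plogis(Q))
}

# encoder stack over the flattened pyramid; lv = neck_forward output
head_encode <- function(P, head, lv, N) {
  cfg <- head$cfg
  D <- cfg$embed_dim
  if (length(lv) < 1L) stop("empty pyramid")
  lay <- seq_layout(lv, N)
  # positional + level embeddings, identical across images
  pos_lvls <- lapply(seq_along(lv), function(l)
    sine_pos_embed(level_token_centers(lv[[l]]$H, lv[[l]]$W), D))
  lvl_emb <- P[["head.level_embed.w"]]
  pos_img <- do.call(cbind, lapply(seq_along(lv), function(l)
    pos_lvls[[l]] + vof(lvl_emb)[, l]))
  pos <- pos_img[, rep(seq_len(lay$Ltot), N) + 0L]
  # reference = each token's own center, replicated per image
  refs_img <- do.call(cbind, lapply(lv, function(s) level_token_centers(s$H, s$W)))
  refs <- refs_img[, rep(seq_len(lay$Ltot), N), drop = FALSE]
  x <- ad_cols(ad_cbind_list(lapply(lv, `[[`, "x")), lay$gather)
  lv_shapes <- lapply(lv, function(s) list(H = s$H, W = s$W))
  # per-image level slices for value gathering (image-major per level)
  level_cols <- lapply(seq_along(lv), function(l) {
    unlist(lapply(seq_len(N), function(n)
      (n - 1L) * lay$Ltot + lay$starts_lvl[l] + seq_len(lay$Ls[l])))
  })
  for (layer in head$enc) {
    q <- ad_add(x, pos)
    vfull <- f_linear(P, layer$attn$value, x)
    values <- lapply(level_cols, function(ci) ad_cols(vfull, ci))
    att <- ms_deform_attn(P, layer$attn, q, values, lv_shapes, refs, N, cfg)
    x <- f_ln(P, layer$ln1, ad_add(att, x))
    ff <- f_linear(P, layer$ffn2, ad_relu(f_linear(P, layer$ffn1, x)))
    x <- f_ln(P, layer$ln2, ad_add(ff, x))
  }
  list(memory = x, pos = pos, refs = refs, lay = lay, lv_shapes = lv_shapes,
       level_cols = level_cols, N = N)
}

# encoder-side proposal generation (two-stage query selection)
encoder_proposals <- function(P, head, mem) {
  cfg <- head$cfg
  ts <- head$twostage
  m <- f_ln(P, ts$memtrans_ln, f_linear(P, ts$memtrans, mem$memory))
  cls <- f_linear(P, ts$enc_cls, m)                 # (ncls, Ltot*N)
  delta <- f_mlp(P, ts$enc_box, m)                  # (4, Ltot*N)
  # base proposal per token: its center, width/height growing with level
  base_wh <- rep(unlist(lapply(seq_along(mem$lv_shapes), function(l)
    rep(0.05 * 2^(l - 1L), mem$lay$Ls[l]))), mem$N)
  base <- rbind(mem$refs, base_wh, base_wh)
  logit_base <- inverse_sigmoid(base)
  prop <- ad_sigmoid(ad_add(delta, logit_base))
  list(cls = cls, boxes = prop, trans = m)
}

# full head forward. dn: optional denoising batch (see build_denoising_batch);
# returns per-layer logits/boxes plus encoder-proposal outputs.
head_forward <- function(P, head, lv, N, dn = NULL) {
  cfg <- head$cfg
  D <- cfg$embed_dim; nq <- cfg$num_queries
  mem <- head_encode(P, head, lv, N)
  ep <- encoder_proposals(P, head, mem)
  # top-k proposals by best class logit, per image
  scr <- apply(vof(ep$cls), 2, max)
  Ltot <- mem$lay$Ltot
  sel <- integer(0)
  for (n in seq_len(N)) {
    block <- (n - 1L) * Ltot + seq_len(Ltot)
    k <- min(nq, Ltot)
    ord <- block[order(scr[block], decreasing = TRUE)[seq_len(k)]]
    if (k < nq) ord <- c(ord, rep(ord[1L], nq - k))
    sel <- c(sel, ord)
  }
  refs0 <- vof(ep$boxes)[, sel, drop = FALSE]       # detached proposals
  content <- P[["head.query_embed.w"]]
  qx <- ad_cols(content, rep(seq_len(nq), N))
  dn_n <- 0L
  mask <- NULL
  if (!is.null(dn) && dn$n_dn > 0L) {
    dn_n <- dn$n_dn
    lbl <- ad_cols(P[["head.label_embed.w"]], dn$labels + 1L)  # (D, dn_n*N)
    # per image: [dn queries | matching queries]
    qs <- vector("list", N)
    for (n in seq_len(N)) {
      cols_dn <- ((n - 1L) * dn_n + 1L):(n * dn_n)
      qs[[n]] <- ad_cbind_list(list(ad_cols(lbl, cols_dn),
                                    ad_cols(content, seq_len(nq))))
    }
    qx <- ad_cbind_list(qs)
    refs_list <- lapply(seq_len(N), function(n) {
      cbind(t(dn$boxes[((n - 1L) * dn_n + 1L):(n * dn_n), , drop = FALSE]),
            refs0[, ((n - 1L) * nq + 1L):(n * nq), drop = FALSE])
    })
    refs0 <- do.call(cbind, refs_list)
    mask <- dn$mask
  }
  M <- nq + dn_n
  refs <- refs0
  layers_out <- vector("list", length(head$dec))
  x <- qx
  for (li in seq_along(head$dec)) {
    layer <- head$dec[[li]]
    posq <- sine_pos_embed(refs[1:2, , drop = FALSE], D)
    sa <- self_attention(P, layer, x, posq, N, M, cfg, mask)
    x <- f_ln(P, layer$ln1, ad_add(sa, x))
    vfull <- f_linear(P, layer$attn$value, mem$memory)
    values <- lapply(mem$level_cols, function(ci) ad_cols(vfull, ci))
    ca <- ms_deform_attn(P, layer$attn, ad_add(x, posq), values, mem$lv_shapes,
                         refs[1:2, , drop = FALSE], N, cfg,
                         ref_wh = refs[3:4, , drop = FALSE])
    x <- f_ln(P, layer$ln2, ad_add(ca, x))
    ff <- f_linear(P, layer$ffn2, ad_relu(f_linear(P, layer$ffn1, x)))
    x <- f_ln(P, layer$ln3, ad_add(ff, x))
    ta <- task_aligned_features(x, cfg$task_alignment)
    logits <- f_mlp(P, layer$cls, ta$F_cls)
    delta <- f_mlp(P, layer$reg, ta$F_reg)
    boxes <- ad_sigmoid(ad_add(delta, inverse_sigmoid(refs)))
    layers_out[[li]] <- list(logits = logits, boxes = boxes)
    refs <- vof(boxes)                                # detached for next layer
  }
  list(layers = layers_out, enc = ep, sel = sel, mem = mem,
       n_dn = dn_n, num_queries = nq, M = M, N = N)
}

# wrap a plain array so it participates in the tape when one is active
ad_leafless <- function(x) if (!is.null(.ad$tape)) ad_op(vof(x), list(), NULL) else vof(x)

#' Encode a feature pyramid into decoder memory
#'
#' Flattens the pyramid levels into a token sequence with sine positional and
#' learned level embeddings, then applies the configured number of deformable
#' self-attention + FFN encoder blocks (0 blocks returns the embedded
#' sequence unchanged).
#'
#' @param pyramid named list of (C, H, W) arrays (e.g. from [map_channels()]
#'   and [extend_pyramid()]).
#' @param head a `head_model` from [build_head()].
#' @return list with `memory` (D x L matrix), `pos`, per-level shapes and the
#'   sequence length `length`.
#' @export
encode <- function(pyramid, head) {
  if (length(pyramid) < 1L) stop("empty pyramid")
  lv <- lapply(pyramid, function(a)
    list(x = matrix(a, dim(a)[1], dim(a)[2] * dim(a)[3]),
         H = dim(a)[2], W = dim(a)[3], C = dim(a)[1]))
  mem <- head_encode(head$ps$arr, head, lv, 1L)
  list(memory = vof(mem$memory), pos = mem$pos, lv_shapes = mem$lv_shapes,
       length = ncol(vof(mem$memory)), internal = mem)
}

#' Decode object queries against encoder memory
#'
#' Runs the decoder stack (self-attention, deformable cross-attention with
#' box-modulated sampling, FFN) with iterative reference refinement in
#' inverse-sigmoid space, reference boxes initialized from encoder proposals.
#'
#' @param memory output of [encode()].
#' @param head a `head_model`.
#' @return list of per-layer query states, each with `queries` (D x Q matrix),
#'   `ref_boxes` (Q x 4, normalized cx cy w h) and `logits` (ncls x Q).
#' @export
decode <- function(memory, head) {
  P <- head$ps$arr
  cfg <- head$cfg
  mem <- memory$internal
  ep <- encoder_proposals(P, head, mem)
  scr <- apply(vof(ep$cls), 2, max)
  nq <- min(cfg$num_queries, mem$lay$Ltot)
  sel <- order(scr, decreasing = TRUE)[seq_len(nq)]
  refs <- vof(ep$boxes)[, sel, drop = FALSE]
  x <- matrix(vof(P[["head.query_embed.w"]])[, seq_len(nq)], cfg$embed_dim, nq)
  out <- vector("list", length(head$dec))
  for (li in seq_along(head$dec)) {
    layer <- head$dec[[li]]
    posq <- sine_pos_embed(refs[1:2, , drop = FALSE], cfg$embed_dim)
    sa <- self_attention(P, layer, x, posq, 1L, nq, cfg)
    x <- f_ln(P, layer$ln1, ad_add(sa, x))
    vfull <- f_linear(P, layer$attn$value, mem$memory)
    values <- lapply(mem$level_cols, function(ci) ad_cols(vfull, ci))
    ca <- ms_deform_attn(P, layer$attn, ad_add(x, posq), values, mem$lv_shapes,
                         refs[1:2, , drop = FALSE], 1L, cfg,
                         ref_wh = refs[3:4, , drop = FALSE])
    x <- f_ln(P, layer$ln2, ad_add(ca, x))
    ff <- f_linear(P, layer$ffn2, ad_relu(f_linear(P, layer$ffn1, x)))
    x <- f_ln(P, layer$ln3, ad_add(ff, x))
    ta <- task_aligned_features(x, cfg$task_alignment)
    logits <- f_mlp(P, layer$cls, ta$F_cls)
    delta <- f_mlp(P, layer$reg, ta$F_reg)
    refs <- vof(ad_sigmoid(ad_add(delta, inverse_sigmoid(refs))))
    out[[li]] <- list(queries = vof(x), ref_boxes = t(refs), logits = vof(logits))
  }
  out
}

#' Prediction MLPs over task-aligned query features
#'
#' @param F_cls,F_reg aligned feature matrices (D x Q), e.g. from
#'   [task_aligned_features()].
#' @param head a `head_model`.
#' @param refs Q x 4 reference boxes the regression deltas refine.
#' @param layer decoder layer whose predictors to use (default last).
#' @return list with `logits` (Q x ncls), `boxes` (Q x 4 normalized cx cy w h)
#'   and `scores` (Q x ncls sigmoid scores).
#' @export
head_predict <- function(F_cls, F_reg, head, refs, layer = length(head$dec)) {
  P <- head$ps$arr
  ly <- head$dec[[layer]]
  logits <- vof(f_mlp(P, ly$cls, F_cls))
  delta <- vof(f_mlp(P, ly$reg, F_reg))
  boxes <- plogis(delta + t(inverse_sigmoid(refs)))
  list(logits = t(logits), boxes = t(boxes), scores = t(plogis(logits)))
}
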