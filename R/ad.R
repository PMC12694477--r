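# Minimal reverse-mode automatic differentiation over plain R arrays.
#
# A tape (environment) records operation nodes in execution order; each node
# holds its value, its parent nodes and a backward closure mapping the output
# gradient to parent gradients. Every primitive transparently accepts either a
# plain numeric array or a node: with no active tape (or no node parents) the
# primitives compute values directly, so the same layer code serves both the
# recorded training path and fast inference.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_start <- function() {
  .ad$tape <- new.env(parent = emptyenv())
  .ad$tape$nodes <- vector("list", 2048L)
  .ad$tape$n <- 0L
  invisible(.ad$tape)
}

ad_tape_stop <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_is_node <- function(x) inherits(x, "adnode")

# Value of a node or plain array.
vof <- function(x) if (ad_is_node(x)) x$value else x

ad_leaf <- function(value) {
  stopifnot(!is.null(.ad$tape))
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- list()
  nd$backfn <- NULL
  class(nd) <- "adnode"
  tp <- .ad$tape
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

# Record an op node. `parents` is a list (possibly mixed node / plain);
# `backfn(g)` returns a list of gradients aligned with `parents` (entries for
# plain parents are ignored and may be NULL).
ad_op <- function(value, parents, backfn) {
  tp <- .ad$tape
  if (is.null(tp)) return(value)
  np <- length(parents)
  isnd <- logical(np)
  any_nd <- FALSE
  for (i in seq_len(np)) if (inherits(parents[[i]], "adnode")) {
    isnd[i] <- TRUE; any_nd <- TRUE
  }
  if (!any_nd) return(value)
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents[isnd]
  nd$pidx <- which(isnd)
  nd$backfn <- backfn
  class(nd) <- "adnode"
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Run backward from a scalar output node.
ad_backward <- function(out) {
  stopifnot(ad_is_node(out), !is.null(.ad$tape))
  out$grad <- if (is.null(dim(out$value))) rep(1, length(out$value))
              else array(1, dim = dim(out$value))
  tp <- .ad$tape
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      gj <- gs[[nd$pidx[j]]]
      if (!is.null(gj)) ad_accum(nd$parents[[j]], gj)
    }
    nd$grad <- NULL  # free memory as we go; leaves keep theirs
  }
  invisible(NULL)
}

ad_detach <- function(x) vof(x)

# --- elementwise arithmetic -------------------------------------------------

ad_add <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_op(av + bv, list(a, b), function(g) list(g, if (length(bv) == 1L) sum(g) else g))
}

ad_sub <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_op(av - bv, list(a, b), function(g) list(g, if (length(bv) == 1L) -sum(g) else -g))
}

ad_mul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_op(av * bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L && length(bv) > 1L) sum(g * bv) else g * bv
    gb <- if (length(bv) == 1L && length(av) > 1L) sum(g * av) else g * av
    list(ga, gb)
  })
}

ad_div <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_op(av / bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L && length(bv) > 1L) sum(g / bv) else g / bv
    gb <- g * (-av / (bv * bv))
    if (length(bv) == 1L && length(gb) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ad_neg <- function(a) ad_op(-vof(a), list(a), function(g) list(-g))

ad_sq <- function(a) {
  av <- vof(a)
  ad_op(av * av, list(a), function(g) list(2 * g * av))
}

ad_sqrt <- function(a) {
  v <- sqrt(vof(a))
  ad_op(v, list(a), function(g) list(g / (2 * v)))
}

ad_exp <- function(a) {
  v <- exp(vof(a))
  ad_op(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  av <- vof(a)
  ad_op(log(av), list(a), function(g) list(g / av))
}

ad_abs <- function(a) {
  av <- vof(a)
  ad_op(abs(av), list(a), function(g) list(g * sign(av)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-vof(a)))
  ad_op(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_tanh <- function(a) {
  v <- tanh(vof(a))
  ad_op(v, list(a), function(g) list(g * (1 - v * v)))
}

ad_relu <- function(a) {
  av <- vof(a)
  m <- av > 0
  ad_op(av * m, list(a), function(g) list(g * m))
}

# swish / SiLU: x * sigmoid(x)
ad_silu <- function(a) {
  av <- vof(a)
  s <- 1 / (1 + exp(-av))
  ad_op(av * s, list(a), function(g) list(g * (s + av * s * (1 - s))))
}

ad_pmax <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  m <- av >= bv
  ad_op(pmax(av, bv), list(a, b), function(g) {
    ga <- g * m; gb <- g * !m
    if (length(av) == 1L && length(ga) > 1L) ga <- sum(ga)
    if (length(bv) == 1L && length(gb) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ad_pmin <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  m <- av <= bv
  ad_op(pmin(av, bv), list(a, b), function(g) {
    ga <- g * m; gb <- g * !m
    if (length(av) == 1L && length(ga) > 1L) ga <- sum(ga)
    if (length(bv) == 1L && length(gb) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

ad_clamp <- function(a, lo, hi) ad_pmin(ad_pmax(a, lo), hi)

# --- reductions -------------------------------------------------------------

ad_sum <- function(a) {
  av <- vof(a)
  ad_op(sum(av), list(a), function(g) {
    gg <- if (is.null(dim(av))) rep(as.numeric(g), length(av)) else array(as.numeric(g), dim = dim(av))
    list(gg)
  })
}

ad_mean <- function(a) {
  av <- vof(a); n <- length(av)
  ad_op(mean(av), list(a), function(g) {
    gg <- if (is.null(dim(av))) rep(as.numeric(g) / n, n) else array(as.numeric(g) / n, dim = dim(av))
    list(gg)
  })
}

ad_rowsums <- function(a) {
  av <- vof(a)
  ad_op(rowSums(av), list(a), function(g) list(matrix(g, nrow(av), ncol(av))))
}

ad_colsums <- function(a) {
  av <- vof(a)
  ad_op(colSums(av), list(a), function(g) list(matrix(g, nrow(av), ncol(av), byrow = TRUE)))
}

ad_rowmeans <- function(a) {
  av <- vof(a); k <- ncol(av)
  ad_op(rowMeans(av), list(a), function(g) list(matrix(g / k, nrow(av), ncol(av))))
}

# --- matrix / structural ops ------------------------------------------------

ad_matmul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_op(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ad_t <- function(a) {
  av <- vof(a)
  ad_op(t(av), list(a), function(g) list(t(g)))
}

ad_reshape <- function(a, dims) {
  av <- vof(a)
  odim <- dim(av)
  v <- av
  dim(v) <- dims
  ad_op(v, list(a), function(g) {
    dim(g) <- odim
    list(g)
  })
}

# add vector v (length nrow) to every column of m
ad_add_colvec <- function(m, v) {
  mv <- vof(m); vv <- vof(v)
  ad_op(mv + vv, list(m, v), function(g) list(g, rowSums(g)))
}

# multiply row i of m by v[i]
ad_mul_colvec <- function(m, v) {
  mv <- vof(m); vv <- vof(v)
  ad_op(mv * vv, list(m, v), function(g) list(g * vv, rowSums(g * mv)))
}

# add vector v (length ncol) to every row of m
ad_add_rowvec <- function(m, v) {
  mv <- vof(m); vv <- vof(v)
  ad_op(sweep(mv, 2L, vv, "+"), list(m, v), function(g) list(g, colSums(g)))
}

# multiply column j of m by v[j]
ad_mul_rowvec <- function(m, v) {
  mv <- vof(m); vv <- vof(v)
  ad_op(sweep(mv, 2L, vv, "*"), list(m, v), function(g)
    list(sweep(g, 2L, vv, "*"), colSums(g * mv)))
}

# column gather (idx may repeat); backward scatter-adds
ad_cols <- function(m, idx) {
  mv <- vof(m)
  ad_op(mv[, idx, drop = FALSE], list(m), function(g) {
    gm <- matrix(0, nrow(mv), ncol(mv))
    acc <- rowsum(t(g), group = idx)            # sums rows of t(g) by idx
    gm[, as.integer(rownames(acc))] <- t(acc)
    list(gm)
  })
}

ad_rows <- function(m, idx) {
  mv <- vof(m)
  ad_op(mv[idx, , drop = FALSE], list(m), function(g) {
    gm <- matrix(0, nrow(mv), ncol(mv))
    acc <- rowsum(g, group = idx)
    gm[as.integer(rownames(acc)), ] <- acc
    list(gm)
  })
}

ad_cbind_list <- function(xs) {
  vals <- lapply(xs, vof)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ad_op(do.call(cbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_rbind_list <- function(xs) {
  vals <- lapply(xs, vof)
  nrows <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nrows)
  starts <- ends - nrows + 1L
  ad_op(do.call(rbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# softmax over the rows of each column (columns sum to one)
ad_softmax_cols <- function(m) {
  mv <- vof(m)
  mx <- apply(mv, 2L, max)
  e <- exp(sweep(mv, 2L, mx, "-"))
  s <- sweep(e, 2L, colSums(e), "/")
  ad_op(s, list(m), function(g) {
    dot <- colSums(g * s)
    list(s * sweep(g, 2L, dot, "-"))
  })
}

# --- normalization cores ----------------------------------------------------
# Affine parameters are applied outside via ad_mul_colvec / ad_add_colvec.

# per-row (channel) normalization over all columns: batch-norm core
ad_bn_core <- function(x, eps = 1e-5) {
  xv <- vof(x)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- xc * istd
  ad_op(xh, list(x), function(g) {
    gm <- rowMeans(g)
    gxh <- rowMeans(g * xh)
    list(istd * (g - gm - xh * gxh))
  })
}

# per-column (token) normalization over rows: layer-norm core
ad_ln_core <- function(x, eps = 1e-5) {
  xv <- vof(x)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu, "-")
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh <- sweep(xc, 2L, istd, "*")
  ad_op(xh, list(x), function(g) {
    gm <- colMeans(g)
    gxh <- colMeans(g * xh)
    list(sweep(sweep(g, 2L, gm, "-") - sweep(xh, 2L, gxh, "*"), 2L, istd, "*"))
  })
}

# group normalization core for feature maps laid out (C, H*W*N):
# statistics over each (group, image) block of C/G channels x H*W pixels
ad_gn_core <- function(x, C, HW, N, G, eps = 1e-5) {
  xv <- vof(x)
  Cg <- C %/% G
  a <- array(xv, c(Cg, G, HW, N))
  ap <- aperm(a, c(1L, 3L, 2L, 4L))            # (Cg, HW, G, N)
  m2 <- matrix(ap, Cg * HW, G * N)
  mu <- colMeans(m2)
  xc <- sweep(m2, 2L, mu, "-")
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xh2 <- sweep(xc, 2L, istd, "*")
  back_perm <- function(m) {
    aa <- array(m, c(Cg, HW, G, N))
    array(aperm(aa, c(1L, 3L, 2L, 4L)), c(C, HW * N))
  }
  xh <- back_perm(xh2)
  ad_op(xh, list(x), function(g) {
    ga <- array(g, c(Cg, G, HW, N))
    g2 <- matrix(aperm(ga, c(1L, 3L, 2L, 4L)), Cg * HW, G * N)
    gm <- colMeans(g2)
    gxh <- colMeans(g2 * xh2)
    dx2 <- sweep(sweep(g2, 2L, gm, "-") - sweep(xh2, 2L, gxh, "*"), 2L, istd, "*")
    list(back_perm(dx2))
  })
}

# --- spatial ops ------------------------------------------------------------
# Feature maps are matrices (C, H*W*N): spatial index fastest (column-major
# H then W), image index slowest.

# zero padding of the spatial dims
ad_pad_spatial <- function(x, C, H, W, N, pad) {
  if (pad == 0L) return(x)
  xv <- vof(x)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  inner <- .sp_inner_idx(H, W, N, pad)
  out <- matrix(0, C, Hp * Wp * N)
  out[, inner] <- xv
  ad_op(out, list(x), function(g) list(g[, inner, drop = FALSE]))
}

# column indices of the unpadded interior inside the padded layout
.sp_inner_idx <- function(H, W, N, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  hh <- rep.int(seq_len(H) + pad, W * N)
  ww <- rep.int(rep(seq_len(W) + pad, each = H), N)
  nn <- rep(seq_len(N) - 1L, each = H * W)
  hh + (ww - 1L) * Hp + nn * Hp * Wp
}

# column indices selecting the (ki,kj) shifted, strided window grid
.sp_win_idx <- function(Hp, Wp, N, ki, kj, stride, Ho, Wo) {
  hh <- rep.int(ki + (seq_len(Ho) - 1L) * stride, Wo * N)
  ww <- rep.int(rep(kj + (seq_len(Wo) - 1L) * stride, each = Ho), N)
  nn <- rep(seq_len(N) - 1L, each = Ho * Wo)
  hh + (ww - 1L) * Hp + nn * Hp * Wp
}

conv_out_side <- function(side, k, stride, pad) (side + 2L * pad - k) %/% stride + 1L

# im2col: returns (C*k*k, Ho*Wo*N); row blocks ordered by (ki, kj)
ad_im2col <- function(x, C, H, W, N, k, stride, pad) {
  xp <- ad_pad_spatial(x, C, H, W, N, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- conv_out_side(H, k, stride, pad)
  Wo <- conv_out_side(W, k, stride, pad)
  blocks <- vector("list", k * k)
  b <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    b <- b + 1L
    blocks[[b]] <- ad_cols(xp, .sp_win_idx(Hp, Wp, N, ki, kj, stride, Ho, Wo))
  }
  ad_rbind_list(blocks)
}

# standard convolution via im2col + matmul; w is (C_out, C_in*k*k)
ad_conv2d <- function(x, w, C, H, W, N, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  if (k == 1L && stride == 1L && pad == 0L) return(ad_matmul(w, x))
  cols <- ad_im2col(x, C, H, W, N, k, stride, pad)
  ad_matmul(w, cols)
}

# depthwise convolution; w is (C, k*k) with columns ordered by (ki, kj)
ad_dwconv2d <- function(x, w, C, H, W, N, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  xp <- ad_pad_spatial(x, C, H, W, N, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- conv_out_side(H, k, stride, pad)
  Wo <- conv_out_side(W, k, stride, pad)
  out <- NULL
  b <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    b <- b + 1L
    blk <- ad_cols(xp, .sp_win_idx(Hp, Wp, N, ki, kj, stride, Ho, Wo))
    term <- ad_mul_colvec(blk, if (ad_is_node(w)) ad_wcol(w, b) else vof(w)[, b])
    out <- if (is.null(out)) term else ad_add(out, term)
  }
  out
}

# column b of a (possibly node) weight matrix, as a vector
ad_wcol <- function(w, b) {
  wv <- vof(w)
  ad_op(wv[, b], list(w), function(g) {
    gw <- matrix(0, nrow(wv), ncol(wv))
    gw[, b] <- g
    list(gw)
  })
}

# global average pool over spatial dims -> (C, N)
ad_gap <- function(x, C, HW, N) {
  xv <- vof(x)
  out <- matrix(0, C, N)
  for (n in seq_len(N))
    out[, n] <- .rowMeans(xv[, ((n - 1L) * HW + 1L):(n * HW), drop = FALSE], C, HW)
  ad_op(out, list(x), function(g) {
    gx <- matrix(0, C, HW * N)
    for (n in seq_len(N))
      gx[, ((n - 1L) * HW + 1L):(n * HW)] <- g[, n] / HW
    list(gx)
  })
}

# repeat per-image channel vector v (C, N) across HW columns -> (C, HW*N)
ad_rep_spatial <- function(v, C, HW, N) {
  vv <- vof(v)
  out <- matrix(0, C, HW * N)
  for (n in seq_len(N)) out[, ((n - 1L) * HW + 1L):(n * HW)] <- vv[, n]
  ad_op(out, list(v), function(g) {
    a <- array(g, c(C, HW, N))
    gv <- apply(a, c(1L, 3L), sum)
    dim(gv) <- c(C, N)
    list(gv)
  })
}
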