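# Parameter store and layer constructors/forwards shared by backbone, neck
# and head. Parameters live as plain arrays in an environment; the training
# loop wraps them in autodiff leaves, inference uses them directly.

param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$arr <- list()
  ps$buf <- list()       # non-trainable buffers (batch-norm running stats)
  ps
}

# active buffer store for batch-norm running statistics during a forward pass
set_buffer_store <- function(ps) {
  old <- .ad$bn_store
  .ad$bn_store <- ps
  invisible(old)
}

p_add <- function(ps, name, value) {
  ps$arr[[name]] <- value
  invisible(name)
}

# Wrap every parameter into a tape leaf; returns named list of nodes.
params_as_leaves <- function(ps) {
  lapply(ps$arr, ad_leaf)
}

param_count_prefix <- function(ps, prefix = "") {
  nm <- names(ps$arr)
  if (nzchar(prefix)) nm <- nm[startsWith(nm, prefix)]
  sum(vapply(ps$arr[nm], length, numeric(1)))
}

kaiming <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

# --- constructors: register parameters, return metadata ---------------------

ly_conv <- function(ps, name, cin, cout, k = 1L, stride = 1L,
                    pad = (k - 1L) %/% 2L, bias = FALSE) {
  p_add(ps, paste0(name, ".w"), kaiming(cout, cin * k * k, cin * k * k))
  if (bias) p_add(ps, paste0(name, ".b"), rep(0, cout))
  list(kind = "conv", name = name, cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), bias = bias)
}

ly_dwconv <- function(ps, name, C, k, stride = 1L) {
  p_add(ps, paste0(name, ".w"), kaiming(C, k * k, k * k))
  list(kind = "dwconv", name = name, C = C, k = as.integer(k),
       stride = as.integer(stride), pad = (as.integer(k) - 1L) %/% 2L)
}

ly_bn <- function(ps, name, C) {
  p_add(ps, paste0(name, ".g"), rep(1, C))
  p_add(ps, paste0(name, ".b"), rep(0, C))
  list(kind = "bn", name = name, C = C)
}

ly_gn <- function(ps, name, C, G) {
  stopifnot(C %% G == 0)
  p_add(ps, paste0(name, ".g"), rep(1, C))
  p_add(ps, paste0(name, ".b"), rep(0, C))
  list(kind = "gn", name = name, C = C, G = as.integer(G))
}

ly_ln <- function(ps, name, D) {
  p_add(ps, paste0(name, ".g"), rep(1, D))
  p_add(ps, paste0(name, ".b"), rep(0, D))
  list(kind = "ln", name = name, D = D)
}

ly_linear <- function(ps, name, din, dout, bias = TRUE, zero = FALSE) {
  w <- if (zero) matrix(0, dout, din) else kaiming(dout, din, din)
  p_add(ps, paste0(name, ".w"), w)
  if (bias) p_add(ps, paste0(name, ".b"), rep(0, dout))
  list(kind = "linear", name = name, din = din, dout = dout, bias = bias)
}

ly_embed <- function(ps, name, n, D) {
  p_add(ps, paste0(name, ".w"), matrix(stats::rnorm(D * n, 0, 0.02), D, n))
  list(kind = "embed", name = name, n = n, D = D)
}

# --- forwards ---------------------------------------------------------------
# Feature maps: matrices (C, H*W*N); token sets: matrices (D, L).

f_conv <- function(P, m, x, H, W, N) {
  out <- ad_conv2d(x, P[[paste0(m$name, ".w")]], m$cin, H, W, N, m$k, m$stride, m$pad)
  if (isTRUE(m$bias)) out <- ad_add_colvec(out, P[[paste0(m$name, ".b")]])
  list(x = out,
       H = conv_out_side(H, m$k, m$stride, m$pad),
       W = conv_out_side(W, m$k, m$stride, m$pad))
}

f_dwconv <- function(P, m, x, H, W, N) {
  out <- ad_dwconv2d(x, P[[paste0(m$name, ".w")]], m$C, H, W, N, m$k, m$stride, m$pad)
  list(x = out,
       H = conv_out_side(H, m$k, m$stride, m$pad),
       W = conv_out_side(W, m$k, m$stride, m$pad))
}

# Batch norm: batch statistics while a tape is active (training), running
# statistics at inference once any have been accumulated (momentum 0.1).
f_bn <- function(P, m, x, eps = 1e-5, momentum = 0.1) {
  precise <- isTRUE(.ad$bn_precise)      # exact one-pass stat refresh
  training <- !is.null(.ad$tape) || precise
  if (precise) momentum <- 1
  st <- .ad$bn_store
  mkey <- paste0(m$name, ".running_mean"); vkey <- paste0(m$name, ".running_var")
  if (training || is.null(st) || is.null(st$buf[[mkey]])) {
    xh <- ad_bn_core(x, eps)
    if (training && !is.null(st)) {
      xv <- vof(x)
      mu <- rowMeans(xv)
      va <- rowMeans((xv - mu)^2)
      om <- st$buf[[mkey]]; ov <- st$buf[[vkey]]
      if (is.null(om)) { om <- mu; ov <- va }
      st$buf[[mkey]] <- (1 - momentum) * om + momentum * mu
      st$buf[[vkey]] <- (1 - momentum) * ov + momentum * va
    }
  } else {
    xh <- (vof(x) - st$buf[[mkey]]) / sqrt(st$buf[[vkey]] + eps)
  }
  ad_add_colvec(ad_mul_colvec(xh, P[[paste0(m$name, ".g")]]), P[[paste0(m$name, ".b")]])
}

f_gn <- function(P, m, x, HW, N, eps = 1e-5) {
  xh <- ad_gn_core(x, m$C, HW, N, m$G, eps)
  ad_add_colvec(ad_mul_colvec(xh, P[[paste0(m$name, ".g")]]), P[[paste0(m$name, ".b")]])
}

f_ln <- function(P, m, x, eps = 1e-5) {
  xh <- ad_ln_core(x, eps)
  ad_add_colvec(ad_mul_colvec(xh, P[[paste0(m$name, ".g")]]), P[[paste0(m$name, ".b")]])
}

f_linear <- function(P, m, x) {
  out <- ad_matmul(P[[paste0(m$name, ".w")]], x)
  if (isTRUE(m$bias)) out <- ad_add_colvec(out, P[[paste0(m$name, ".b")]])
  out
}

# parameter counts per layer metadata (used by the analytic profiler)
ly_params <- function(m) {
  switch(m$kind,
    conv = m$cout * m$cin * m$k^2 + if (isTRUE(m$bias)) m$cout else 0,
    dwconv = m$C * m$k^2,
    bn = 2 * m$C, gn = 2 * m$C, ln = 2 * m$D,
    linear = m$dout * m$din + if (isTRUE(m$bias)) m$dout else 0,
    embed = m$n * m$D,
    stop("unknown layer kind"))
}

# multiply-accumulate count at given input spatial size (convs) or token
# count (linears); one MAC per weight-input product
ly_macs <- function(m, H = NULL, W = NULL, L = NULL) {
  switch(m$kind,
    conv = {
      Ho <- conv_out_side(H, m$k, m$stride, m$pad)
      Wo <- conv_out_side(W, m$k, m$stride, m$pad)
      m$cout * m$cin * m$k^2 * Ho * Wo
    },
    dwconv = {
      Ho <- conv_out_side(H, m$k, m$stride, m$pad)
      Wo <- conv_out_side(W, m$k, m$stride, m$pad)
      m$C * m$k^2 * Ho * Wo
    },
    linear = m$dout * m$din * L,
    0)
}
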