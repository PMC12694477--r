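# Shared fixtures and independent oracles for the test suite.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

smoke_model <- function() fixture("smoke_model", function()
  soystage_model("smoke", seed = 42))

smoke_dataset <- function() fixture("smoke_dataset", function()
  generate_dataset(10, dir = NULL, spec = scene_spec(side = 64, small_fraction = 0),
                   seed = 9))

tiny_pyramid <- function(D = 32L, sides = c(16L, 8L, 4L, 2L), seed = 3) {
  set.seed(seed)
  out <- lapply(sides, function(s) array(rnorm(D * s * s), c(D, s, s)))
  names(out) <- paste0("P", seq(3, length.out = length(sides)))
  out
}

tiny_head <- function(enc = 2L, dec = 2L, seed = 5) {
  build_head(head_config(num_encoder_layers = enc, num_decoder_layers = dec,
                         embed_dim = 32L, num_queries = 10L, ffn_dim = 64L,
                         num_heads = 2L, sampling_points = 2L, mlp_hidden = 16L,
                         num_levels = 4L), seed = seed)
}

# exhaustive minimum-cost assignment over all injections (rows -> columns)
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i], k - 1)) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf; bestp <- NULL
  for (p in perms(seq_len(m), n)) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) { best <- s; bestp <- p }
  }
  list(cost = best, assignment = bestp)
}

# Independent scalar-loop implementation of the COCO protocol (area "all"):
# per-image greedy matching in score order, global accumulation, 101-point
# interpolated precision, mean over IoU thresholds and GT-present classes.
oracle_coco_ap <- function(dets, gts, iou_thrs = seq(0.5, 0.95, by = 0.05)) {
  box_iou <- function(a, b) {
    ax2 <- a[1] + a[3]; ay2 <- a[2] + a[4]
    bx2 <- b[1] + b[3]; by2 <- b[2] + b[4]
    iw <- min(ax2, bx2) - max(a[1], b[1])
    ih <- min(ay2, by2) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    inter / (a[3] * a[4] + b[3] * b[4] - inter)
  }
  classes <- sort(unique(gts$category_id))
  aps <- c()
  for (cl in classes) {
    g_all <- gts[gts$category_id == cl, , drop = FALSE]
    d_all <- dets[dets$category_id == cl, , drop = FALSE]
    for (t in iou_thrs) {
      scores <- numeric(0); hits <- logical(0)
      for (img in unique(c(g_all$image_id, d_all$image_id))) {
        g <- g_all[g_all$image_id == img, , drop = FALSE]
        d <- d_all[d_all$image_id == img, , drop = FALSE]
        d <- d[order(d$score, decreasing = TRUE), , drop = FALSE]
        used <- rep(FALSE, nrow(g))
        for (i in seq_len(nrow(d))) {
          best <- t - 1e-12; pick <- 0
          for (j in seq_len(nrow(g))) {
            if (used[j]) next
            iou <- box_iou(as.numeric(d[i, c("x", "y", "w", "h")]),
                           as.numeric(g[j, c("x", "y", "w", "h")]))
            if (iou >= best) { best <- iou; pick <- j }
          }
          hit <- FALSE
          if (pick > 0) { used[pick] <- TRUE; hit <- TRUE }
          scores <- c(scores, d$score[i]); hits <- c(hits, hit)
        }
      }
      npig <- nrow(g_all)
      ord <- order(scores, decreasing = TRUE)
      hits <- hits[ord]
      ap <- 0
      if (length(hits)) {
        tp <- cumsum(hits); fp <- cumsum(!hits)
        rec <- tp / npig; prec <- tp / (tp + fp)
        qs <- numeric(101)
        for (ri in 0:100) {
          r <- ri / 100
          ok <- which(rec >= r - 1e-12)
          qs[ri + 1] <- if (length(ok)) max(prec[ok[1]:length(prec)]) else 0
        }
        ap <- mean(qs)
      }
      aps <- c(aps, ap)
    }
  }
  100 * mean(aps)
}

# random small detection instances for oracle comparisons
random_instance <- function(seed) {
  set.seed(seed)
  n_img <- sample(1:3, 1)
  gts <- NULL; dets <- NULL
  for (img in seq_len(n_img)) {
    ng <- sample(1:3, 1)
    for (j in seq_len(ng)) {
      b <- c(runif(1, 0, 400), runif(1, 0, 400), runif(1, 20, 100), runif(1, 20, 100))
      cl <- sample(0:1, 1)
      gts <- rbind(gts, data.frame(image_id = img, category_id = cl,
                                   x = b[1], y = b[2], w = b[3], h = b[4]))
      nd <- sample(0:2, 1)
      for (k in seq_len(nd)) {
        jit <- b + c(rnorm(2, 0, 25), rnorm(2, 0, 12))
        jit[3:4] <- pmax(jit[3:4], 5)
        dets <- rbind(dets, data.frame(image_id = img,
                                       category_id = sample(0:1, 1),
                                       score = runif(1),
                                       x = jit[1], y = jit[2],
                                       w = jit[3], h = jit[4]))
      }
    }
  }
  if (is.null(dets))
    dets <- data.frame(image_id = integer(0), category_id = integer(0),
                       score = numeric(0), x = numeric(0), y = numeric(0),
                       w = numeric(0), h = numeric(0))
  list(dets = dets, gts = gts)
}
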