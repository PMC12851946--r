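# Attention-based multiple-instance learning on tile bags. The desk-scale
# encoder is a 3-block CNN (3x3 convs, average pooling, global average
# pooling) trained end-to-end together with a gated-attention pooling head
# and a linear 3-class classifier under class-weighted cross-entropy.
# Everything (forward, backward, Adam) is implemented with BLAS-batched
# im2col matrix products; given a seed, training is bit-reproducible.
#
# Tile tensors use (channels, height, width) flattening: index
# c + C*(y-1) + C*H*(x-1); im2col rows are ordered (channel fastest, then
# kernel dy, then kernel dx), matching the weight layout.

# ---- tensor plumbing --------------------------------------------------------

# H x W x 3 image array -> flattened (C*H*W) vector in (C,H,W) layout,
# centered/scaled (H&E tiles are bright; removing the DC component keeps the
# ReLU blocks well-conditioned)
flatten_tile <- function(img) (as.numeric(aperm(img, c(3, 1, 2))) - 0.8) / 0.25

# im2col gather index for a 3x3 same-convolution; pad pixels point at the
# zero sentinel row (C*H*W + 1)
make_im2col_idx <- function(C, H, W) {
  pad <- C * H * W + 1L
  y0 <- rep(seq_len(H), times = W)           # output pixel order: y fastest
  x0 <- rep(seq_len(W), each = H)
  rows <- vector("list", 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    iy <- y0 + dy; ix <- x0 + dx
    ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    base <- ifelse(ok, C * (iy - 1) + C * H * (ix - 1), NA_integer_)
    # C consecutive channel indices per (dy,dx); C fastest within the block
    block <- matrix(NA_integer_, C, H * W)
    for (cc in seq_len(C)) block[cc, ] <- base + cc
    block[, !ok] <- pad
    rows[[k]] <- block
  }
  idx <- do.call(rbind, rows)                # (9C) x (H*W)
  storage.mode(idx) <- "integer"
  idx
}

# batched same-conv forward: Xf (C*H*W x n) -> list(out (Cout x HW*n), xcol)
conv_forward <- function(Xf, idx, Wt, b) {
  n <- ncol(Xf)
  Xext <- rbind(Xf, 0)
  xcol <- Xext[as.integer(idx), , drop = FALSE]       # (9C*HW) x n
  dim(xcol) <- c(nrow(idx), ncol(idx) * n)            # (9C) x (HW*n)
  out <- Wt %*% xcol + b
  list(out = out, xcol = xcol)
}

# backward through the same conv: returns grads and input gradient
conv_backward <- function(dY, xcol, idx, Wt, C, H, W, n, need_dx = TRUE) {
  dW <- dY %*% t(xcol)
  db <- rowSums(dY)
  dx <- NULL
  if (need_dx) {
    dXcol <- t(Wt) %*% dY                              # (9C) x (HW*n)
    dim(dXcol) <- c(length(idx), n)                    # (9C*HW) x n
    grp <- as.integer(idx)
    acc <- rowsum(dXcol, grp)                          # sorted by index
    keep <- as.integer(rownames(acc)) <= C * H * W
    dx <- matrix(0, C * H * W, n)
    dx[as.integer(rownames(acc))[keep], ] <- acc[keep, , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

# 2x2 average pool on (C, H*W*n) matrices; returns pooled matrix
avgpool2 <- function(Y, C, H, W, n) {
  a <- array(Y, c(C, H, W, n))
  o <- (a[, seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
        a[, seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
        a[, seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
        a[, seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
  matrix(o, C, (H / 2) * (W / 2) * n)
}

avgpool2_backward <- function(dO, C, H, W, n) {
  # H, W are the *input* dims; spread gradient / 4
  d <- array(dO / 4, c(C, H / 2, W / 2, n))
  out <- array(0, c(C, H, W, n))
  out[, seq(1, H, 2), seq(1, W, 2), ] <- d
  out[, seq(2, H, 2), seq(1, W, 2), ] <- d
  out[, seq(1, H, 2), seq(2, W, 2), ] <- d
  out[, seq(2, H, 2), seq(2, W, 2), ] <- d
  matrix(out, C, H * W * n)
}

# global average pooling (C x HW*n) -> (C x n)
gap_forward <- function(Y, C, HW, n) {
  a <- array(Y, c(C, HW, n))
  o <- matrix(0, C, n)
  for (t in seq_len(n)) o[, t] <- rowMeans(a[, , t, drop = FALSE][, , 1])
  o
}

# ---- model definition -------------------------------------------------------

#' MIL classifier configuration
#'
#' @param tile_px tile side expected by the encoder (default 64).
#' @param channels widths of the three conv blocks.
#' @param attention_width hidden width of the gated-attention head.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param class_weights "balanced" (inverse frequency) or a numeric 3-vector.
#' @param augment apply random 90-degree rotations/flips during training.
#' @param seed training seed (fixed by default; same seed = identical model).
#' @return list of class `mil_config`.
#' @export
mil_config <- function(tile_px = 64, channels = c(8, 16, 32),
                       attention_width = 16, epochs = 8, lr = 1e-3,
                       class_weights = "balanced", augment = TRUE,
                       seed = 1L) {
  structure(list(tile_px = as.integer(tile_px), channels = channels,
                 attention_width = attention_width, epochs = epochs, lr = lr,
                 class_weights = class_weights, augment = augment,
                 seed = as.integer(seed)), class = "mil_config")
}

mil_init_params <- function(cfg) {
  C <- cfg$channels
  M <- cfg$attention_width
  D <- C[3]
  he <- function(fan_in, nr, nc) {
    matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  list(
    W1 = he(27, C[1], 27), b1 = numeric(C[1]),
    W2 = he(9 * C[1], C[2], 9 * C[1]), b2 = numeric(C[2]),
    W3 = he(9 * C[2], C[3], 9 * C[2]), b3 = numeric(C[3]),
    V = he(D, M, D), bv = numeric(M),
    U = he(D, M, D), bu = numeric(M),
    wa = matrix(rnorm(M, 0, sqrt(1 / M)), 1, M),
    Wc = he(D, 3, D), bc = numeric(3)
  )
}

# geometry for a config: dims at each stage
mil_geom <- function(cfg) {
  px <- cfg$tile_px
  stopifnot(px %% 8 == 0)
  list(px = px,
       h1 = px, h2 = px / 4, h3 = px / 8,   # conv1 @ px, pool4 -> conv2, pool2 -> conv3
       idx1 = make_im2col_idx(3, px, px),
       idx2 = make_im2col_idx(cfg$channels[1], px / 4, px / 4),
       idx3 = make_im2col_idx(cfg$channels[2], px / 8, px / 8))
}

# full encoder forward for a batch of flattened tiles Xf (3*px^2 x n).
# Returns embeddings plus caches for backward / Grad-CAM.
encoder_forward <- function(Xf, p, g, C) {
  n <- ncol(Xf)
  c1 <- conv_forward(Xf, g$idx1, p$W1, p$b1)
  r1 <- pmax(c1$out, 0)
  p1 <- avgpool2(r1, C[1], g$h1, g$h1, n)
  p1 <- avgpool2(p1, C[1], g$h1 / 2, g$h1 / 2, n)      # pool 4 total
  dim(p1) <- c(C[1] * g$h2^2, n)                       # (C*HW) x n layout
  c2 <- conv_forward(p1, g$idx2, p$W2, p$b2)
  r2 <- pmax(c2$out, 0)
  p2 <- avgpool2(r2, C[2], g$h2, g$h2, n)
  dim(p2) <- c(C[2] * g$h3^2, n)
  c3 <- conv_forward(p2, g$idx3, p$W3, p$b3)
  r3 <- pmax(c3$out, 0)                                # last conv activations
  hw3 <- g$h3 * g$h3
  emb <- gap_forward(r3, C[3], hw3, n)
  list(emb = emb, n = n, c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
       p2 = p2, c3 = c3, r3 = r3, hw3 = hw3)
}

# gated-attention pooling + linear classifier; emb (D x n)
head_forward <- function(emb, p) {
  pre_v <- p$V %*% emb + p$bv
  pre_u <- p$U %*% emb + p$bu
  tv <- tanh(pre_v)
  su <- 1 / (1 + exp(-pre_u))
  gate <- tv * su
  e <- as.numeric(p$wa %*% gate)                 # attention logits
  a <- exp(e - max(e)); a <- a / sum(a)
  z <- as.numeric(emb %*% a)                     # slide embedding
  logits <- as.numeric(p$Wc %*% z + p$bc)
  pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
  list(pre_v = pre_v, pre_u = pre_u, tv = tv, su = su, gate = gate,
       e = e, a = a, z = z, logits = logits, probs = pr)
}

# backward for one bag. y in 0..2; cw = class weights. Returns gradient list
# (same shapes as params) and the loss.
mil_backward <- function(Xf, y, p, g, C, cw) {
  n <- ncol(Xf)
  enc <- encoder_forward(Xf, p, g, C)
  hd <- head_forward(enc$emb, p)
  w <- cw[y + 1]
  loss <- -w * log(max(hd$probs[y + 1], 1e-12))
  dlogits <- w * hd$probs
  dlogits[y + 1] <- dlogits[y + 1] - w
  gWc <- tcrossprod(dlogits, hd$z)
  gbc <- dlogits
  dz <- as.numeric(crossprod(p$Wc, dlogits))     # D
  da <- as.numeric(crossprod(enc$emb, dz))       # n
  # softmax jacobian
  de <- hd$a * (da - sum(da * hd$a))
  dgate <- p$wa[1, ] %o% de                      # M x n
  gwa <- matrix(as.numeric(hd$gate %*% de), 1)
  dtv <- dgate * hd$su
  dsu <- dgate * hd$tv
  dpre_v <- dtv * (1 - hd$tv^2)
  dpre_u <- dsu * hd$su * (1 - hd$su)
  gV <- tcrossprod(dpre_v, enc$emb)
  gbv <- rowSums(dpre_v)
  gU <- tcrossprod(dpre_u, enc$emb)
  gbu <- rowSums(dpre_u)
  demb <- crossprod(p$V, dpre_v) + crossprod(p$U, dpre_u) +
    dz %o% hd$a                                  # D x n
  # GAP backward -> (C3, hw3*n)
  dr3 <- matrix(0, C[3], enc$hw3 * n)
  for (t in seq_len(n)) {
    cols <- ((t - 1) * enc$hw3 + 1):(t * enc$hw3)
    dr3[, cols] <- demb[, t] / enc$hw3
  }
  dc3 <- dr3 * (enc$c3$out > 0)
  bw3 <- conv_backward(dc3, enc$c3$xcol, g$idx3, p$W3,
                       C[2], g$h3, g$h3, n)
  dp2 <- bw3$dx
  dr2 <- avgpool2_backward(matrix(dp2, C[2], (g$h2 / 2)^2 * n),
                           C[2], g$h2, g$h2, n)
  dc2 <- dr2 * (enc$c2$out > 0)
  bw2 <- conv_backward(dc2, enc$c2$xcol, g$idx2, p$W2,
                       C[1], g$h2, g$h2, n)
  dp1 <- bw2$dx
  dmid <- avgpool2_backward(matrix(dp1, C[1], (g$h1 / 4)^2 * n),
                            C[1], g$h1 / 2, g$h1 / 2, n)
  dr1 <- avgpool2_backward(dmid, C[1], g$h1, g$h1, n)
  dc1 <- dr1 * (enc$c1$out > 0)
  bw1 <- conv_backward(dc1, enc$c1$xcol, g$idx1, p$W1,
                       3, g$h1, g$h1, n, need_dx = FALSE)
  grads <- list(W1 = bw1$dW, b1 = bw1$db, W2 = bw2$dW, b2 = bw2$db,
                W3 = bw3$dW, b3 = bw3$db, V = gV, bv = gbv, U = gU,
                bu = gbu, wa = gwa, Wc = gWc, bc = gbc)
  list(grads = grads, loss = loss, probs = hd$probs)
}

# random 90-degree rotation / flip of an H x W x 3 tile
augment_tile <- function(img) {
  k <- sample(0:3, 1)
  if (k > 0) for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
  }
  if (runif(1) < 0.5) img <- img[, dim(img)[2]:1, , drop = FALSE]
  img
}

#' Train the attention-MIL classifier
#'
#' Minimizes class-weighted cross-entropy on slide-level labels with Adam,
#' training the CNN encoder, gated-attention pooling and linear classifier
#' end-to-end. Deterministic given `config$seed`.
#'
#' @param bags list of bags; each bag is a list with `tiles` (list of
#'   H x W x 3 arrays) and `label` (0 = osteoporotic, 1 = traumatic,
#'   2 = neoplastic).
#' @param config a [mil_config()].
#' @param verbose print per-epoch loss.
#' @return object of class `mil_model` (parameters, config, training log).
#' @export
train_mil <- function(bags, config = mil_config(), verbose = FALSE) {
  labels <- vapply(bags, function(b) b$label, numeric(1))
  abort_if(length(unique(labels)) < 2,
           "training set must contain at least two classes")
  cw <- if (identical(config$class_weights, "balanced")) {
    tab <- tabulate(labels + 1, 3)
    length(labels) / (3 * pmax(tab, 1))     # inverse-frequency weights
  } else if (identical(config$class_weights, "none")) {
    rep(1, 3)
  } else as.numeric(config$class_weights)
  g <- mil_geom(config)
  C <- config$channels
  with_seed(config$seed, {
    p <- mil_init_params(config)
    mstate <- lapply(p, function(x) x * 0)
    vstate <- lapply(p, function(x) x * 0)
    tstep <- 0
    log <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(seq_along(bags))
      tot <- 0
      for (bi in ord) {
        b <- bags[[bi]]
        tiles <- b$tiles
        if (isTRUE(config$augment)) tiles <- lapply(tiles, augment_tile)
        Xf <- vapply(tiles, flatten_tile, numeric(3 * g$px^2))
        res <- mil_backward(Xf, b$label, p, g, C, cw)
        tot <- tot + res$loss
        tstep <- tstep + 1
        b1c <- 1 - 0.9^tstep; b2c <- 1 - 0.999^tstep
        for (nm in names(p)) {
          gr <- res$grads[[nm]]
          mstate[[nm]] <- 0.9 * mstate[[nm]] + 0.1 * gr
          vstate[[nm]] <- 0.999 * vstate[[nm]] + 0.001 * gr^2
          p[[nm]] <- p[[nm]] - config$lr * (mstate[[nm]] / b1c) /
            (sqrt(vstate[[nm]] / b2c) + 1e-8)
        }
      }
      log[ep] <- tot / length(bags)
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, log[ep]))
    }
    structure(list(params = p, config = config, class_weights = cw,
                   train_loss = log),
              class = "mil_model")
  })
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> 3-block CNN (D=%d), %d epochs, final loss %.4f\n",
              x$config$channels[3], x$config$epochs,
              tail(x$train_loss, 1)))
  invisible(x)
}

#' Encode tiles into embedding vectors
#'
#' @param model trained [train_mil()] model.
#' @param tiles list of H x W x 3 arrays (or a `tile_bag`).
#' @return n x D matrix of embeddings (deterministic; permutation of tiles
#'   permutes rows identically).
#' @export
encode_tiles <- function(model, tiles) {
  if (inherits(tiles, "tile_bag")) tiles <- tiles$tiles
  abort_if(length(tiles) == 0, "empty bag")
  g <- mil_geom(model$config)
  Xf <- vapply(tiles, flatten_tile, numeric(3 * g$px^2))
  enc <- encoder_forward(Xf, model$params, g, model$config$channels)
  t(enc$emb)
}

#' Gated-attention pooling of embeddings
#'
#' @param model trained model.
#' @param embeddings n x D matrix.
#' @return list(slide_embedding, attention) with attention summing to 1.
#' @export
attention_pool <- function(model, embeddings) {
  abort_if(nrow(embeddings) < 1, "need at least one tile")
  hd <- head_forward(t(embeddings), model$params)
  list(slide_embedding = hd$z, attention = hd$a)
}

#' Predict a slide from its tile bag
#'
#' @param model trained model.
#' @param bag a `tile_bag` or list with `tiles`.
#' @return object of class `slide_prediction`: list(class_probs,
#'   predicted_class, attention, slide_id). Probabilities sum to 1; attention
#'   sums to 1; argmax ties break to the lowest class index.
#' @export
predict_slide <- function(model, bag) {
  abort_if(!inherits(model, "mil_model"), "untrained or invalid model")
  tiles <- if (inherits(bag, "tile_bag") || is.list(bag$tiles)) bag$tiles else bag
  abort_if(length(tiles) == 0, "empty bag")
  g <- mil_geom(model$config)
  Xf <- vapply(tiles, flatten_tile, numeric(3 * g$px^2))
  enc <- encoder_forward(Xf, model$params, g, model$config$channels)
  hd <- head_forward(enc$emb, model$params)
  structure(list(
    class_probs = setNames(hd$probs, names(VCF_CLASSES)),
    predicted_class = unname(which.max(hd$probs) - 1L),  # ties: lowest index
    attention = hd$a,
    slide_id = bag$slide_id %||% NA_character_
  ), class = "slide_prediction")
}

#' Grad-CAM heatmap for one tile
#'
#' Channel weights are the spatial mean of the target-class logit gradient
#' at the last convolutional layer; the map is the rectified weighted sum of
#' activations, bilinearly upsampled to tile size and min-max scaled to
#' \[0,1\]. Constant tiles produce an all-zero map flagged degenerate.
#'
#' @param model trained model.
#' @param tile H x W x 3 array.
#' @param target_class 0, 1 or 2.
#' @return H x W matrix in \[0,1\] with attribute `degenerate`.
#' @export
gradcam <- function(model, tile, target_class) {
  g <- mil_geom(model$config)
  C <- model$config$channels
  px <- g$px
  if (max(tile) - min(tile) < 1e-9) {
    out <- matrix(0, px, px)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  Xf <- matrix(flatten_tile(tile), ncol = 1)
  enc <- encoder_forward(Xf, model$params, g, C)
  A <- matrix(enc$r3, C[3], enc$hw3)            # last conv activations
  # d logit_c / d A for a single-tile bag: attention weight is 1, so the
  # gradient through GAP is Wc[c, ch] / hw3, spatially uniform
  alpha <- model$params$Wc[target_class + 1, ] / enc$hw3
  cam <- pmax(colSums(A * alpha), 0)
  cam_m <- matrix(cam, g$h3, g$h3)
  up <- upsample_bilinear(cam_m, px, px)
  rng <- max(up) - min(up)
  if (rng < 1e-12) {
    out <- matrix(0, px, px)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (up - min(up)) / rng
  attr(out, "degenerate") <- FALSE
  out
}

#' Attention-weighted slide heatmap composite
#'
#' @param model trained model.
#' @param bag tile bag (with `coords` when available).
#' @param target_class class for Grad-CAM (default: predicted).
#' @return list(tile_maps, attention, composite) where composite is each
#'   tile's map scaled by its attention weight.
#' @export
slide_heatmap <- function(model, bag, target_class = NULL) {
  pred <- predict_slide(model, bag)
  if (is.null(target_class)) target_class <- pred$predicted_class
  maps <- lapply(bag$tiles, gradcam, model = model,
                 target_class = target_class)
  comp <- Map(function(m, a) m * a, maps, as.list(pred$attention))
  list(tile_maps = maps, attention = pred$attention, composite = comp,
       target_class = target_class)
}

# ---- evaluation -------------------------------------------------------------

# one-vs-rest rank AUC; NA if a class is absent
ovr_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (step-wise PR curve)
average_precision <- function(scores, positive) {
  if (!any(positive)) return(NA_real_)
  o <- order(-scores)
  pos <- positive[o]
  cum_tp <- cumsum(pos)
  prec <- cum_tp / seq_along(pos)
  sum(prec[pos]) / sum(pos)
}

#' Classification metrics from labels, predictions and probabilities
#'
#' Overall accuracy, per-class one-vs-rest AUC / average precision /
#' precision / recall / F1, a 3 x 3 confusion matrix, and percentile
#' bootstrap CIs (default 1,000 resamples) for accuracy and macro F1.
#'
#' @param labels true classes (0/1/2).
#' @param pred_class predicted classes (0/1/2).
#' @param probs n x 3 matrix of class probabilities.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list(accuracy, accuracy_ci, macro_f1, macro_f1_ci, per_class,
#'   confusion, predictions).
#' @export
classification_metrics <- function(labels, pred_class, probs, n_boot = 1000,
                                   seed = 1L) {
  conf <- matrix(0L, 3, 3, dimnames = list(true = names(VCF_CLASSES),
                                           pred = names(VCF_CLASSES)))
  for (i in seq_along(labels)) {
    conf[labels[i] + 1, pred_class[i] + 1] <- conf[labels[i] + 1,
                                                   pred_class[i] + 1] + 1L
  }
  per_class <- do.call(rbind, lapply(0:2, function(k) {
    pos <- labels == k
    tp <- sum(pred_class == k & pos)
    fp <- sum(pred_class == k & !pos)
    fn <- sum(pred_class != k & pos)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    data.frame(class = names(VCF_CLASSES)[k + 1],
               auc = ovr_auc(probs[, k + 1], pos),
               average_precision = average_precision(probs[, k + 1], pos),
               precision = prec, recall = rec, f1 = f1,
               n = sum(pos))
  }))
  acc <- mean(pred_class == labels)
  df <- data.frame(pred = pred_class, label = labels)
  macro_f1_fn <- function(d) {
    f1s <- vapply(0:2, function(k) {
      tp <- sum(d$pred == k & d$label == k)
      fp <- sum(d$pred == k & d$label != k)
      fn <- sum(d$pred != k & d$label == k)
      if (2 * tp + fp + fn == 0) return(NA_real_)
      2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    mean(f1s, na.rm = TRUE)
  }
  acc_bs <- bootstrap_ci(df, function(d) mean(d$pred == d$label),
                         B = n_boot, seed = derive_seed(seed, "acc"))
  f1_bs <- bootstrap_ci(df, macro_f1_fn, B = n_boot,
                        seed = derive_seed(seed, "f1"))
  list(accuracy = acc, accuracy_ci = c(acc_bs$lower, acc_bs$upper),
       macro_f1 = macro_f1_fn(df), macro_f1_ci = c(f1_bs$lower, f1_bs$upper),
       per_class = per_class, confusion = conf,
       predictions = data.frame(label = labels, pred = pred_class, probs))
}

#' Evaluate the classifier on labeled bags
#'
#' Runs [predict_slide()] over the bags and computes
#' [classification_metrics()].
#'
#' @param model trained model.
#' @param bags labeled bags (each with `label`).
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return see [classification_metrics()].
#' @export
evaluate_classifier <- function(model, bags, n_boot = 1000, seed = 1L) {
  preds <- lapply(bags, function(b) predict_slide(model, b))
  probs <- do.call(rbind, lapply(preds, function(p) p$class_probs))
  pred_class <- vapply(preds, function(p) p$predicted_class, numeric(1))
  labels <- vapply(bags, function(b) b$label, numeric(1))
  classification_metrics(labels, pred_class, probs, n_boot = n_boot,
                         seed = seed)
}

#' Synthetic MIL cohort of tile bags
#'
#' Each bag mixes shared plain-marrow tiles with class-hallmark tiles
#' (fragmented thin strands + fat for osteoporotic; cleft bands with
#' inflammatory cells for traumatic; dense elongated-nucleus clusters for
#' neoplastic). Planted discriminative masks ride along per tile.
#'
#' @param n_per_class bags per class (default 60).
#' @param tiles_per_bag tiles per bag (default 30).
#' @param tile_px tile side (default 64).
#' @param hallmark_fraction fraction of hallmark tiles per bag.
#' @param blend_fraction fraction of osteoporotic/traumatic hallmark tiles
#'   swapped between those two classes (blurs the osteo-trauma boundary; 0
#'   by default).
#' @param seed integer seed.
#' @return list of bags: list(tiles, label, types, masks, slide_id).
#' @export
synth_mil_cohort <- function(n_per_class = 60, tiles_per_bag = 30,
                             tile_px = 64, hallmark_fraction = 0.5,
                             blend_fraction = 0, seed = 1L) {
  hallmark <- c(osteoporotic = "osteo", traumatic = "trauma",
                neoplastic = "tumor")
  bags <- list()
  k <- 0
  for (cls in names(VCF_CLASSES)) {
    for (b in seq_len(n_per_class)) {
      k <- k + 1
      bseed <- derive_seed(seed, paste0(cls, b))
      bags[[k]] <- with_seed(bseed, {
        n_h <- round(hallmark_fraction * tiles_per_bag)
        types <- c(rep(hallmark[cls], n_h),
                   rep("marrow", tiles_per_bag - n_h))
        if (blend_fraction > 0 && cls %in% c("osteoporotic", "traumatic")) {
          other <- if (cls == "osteoporotic") "trauma" else "osteo"
          n_swap <- round(blend_fraction * n_h)
          if (n_swap > 0) types[seq_len(n_swap)] <- other
        }
        types <- sample(types)
        tls <- lapply(seq_along(types), function(i) {
          render_tile(types[i], px = tile_px,
                      seed = derive_seed(bseed, paste0("t", i)))
        })
        list(tiles = lapply(tls, `[[`, "image"),
             masks = lapply(tls, `[[`, "mask"),
             types = types,
             label = unname(VCF_CLASSES[cls]),
             slide_id = sprintf("%s_%03d", cls, b))
      })
    }
  }
  bags
}
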