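test_that("backward gradients match finite differences on a tiny model", {
  set.seed(2)
  cfg <- mil_config(tile_px = 16, channels = c(4, 5, 6),
                    attention_width = 4, seed = 1)
  g <- spinepath:::mil_geom(cfg)
  p <- spinepath:::mil_init_params(cfg)
  Xf <- matrix(runif(3 * 16 * 16 * 3), ncol = 3)
  y <- 2; cw <- c(1, 1, 1)
  res <- spinepath:::mil_backward(Xf, y, p, g, cfg$channels, cw)
  lossfn <- function(pp) {
    enc <- spinepath:::encoder_forward(Xf, pp, g, cfg$channels)
    hd <- spinepath:::head_forward(enc$emb, pp)
    -log(hd$probs[y + 1])
  }
  eps <- 1e-5
  for (nm in c("W1", "W3", "V", "wa", "Wc", "bc")) {
    i <- sample(length(p[[nm]]), 1)
    p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
    expect_equal(res$grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("encoding is deterministic, shape-correct and permutation-consistent", {
  tm <- get_test_mil()
  tiles <- tm$bags[[1]]$tiles[1:9]
  emb <- encode_tiles(tm$model, tiles)
  expect_equal(dim(emb), c(9, tm$model$config$channels[3]))
  expect_true(all(is.finite(emb)))
  # identical tiles -> identical embeddings
  emb2 <- encode_tiles(tm$model, list(tiles[[1]], tiles[[1]]))
  expect_equal(emb2[1, ], emb2[2, ])
  # permuting tiles permutes embeddings identically
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  expect_equal(encode_tiles(tm$model, tiles[perm]), emb[perm, ],
               tolerance = 1e-12)
  expect_error(encode_tiles(tm$model, list()), "empty")
})

test_that("attention pooling satisfies its symmetry and normalization laws", {
  tm <- get_test_mil()
  emb1 <- encode_tiles(tm$model, tm$bags[[1]]$tiles[1])
  ap1 <- attention_pool(tm$model, emb1)
  expect_equal(ap1$attention, 1)
  expect_equal(ap1$slide_embedding, as.numeric(emb1[1, ]))
  # k identical tiles -> each weight 1/k, slide embedding = tile embedding
  k <- 7
  apk <- attention_pool(tm$model, emb1[rep(1, k), , drop = FALSE])
  expect_equal(apk$attention, rep(1 / k, k))
  expect_equal(apk$slide_embedding, as.numeric(emb1[1, ]), tolerance = 1e-12)
  # weights sum to 1 for random bags of assorted sizes
  set.seed(4)
  for (n in c(1, 3, 17, 100)) {
    e <- matrix(rnorm(n * ncol(emb1)), n)
    expect_equal(sum(attention_pool(tm$model, e)$attention), 1,
                 tolerance = 1e-12)
  }
})

test_that("predictions satisfy simplex constraints and bag symmetries", {
  tm <- get_test_mil()
  b <- tm$bags[[3]]
  p <- predict_slide(tm$model, b)
  expect_equal(sum(p$class_probs), 1, tolerance = 1e-12)
  expect_true(all(p$class_probs >= 0))
  expect_equal(sum(p$attention), 1, tolerance = 1e-12)
  expect_equal(p$predicted_class, unname(which.max(p$class_probs)) - 1L)
  # permutation invariance of slide-level outputs
  perm <- sample(seq_along(b$tiles))
  p2 <- predict_slide(tm$model, list(tiles = b$tiles[perm]))
  expect_equal(p2$class_probs, p$class_probs, tolerance = 1e-6)
  expect_equal(p2$attention, p$attention[perm], tolerance = 1e-6)
  # duplicating every tile leaves class probabilities unchanged
  p3 <- predict_slide(tm$model, list(tiles = c(b$tiles, b$tiles)))
  expect_equal(p3$class_probs, p$class_probs, tolerance = 1e-6)
})

test_that("training rejects single-class data and is seed-deterministic", {
  bags <- synth_mil_cohort(n_per_class = 2, tiles_per_bag = 4, seed = 77)
  one_class <- Filter(function(b) b$label == 0, bags)
  expect_error(train_mil(one_class, mil_config(epochs = 1)), "two classes")
  cfg <- mil_config(epochs = 2, lr = 3e-3, seed = 42)
  m1 <- train_mil(bags, cfg)
  m2 <- train_mil(bags, cfg)
  expect_identical(digest::digest(m1$params), digest::digest(m2$params))
})

test_that("gradcam maps are in [0,1] and degenerate inputs are flagged", {
  tm <- get_test_mil()
  tile <- render_tile("tumor", seed = 123)
  cam <- gradcam(tm$model, tile$image, 2)
  expect_true(all(cam >= 0 & cam <= 1))
  expect_equal(dim(cam), dim(tile$mask))
  expect_false(attr(cam, "degenerate"))
  flat <- gradcam(tm$model, array(0.5, c(64, 64, 3)), 0)
  expect_true(attr(flat, "degenerate"))
  expect_true(all(flat == 0))
})

test_that("classification metrics match hand-computed tallies", {
  labels <- c(0, 0, 0, 1, 1, 1, 2, 2, 2, 0)
  pred   <- c(0, 1, 0, 1, 1, 0, 2, 2, 1, 0)
  set.seed(1)
  probs <- matrix(runif(30), 10, 3)
  probs[cbind(1:10, pred + 1)] <- probs[cbind(1:10, pred + 1)] + 1
  probs <- probs / rowSums(probs)
  m <- classification_metrics(labels, pred, probs, n_boot = 100)
  # brute-force confusion tally
  conf <- matrix(0, 3, 3)
  for (i in 1:10) conf[labels[i] + 1, pred[i] + 1] <-
      conf[labels[i] + 1, pred[i] + 1] + 1
  expect_equal(unname(m$confusion), conf)
  expect_equal(m$accuracy, mean(labels == pred))
  # class 0: tp=3, fp=1, fn=1 -> precision .75, recall .75
  expect_equal(m$per_class$precision[1], 0.75)
  expect_equal(m$per_class$recall[1], 0.75)
  # perfect predictions
  mp <- classification_metrics(labels, labels,
                               diag(3)[labels + 1, ], n_boot = 100)
  expect_equal(mp$accuracy, 1)
  expect_true(all(mp$per_class$f1 == 1))
})

test_that("shuffled predictions give chance-level per-class AUC", {
  set.seed(9)
  n <- 1000
  labels <- sample(0:2, n, replace = TRUE)
  probs <- matrix(runif(3 * n), n)
  probs <- probs / rowSums(probs)
  pred <- max.col(probs) - 1
  m <- classification_metrics(labels, pred, probs, n_boot = 100)
  expect_true(all(abs(m$per_class$auc - 0.5) < 0.05))
})

test_that("an absent class yields NA AUC, not an error", {
  labels <- c(0, 0, 1, 1)
  probs <- matrix(0.34, 4, 3); probs <- probs / rowSums(probs)
  m <- classification_metrics(labels, c(0, 0, 1, 1), probs, n_boot = 100)
  expect_true(is.na(m$per_class$auc[3]))
})

test_that("blending osteoporotic and traumatic bags concentrates confusions there", {
  tm <- get_test_mil()
  blended <- synth_mil_cohort(n_per_class = 6, tiles_per_bag = 10,
                              blend_fraction = 0.5, seed = 314)
  ev <- evaluate_classifier(tm$model, blended, n_boot = 100)
  conf <- ev$confusion
  ot_errors <- conf[1, 2] + conf[2, 1]
  neo_errors <- conf[1, 3] + conf[2, 3] + conf[3, 1] + conf[3, 2]
  expect_gte(ot_errors, neo_errors)
})
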