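make_mixture_image <- function(V, H = 80, W = 80, seed = 1) {
  # random two-stain concentrations with some near-pure pixels
  set.seed(seed)
  n <- H * W
  c1 <- pmax(0, runif(n, 0, 1) * rbinom(n, 1, 0.8))
  c2 <- pmax(0, runif(n, 0, 1) * rbinom(n, 1, 0.8))
  od <- V %*% rbind(c1, c2)
  img <- array(0, c(H, W, 3))
  for (k in 1:3) img[, , k] <- matrix(rgb_from_od(od[k, ]), H, W)
  img
}

test_that("tissue segmentation isolates a two-level image and flags blanks", {
  img <- array(0.9, c(60, 60, 3))
  img[10:40, 10:40, ] <- 0.2
  m <- segment_tissue(img)
  inner <- m[12:38, 12:38]
  expect_true(all(inner))
  expect_false(any(m[1:5, 1:5]))
  expect_warning(m2 <- segment_tissue(array(1, c(32, 32, 3))), "tissue")
  expect_false(any(m2))
})

test_that("Macenko recovers the planted stain vectors within 5 degrees", {
  V <- he_reference_stains()[, 1:2]
  for (seed in c(1, 2)) {
    img <- make_mixture_image(V, seed = seed)
    est <- estimate_stains(img)
    expect_lt(angle_deg(est$stain_matrix[, 1], V[, 1]), 5)
    expect_lt(angle_deg(est$stain_matrix[, 2], V[, 2]), 5)
    # hematoxylin ordered first (larger blue-channel OD)
    expect_gt(est$stain_matrix[3, 1], est$stain_matrix[3, 2])
  }
})

test_that("stain estimation rejects degenerate inputs", {
  V <- he_reference_stains()
  # single stain image -> rank deficiency
  set.seed(5)
  od <- V[, 2, drop = FALSE] %*% matrix(runif(1600, 0.2, 1), 1)
  img <- array(0, c(40, 40, 3))
  for (k in 1:3) img[, , k] <- matrix(rgb_from_od(od[k, ]), 40, 40)
  expect_error(estimate_stains(img), "single stain|rank")
  # nearly blank image -> too few pixels
  expect_error(estimate_stains(array(1, c(40, 40, 3))), "tissue")
})

test_that("self-normalization is the identity within 2 intensity units", {
  r <- render_slide(slide_spec("osteoporotic", image_size = c(256, 256),
                               collagen_fraction_target = 0, seed = 13))
  est <- estimate_stains(r$image, r$truth$masks$tissue)
  out <- normalize_stains(r$image, est, est)
  expect_lt(mean(abs(out - r$image)) * 255, 2)
})

test_that("normalization identities: source == reference, white stays white", {
  V <- he_reference_stains()[, 1:2]
  img <- make_mixture_image(V, seed = 3)
  prof <- estimate_stains(img)
  out <- normalize_stains(img, prof, prof)
  expect_lt(mean(abs(out - img)) * 255, 2)
  img[1:5, 1:5, ] <- 254 / 255
  out2 <- normalize_stains(img, prof, reference_stain_profile())
  expect_true(all(abs(out2[1:5, 1:5, ] - 254 / 255) * 255 < 2))
})

test_that("unmixing isolates the eosin component", {
  V <- he_reference_stains()[, 1:2]
  set.seed(9)
  c1 <- matrix(runif(900, 0.1, 0.8), 30, 30)   # hematoxylin
  c2 <- matrix(runif(900, 0.1, 0.8), 30, 30)   # eosin
  build <- function(c1, c2) {
    od <- V %*% rbind(as.numeric(c1), as.numeric(c2))
    img <- array(0, c(30, 30, 3))
    for (k in 1:3) img[, , k] <- matrix(rgb_from_od(od[k, ]), 30, 30)
    img
  }
  unmix <- function(img) {
    od <- od_from_rgb(img)
    spinepath:::nnls_two(V, rbind(as.numeric(od[, , 1]),
                                  as.numeric(od[, , 2]),
                                  as.numeric(od[, , 3])))
  }
  conc_a <- unmix(build(c1, c2))
  conc_b <- unmix(build(c1, 1.5 * c2))
  # hematoxylin concentrations unchanged, eosin scaled by 1.5
  expect_equal(mean(conc_b[2, ] / pmax(conc_a[2, ], 1e-6)), 1.5,
               tolerance = 0.05)
  expect_equal(mean(conc_b[1, ] - conc_a[1, ]), 0, tolerance = 0.02)
})

test_that("tiling matches the closed-form grid count and edge policy", {
  img <- array(0.4, c(1024, 1024, 3))
  mask <- matrix(TRUE, 1024, 1024)
  cfg <- preprocess_config(tile_size_px = 512, overlap_fraction = 0.5)
  bag <- tile_slide(img, mask, cfg, artifact_checks = FALSE)
  expect_equal(length(bag$tiles), 9)
  expect_setequal(unique(bag$coords$row), c(0, 256, 512))
  expect_setequal(unique(bag$coords$col), c(0, 256, 512))
  # single-tile case
  img2 <- array(0.4, c(512, 512, 3))
  bag2 <- tile_slide(img2, matrix(TRUE, 512, 512), cfg,
                     artifact_checks = FALSE)
  expect_equal(length(bag2$tiles), 1)
  expect_equal(unlist(bag2$coords), c(row = 0, col = 0))
  # closed-form count on assorted geometries, plus one inward-shifted tile
  # per axis whose span is not a stride multiple (documented edge policy)
  for (dims in list(c(640, 896), c(768, 768))) {
    b <- tile_slide(array(0.4, c(dims, 3)), matrix(TRUE, dims[1], dims[2]),
                    cfg, artifact_checks = FALSE)
    S <- 256
    n_axis <- function(L) floor((L - 512) / S) + 1 + ((L - 512) %% S > 0)
    expect_equal(length(b$tiles), n_axis(dims[1]) * n_axis(dims[2]))
  }
  expect_false(any(duplicated(bag$coords)))
})

test_that("tiles blanked beyond 50% are dropped and logged", {
  img <- array(0.4, c(512, 768, 3))
  mask <- matrix(FALSE, 512, 768)
  mask[, 1:199] <- TRUE      # sparse tissue at both bbox ends: both grid
  mask[, 600:768] <- TRUE    # tiles are > 50% blank
  cfg <- preprocess_config(tile_size_px = 512, overlap_fraction = 0.5)
  bag <- tile_slide(img, mask, cfg, artifact_checks = FALSE)
  expect_true(all(bag$qc_log$kept == (bag$qc_log$blank_fraction <= 0.5)))
  expect_true(any(!bag$qc_log$kept))
  dropped <- bag$qc_log[!bag$qc_log$kept, ]
  expect_true(all(dropped$blank_fraction > 0.5))
  expect_warning(
    empty <- tile_slide(img, matrix(FALSE, 512, 768), cfg), "empty")
  expect_equal(length(empty$tiles), 0)
})

test_that("artifact detection flags blur, blank and fold tiles", {
  tile <- render_tile("trauma", px = 64, seed = 8)$image
  cfg <- preprocess_config(tile_size_px = 64)
  clean <- detect_artifacts(tile, cfg)
  expect_false(any(clean))
  blurred <- blur_gaussian(tile, 8)
  expect_true(detect_artifacts(blurred, cfg)[["blur"]])
  expect_true(detect_artifacts(array(1, c(64, 64, 3)), cfg)[["blank"]])
  fold <- tile
  fold[20:50, 20:50, 1] <- 0.05; fold[20:50, 20:50, 2] <- 0.02
  fold[20:50, 20:50, 3] <- 0.25
  expect_true(detect_artifacts(fold, cfg)[["fold"]])
})
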