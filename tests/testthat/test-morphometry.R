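# helper: compose an RGB image from H/E/collagen concentration maps with the
# packaged stain vectors (same convention as the renderer)
compose_stains <- function(ch, ce, cc = NULL) {
  H <- nrow(ch); W <- ncol(ch)
  if (is.null(cc)) cc <- matrix(0, H, W)
  V <- he_reference_stains()
  od <- V %*% rbind(as.numeric(ch), as.numeric(ce), as.numeric(cc))
  img <- array(0, c(H, W, 3))
  for (k in 1:3) img[, , k] <- matrix(rgb_from_od(od[k, ]), H, W)
  img
}

test_that("bone segmentation recovers the planted mask (Dice >= 0.9)", {
  for (cls in c("osteoporotic", "neoplastic")) {
    r <- render_slide(slide_spec(cls, image_size = c(320, 320), seed = 41))
    seg <- segment_bone(r$image, r$truth$masks$tissue)
    truth <- r$truth$masks$bone
    dice <- 2 * sum(seg$bone & truth) / (sum(seg$bone) + sum(truth))
    expect_gte(dice, 0.9)
    expect_false(any(seg$bone & seg$marrow))
    expect_true(all((seg$bone | seg$marrow) == r$truth$masks$tissue))
  }
})

test_that("bone-only and marrow-only fixtures give fraction 1 and 0", {
  bone_img <- compose_stains(matrix(0.07, 96, 96), matrix(0.85, 96, 96))
  tissue <- matrix(TRUE, 96, 96)
  marrow_img <- compose_stains(matrix(0.05, 96, 96), matrix(0.22, 96, 96))
  seg_b <- segment_bone(bone_img, tissue)
  seg_m <- segment_bone(marrow_img, tissue)
  # single-intensity eosin: bone-only ends up all bone or degenerate-empty;
  # fraction within tissue is what matters
  expect_gte(sum(seg_b$bone) / sum(tissue), 0.95)
  expect_equal(sum(seg_m$bone) / sum(tissue), 0, tolerance = 0.02)
})

test_that("bar thickness matches the maximal-inscribed-disc value within 1 px", {
  for (w in c(4, 8, 16, 32)) {
    m <- matrix(FALSE, 128, 160)
    m[50:(50 + w - 1), 16:144] <- TRUE
    tm <- trabecular_metrics(m, microns_per_pixel = 1)
    expect_equal(tm$thickness_um, w, tolerance = 1 / w)
    # separation responds to the complement geometry
    expect_gt(tm$separation_um, w)
  }
})

test_that("disruption score: solid disc contributes no component excess and cuts increase it", {
  disc <- matrix(FALSE, 96, 96)
  yy <- row(disc); xx <- col(disc)
  disc <- (yy - 48)^2 + (xx - 48)^2 <= 30^2
  tm <- trabecular_metrics(disc, 4)
  expect_equal(tm$n_components, 1)
  lattice <- spinepath:::trabecular_lattice(256, 256, 10, 50,
                                            matrix(TRUE, 256, 256),
                                            wobble = FALSE)$mask
  set.seed(12)
  prev <- -Inf
  for (cuts in c(0, 4, 8)) {
    m <- lattice
    if (cuts > 0) {
      ys <- runif(cuts, 25, 230); xs <- runif(cuts, 25, 230)
      for (i in seq_len(cuts)) {
        m <- m & !(((row(m) - ys[i])^2 + (col(m) - xs[i])^2) <= 144)
      }
    }
    sc <- trabecular_metrics(m, 4)$disruption_score
    expect_gt(sc, prev)
    prev <- sc
  }
})

test_that("empty mask yields fraction 0 and missing metrics", {
  tm <- trabecular_metrics(matrix(FALSE, 32, 32), 4)
  expect_equal(tm$bone_fraction, 0)
  expect_true(is.na(tm$thickness_um))
  expect_true(is.na(tm$disruption_score))
})

test_that("marrow adiposity recovers planted vacuole fractions", {
  r <- render_slide(slide_spec("osteoporotic",
                               adiposity_fraction_target = 0.25, seed = 5))
  ad <- marrow_adiposity(r$image, r$truth$masks$marrow)
  expect_equal(ad, r$truth$adiposity_fraction, tolerance = 0.03 / 0.25)
  # no vacuoles -> 0; tumor-packed marrow -> ~0; empty marrow -> NA
  r0 <- render_slide(slide_spec("traumatic", adiposity_fraction_target = 0,
                                fracture_line = FALSE, seed = 6))
  expect_lt(marrow_adiposity(r0$image, r0$truth$masks$marrow), 0.02)
  ch <- matrix(0.85, 96, 96)               # dense nuclei everywhere
  tumor_img <- compose_stains(ch, matrix(0.15, 96, 96))
  expect_lt(marrow_adiposity(tumor_img, matrix(TRUE, 96, 96)), 0.02)
  expect_true(is.na(marrow_adiposity(tumor_img, matrix(FALSE, 96, 96))))
})

test_that("collagen fraction recovers planted fibrosis and doubles below saturation", {
  r <- render_slide(slide_spec("neoplastic", collagen_fraction_target = 0.4,
                               tumor_cluster_count = 0, seed = 17))
  cf <- collagen_fraction(r$image, r$truth$masks$marrow)
  expect_equal(cf$collagen_fraction, r$truth$collagen_fraction,
               tolerance = 0.05 / 0.4)
  r0 <- render_slide(slide_spec("osteoporotic", collagen_fraction_target = 0,
                                seed = 18))
  expect_lt(collagen_fraction(r0$image, r0$truth$masks$marrow)$collagen_fraction,
            0.02)
  r1 <- render_slide(slide_spec("osteoporotic",
                                collagen_fraction_target = 0.1,
                                adiposity_fraction_target = 0.1, seed = 19))
  r2 <- render_slide(slide_spec("osteoporotic",
                                collagen_fraction_target = 0.2,
                                adiposity_fraction_target = 0.1, seed = 19))
  f1 <- collagen_fraction(r1$image, r1$truth$masks$marrow)$collagen_fraction
  f2 <- collagen_fraction(r2$image, r2$truth$masks$marrow)$collagen_fraction
  expect_equal(f2 / f1, 2, tolerance = 0.25)
  expect_equal(cf$fibrosis_score, min(1, cf$collagen_fraction / 0.5))
})

test_that("nucleus eccentricity is exact for analytic ellipses and circles", {
  ch <- matrix(0.05, 96, 96)
  ell <- spinepath:::paint_ellipses(
    ch, data.frame(y = 48, x = 48, a = 24, b = 12, theta = 0.4), 0.9)$field
  img <- compose_stains(ell, matrix(0.2, 96, 96))
  nm <- nuclei_morphometry(img, matrix(FALSE, 96, 96), matrix(TRUE, 96, 96))
  expect_equal(nm$eccentricity_mean, sqrt(3) / 2, tolerance = 0.01 / 0.866)
  circ <- spinepath:::paint_ellipses(
    ch, data.frame(y = c(30, 66), x = c(30, 66), a = 12, b = 12, theta = 0),
    0.9)$field
  img2 <- compose_stains(circ, matrix(0.2, 96, 96))
  nm2 <- nuclei_morphometry(img2, matrix(FALSE, 96, 96), matrix(TRUE, 96, 96))
  expect_lt(nm2$eccentricity_mean, 0.35)
  expect_equal(nrow(nm2$nuclei), 2)
})

test_that("osteocyte lacunae density is recovered within 10%", {
  r <- render_slide(slide_spec("traumatic", fracture_line = FALSE,
                               inflammatory_cell_density_target = 0,
                               lacunae_per_mm2 = 80, seed = 23))
  seg <- list(bone = r$truth$masks$bone, marrow = r$truth$masks$marrow)
  nm <- nuclei_morphometry(r$image, seg$bone, seg$marrow, 4)
  planted <- r$truth$lacunae_count / (sum(seg$bone) / (1000 / 4)^2)
  expect_equal(nm$osteocyte_density_per_mm2, planted, tolerance = 0.10)
})

test_that("feature table has one complete row per case and rejects duplicates", {
  imgs <- list(
    a = render_slide(slide_spec("osteoporotic", image_size = c(256, 256),
                                seed = 1))$image,
    b = render_slide(slide_spec("traumatic", image_size = c(256, 256),
                                seed = 2))$image,
    c = render_slide(slide_spec("neoplastic", image_size = c(256, 256),
                                seed = 3))$image)
  ft <- feature_table(imgs)
  expect_equal(nrow(ft), 3)
  expect_equal(ncol(ft), 12)      # case_id + 11 features
  expect_false(anyNA(ft))
  ft2 <- feature_table(imgs)
  expect_identical(ft, ft2)
  expect_error(feature_table(setNames(imgs, c("a", "a", "b"))), "duplicate")
})

test_that("features are scale-equivariant in microns_per_pixel", {
  m <- matrix(FALSE, 96, 96); m[40:49, 10:86] <- TRUE
  t1 <- trabecular_metrics(m, microns_per_pixel = 4)
  t2 <- trabecular_metrics(m, microns_per_pixel = 2)
  expect_equal(t1$bone_fraction, t2$bone_fraction)
  expect_equal(t1$thickness_um / t2$thickness_um, 2)
  expect_equal(t2$disruption_score / t1$disruption_score, 4,
               tolerance = 1e-10)
})

test_that("planted class differences separate: thickness and eccentricity ordering", {
  # scaled down from the 30-per-class statement to 8 per class at 320 px to
  # stay inside the suite's time budget; the planted gaps are large
  feats <- list()
  for (cls in c("osteoporotic", "traumatic", "neoplastic")) {
    feats[[cls]] <- t(vapply(1:8, function(i) {
      r <- render_slide(slide_spec(cls, image_size = c(320, 320),
                                   seed = 6000 + i))
      f <- compute_histomorphometry(r$image, 4, r$truth$masks$tissue)
      c(th = f$trabecular_thickness_um, ecc = f$nucleus_eccentricity_mean)
    }, numeric(2)))
  }
  th <- vapply(feats, function(m) mean(m[, "th"]), numeric(1))
  ecc <- vapply(feats, function(m) mean(m[, "ecc"]), numeric(1))
  expect_lt(th["osteoporotic"], th["traumatic"])
  expect_lt(th["osteoporotic"], th["neoplastic"])
  expect_equal(names(which.max(ecc)), "neoplastic")
})
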