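# Seeded generator of H&E-like vertebral bone histology with planted ground
# truth. Slides are composed in stain-concentration space (hematoxylin,
# eosin, and an optional collagen-toned third stain) and converted to RGB
# through fixed reference optical-density stain vectors, so Macenko stain
# estimation has a known answer and every morphometric quantity is
# recomputable from the emitted masks.

VCF_CLASSES <- c(osteoporotic = 0L, traumatic = 1L, neoplastic = 2L)

#' Reference H&E (+ collagen) optical-density stain vectors
#'
#' Fixed unit-norm OD vectors used both to render synthetic slides and as the
#' Macenko reference profile. Hematoxylin first (largest blue-channel OD),
#' then eosin, then a collagen-toned third vector used only by the fibrosis
#' deconvolution.
#'
#' @return 3 x 3 matrix, columns H, E, C; all entries >= 0, unit columns.
#' @export
he_reference_stains <- function() {
  v <- cbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    eosin       = c(0.070, 0.990, 0.110),
    collagen    = c(0.260, 0.680, 0.660)
  )
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

#' Specification of one synthetic slide
#'
#' Class-conditional defaults plant the histologic hallmarks of each fracture
#' etiology: osteoporotic slides get thin sparse trabeculae and fat-rich
#' marrow; traumatic slides a fracture cleft with surrounding inflammatory
#' infiltrates; neoplastic slides dense clusters of elongated (high
#' eccentricity) nuclei replacing marrow. All defaults can be overridden.
#'
#' @param fracture_class "osteoporotic", "traumatic" or "neoplastic" (or the
#'   integer codes 0/1/2).
#' @param image_size c(H, W) in pixels, at least 256 x 256.
#' @param microns_per_pixel physical scale (default 4 um/px: a 512-px slide
#'   spans a 2 x 2 mm field, matching realistic trabecular geometry).
#' @param trabecular_width_px strand width in pixels.
#' @param bone_fraction_target area fraction of tissue occupied by bone.
#' @param adiposity_fraction_target area fraction of marrow occupied by fat
#'   vacuoles.
#' @param tumor_cluster_count number of planted tumor-cell clusters.
#' @param inflammatory_cell_density_target cells per mm^2 of marrow.
#' @param collagen_fraction_target area fraction of marrow with collagen.
#' @param fracture_line logical; plant a fracture cleft.
#' @param nucleus_eccentricity_mean mean eccentricity of the dominant nucleus
#'   population.
#' @param lacunae_per_mm2 osteocyte lacunae per mm^2 of bone.
#' @param seed integer seed; identical spec + seed renders byte-identical
#'   output.
#' @return object of class `slide_spec`.
#' @export
slide_spec <- function(fracture_class = "osteoporotic",
                       image_size = c(512, 512),
                       microns_per_pixel = 4,
                       trabecular_width_px = NULL,
                       bone_fraction_target = NULL,
                       adiposity_fraction_target = NULL,
                       tumor_cluster_count = NULL,
                       inflammatory_cell_density_target = NULL,
                       collagen_fraction_target = NULL,
                       fracture_line = NULL,
                       nucleus_eccentricity_mean = NULL,
                       lacunae_per_mm2 = 80,
                       seed = 1L) {
  if (is.numeric(fracture_class)) {
    fracture_class <- names(VCF_CLASSES)[match(fracture_class, VCF_CLASSES)]
  }
  fracture_class <- match.arg(fracture_class, names(VCF_CLASSES))
  defaults <- switch(fracture_class,
    osteoporotic = list(width = 18, bone = 0.14, fat = 0.45, tumor = 0L,
                        infl = 100, coll = 0.04, cleft = FALSE, ecc = 0.35),
    traumatic    = list(width = 36, bone = 0.30, fat = 0.18, tumor = 0L,
                        infl = 800, coll = 0.10, cleft = TRUE, ecc = 0.45),
    neoplastic   = list(width = 30, bone = 0.24, fat = 0.05, tumor = 4L,
                        infl = 250, coll = 0.20, cleft = FALSE, ecc = 0.85)
  )
  spec <- structure(list(
    fracture_class = fracture_class,
    class_code = unname(VCF_CLASSES[fracture_class]),
    image_size = as.integer(image_size),
    microns_per_pixel = microns_per_pixel,
    trabecular_width_px = trabecular_width_px %||% defaults$width,
    bone_fraction_target = bone_fraction_target %||% defaults$bone,
    adiposity_fraction_target = adiposity_fraction_target %||% defaults$fat,
    tumor_cluster_count = as.integer(tumor_cluster_count %||% defaults$tumor),
    inflammatory_cell_density_target =
      inflammatory_cell_density_target %||% defaults$infl,
    collagen_fraction_target = collagen_fraction_target %||% defaults$coll,
    fracture_line = fracture_line %||% defaults$cleft,
    nucleus_eccentricity_mean = nucleus_eccentricity_mean %||% defaults$ecc,
    lacunae_per_mm2 = lacunae_per_mm2,
    seed = as.integer(seed)
  ), class = "slide_spec")
  validate_slide_spec(spec)
  spec
}

validate_slide_spec <- function(spec) {
  abort_if(any(spec$image_size < 256), "image_size must be at least 256 x 256")
  abort_if(spec$trabecular_width_px <= 0, "trabecular_width_px must be > 0")
  abort_if(spec$bone_fraction_target <= 0 || spec$bone_fraction_target >= 1,
           "bone_fraction_target must be in (0, 1)")
  abort_if(spec$adiposity_fraction_target < 0 ||
             spec$adiposity_fraction_target >= 1,
           "adiposity_fraction_target must be in [0, 1)")
  abort_if(spec$bone_fraction_target + spec$adiposity_fraction_target > 0.95,
           "infeasible targets: bone + fat fractions exceed 0.95")
  abort_if(spec$collagen_fraction_target < 0 ||
             spec$collagen_fraction_target >= 1,
           "collagen_fraction_target must be in [0, 1)")
  abort_if(spec$tumor_cluster_count < 0, "tumor_cluster_count must be >= 0")
  invisible(spec)
}

#' @export
print.slide_spec <- function(x, ...) {
  cat("<slide_spec>", x$fracture_class,
      sprintf("(%d x %d px, %.1f um/px, seed %d)\n",
              x$image_size[1], x$image_size[2], x$microns_per_pixel, x$seed))
  invisible(x)
}

# ---- internal painters ------------------------------------------------------

# Fill ellipses into a numeric matrix; nuclei is a data.frame with columns
# y, x, a, b, theta. Returns list(field, mask) where field has `value` painted.
paint_ellipses <- function(field, nuclei, value, jitter_sd = 0) {
  H <- nrow(field); W <- ncol(field)
  mask <- matrix(FALSE, H, W)
  if (nrow(nuclei) == 0) return(list(field = field, mask = mask))
  vals <- if (jitter_sd > 0) {
    pmax(0, value + rnorm(nrow(nuclei), 0, jitter_sd))
  } else rep(value, nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    a <- nuclei$a[i]; b <- nuclei$b[i]; th <- nuclei$theta[i]
    cy <- nuclei$y[i]; cx <- nuclei$x[i]
    r <- ceiling(a)
    ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    if (!length(ys) || !length(xs)) next
    dy <- outer(ys - cy, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - cx)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    sub <- field[ys, xs, drop = FALSE]
    sub[inside] <- vals[i]
    field[ys, xs] <- sub
    msub <- mask[ys, xs, drop = FALSE]
    msub[inside] <- TRUE
    mask[ys, xs] <- msub
  }
  list(field = field, mask = mask)
}

# sample nucleus geometry: n ellipses with mean semi-major a_mean and
# eccentricity centred on ecc_mean, at the given (y, x) centers
sample_nuclei <- function(y, x, a_mean, ecc_mean, ecc_sd = 0.08) {
  n <- length(y)
  a <- pmax(1.5, rnorm(n, a_mean, a_mean * 0.15))
  ecc <- clamp(rnorm(n, ecc_mean, ecc_sd), 0, 0.97)
  b <- a * sqrt(1 - ecc^2)
  data.frame(y = y, x = x, a = a, b = b, theta = runif(n, 0, pi), ecc = ecc)
}

# smooth random field in [0,1] (blurred white noise), used for collagen blobs
smooth_noise_field <- function(H, W, sigma = 12) {
  f <- blur_gaussian(matrix(runif(H * W), H, W), sigma)
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

# trabecular lattice mask: two orthogonal families of sinusoidally displaced
# strands of width w, spacing s, clipped to `tissue`. With a handful of
# strands per direction, pixelation and edge clipping push the area fraction
# off its continuum value, so the width is bisected against the target
# fraction (the planted thickness is the fitted width).
trabecular_lattice <- function(H, W, w, s, tissue, wobble = TRUE,
                               target_fraction = NULL) {
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  amp <- if (wobble) min(s / 6, 8) else 0
  lam <- H / 2
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  off1 <- runif(1, 0, s); off2 <- runif(1, 0, s)
  base_x <- (x + amp * sin(2 * pi * y / lam + ph1) - off1) %% s
  base_y <- (y + amp * sin(2 * pi * x / lam + ph2) - off2) %% s
  build <- function(wi) (base_x < wi | base_y < wi) & tissue
  if (is.null(target_fraction)) {
    return(list(mask = build(w), width = w))
  }
  nt <- sum(tissue)
  lo <- w * 0.4; hi <- min(w * 2.5, s * 0.95)
  wi <- w
  for (i in 1:12) {
    f <- sum(build(wi)) / nt
    if (abs(f - target_fraction) < 0.004) break
    if (f > target_fraction) hi <- wi else lo <- wi
    wi <- (lo + hi) / 2
  }
  list(mask = build(wi), width = wi)
}

#' Render a synthetic slide
#'
#' Deterministically renders the H&E-like image described by a [slide_spec()]
#' together with its ground truth: pixel masks (tissue, bone, marrow, fat,
#' collagen, nuclei, lacunae, planted discriminative regions), the nucleus
#' table, and the planted scalar quantities measured back from the rendered
#' masks.
#'
#' @param spec a [slide_spec()].
#' @return list with elements `image` (H x W x 3 array in \[0,1\], 8-bit
#'   quantized), `truth` (ground-truth list) and `spec`.
#' @export
render_slide <- function(spec) {
  validate_slide_spec(spec)
  with_seed(spec$seed, render_slide_impl(spec))
}

render_slide_impl <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  mpp <- spec$microns_per_pixel
  px_per_mm2 <- (1000 / mpp)^2

  # tissue occupies the canvas minus a white border
  margin <- round(0.04 * min(H, W))
  tissue <- matrix(FALSE, H, W)
  tissue[(margin + 1):(H - margin), (margin + 1):(W - margin)] <- TRUE

  # --- trabecular bone ---
  w <- spec$trabecular_width_px
  f <- spec$bone_fraction_target
  s <- w / (1 - sqrt(1 - f))          # 1 - (1 - w/s)^2 = f for the lattice
  lat <- trabecular_lattice(H, W, w, s, tissue, target_fraction = f)
  bone <- lat$mask
  w <- lat$width                      # planted thickness = fitted width

  # fracture cleft (traumatic): jagged band wiping out bone and marrow
  cleft <- matrix(FALSE, H, W)
  if (isTRUE(spec$fracture_line)) {
    path <- cumsum(rnorm(W, 0, 3))
    path <- path - mean(path) + H / 2
    path <- as.numeric(blur_gaussian(matrix(path, 1), 8))
    half <- pmax(6, rnorm(W, 12, 2))
    y <- matrix(seq_len(H), H, W)
    ctr <- matrix(path, H, W, byrow = TRUE)
    hw <- matrix(half, H, W, byrow = TRUE)
    cleft <- abs(y - ctr) <= hw & tissue
    bone <- bone & !cleft
  }

  # osteoporotic fragmentation: punch small gaps into strands
  if (spec$fracture_class == "osteoporotic") {
    ngap <- rpois_det(25)
    if (ngap > 0) {
      gy <- runif(ngap, 1, H); gx <- runif(ngap, 1, W)
      gaps <- paint_ellipses(matrix(0, H, W),
                             data.frame(y = gy, x = gx,
                                        a = runif(ngap, w, 2 * w),
                                        b = runif(ngap, w, 2 * w),
                                        theta = 0),
                             1)$mask
      bone <- bone & !gaps
    }
  }

  marrow <- tissue & !bone & !cleft

  # --- osteocyte lacunae: bright holes inside bone ---
  bone_px <- which(bone)
  bone_mm2 <- length(bone_px) / px_per_mm2
  n_lac <- round(spec$lacunae_per_mm2 * bone_mm2)
  lac_mask <- matrix(FALSE, H, W)
  lacunae <- data.frame()
  if (n_lac > 0 && length(bone_px) > 0) {
    # keep lacunae off strand edges so they stay inside bone
    core <- erode_mask(bone, 3)
    core_px <- which(core)
    n_lac <- min(n_lac, length(core_px))
    if (n_lac > 0) {
      idx <- sample(core_px, n_lac)
      lacunae <- sample_nuclei((idx - 1) %% H + 1, (idx - 1) %/% H + 1,
                               a_mean = 2.6, ecc_mean = 0.55)
      lac_mask <- paint_ellipses(matrix(0, H, W), lacunae, 1)$mask & bone
    }
  }

  # --- marrow fat vacuoles ---
  marrow_px <- which(marrow)
  fat <- matrix(FALSE, H, W)
  target_fat <- spec$adiposity_fraction_target
  if (target_fat > 0 && length(marrow_px) > 0) {
    need <- target_fat * length(marrow_px)
    got <- 0; tries <- 0
    while (got < need && tries < 4000) {
      tries <- tries + 1
      ctr <- sample(marrow_px, 1)
      cy <- (ctr - 1) %% H + 1; cx <- (ctr - 1) %/% H + 1
      r <- clamp(rnorm(1, 11, 2.5), 5, 18)
      ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
      xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
      dy <- outer(ys - cy, rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - cx)
      disc <- (dy^2 + dx^2) <= r^2
      sub <- marrow[ys, xs, drop = FALSE] & disc & !fat[ys, xs, drop = FALSE]
      add <- sum(sub)
      if (add < 0.5 * sum(disc)) next   # mostly overlaps bone/fat: skip
      fsub <- fat[ys, xs, drop = FALSE]
      fsub[sub] <- TRUE
      fat[ys, xs] <- fsub
      got <- got + add
    }
  }

  # --- collagen / fibrosis patches (exact-fraction by field quantile) ---
  collagen <- matrix(FALSE, H, W)
  target_coll <- spec$collagen_fraction_target
  coll_zone <- marrow & !fat
  if (target_coll > 0 && any(coll_zone)) {
    fld <- smooth_noise_field(H, W, sigma = 14)
    # fraction is defined over marrow; restrict support to marrow minus fat
    nm <- sum(marrow)
    k <- min(round(target_coll * nm), sum(coll_zone))
    if (k > 0) {
      thr <- sort(fld[coll_zone], decreasing = TRUE)[k]
      collagen <- coll_zone & fld >= thr
    }
  }

  # --- nuclei ---
  nuclei_all <- list()
  # inflammatory / stromal cells in marrow
  marrow_mm2 <- sum(marrow) / px_per_mm2
  n_inf <- round(spec$inflammatory_cell_density_target * marrow_mm2)
  cell_zone_px <- which(marrow & !fat)
  if (n_inf > 0 && length(cell_zone_px) > 0) {
    if (isTRUE(spec$fracture_line)) {
      # inflammatory infiltrate concentrates around the cleft
      near <- dilate_mask(cleft, 30) & marrow & !fat
      near_px <- which(near)
      n_near <- round(0.6 * n_inf)
      idx <- c(
        if (length(near_px)) sample(near_px, min(n_near, length(near_px)),
                                    replace = TRUE),
        sample(cell_zone_px, n_inf - min(n_near, length(near_px)),
               replace = TRUE)
      )
    } else {
      idx <- sample(cell_zone_px, n_inf, replace = TRUE)
    }
    infl <- sample_nuclei((idx - 1) %% H + 1, (idx - 1) %/% H + 1,
                          a_mean = 2.8, ecc_mean = 0.30)
    infl$type <- "inflammatory"
    nuclei_all$infl <- infl
  }
  # tumor clusters
  tumor_mask <- matrix(FALSE, H, W)
  if (spec$tumor_cluster_count > 0) {
    zone <- erode_mask(tissue, 40)
    zone_px <- which(zone & !cleft)
    for (ci in seq_len(spec$tumor_cluster_count)) {
      ok <- FALSE
      for (attempt in 1:50) {
        ctr <- sample(zone_px, 1)
        cy <- (ctr - 1) %% H + 1; cx <- (ctr - 1) %/% H + 1
        r <- runif(1, 30, 42)
        ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
        xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
        dy <- outer(ys - cy, rep(1, length(xs)))
        dx <- outer(rep(1, length(ys)), xs - cx)
        disc <- (dy^2 + dx^2) <= r^2
        # require clusters to be disjoint so component counts are exact
        if (any(tumor_mask[ys, xs][disc])) next
        tsub <- tumor_mask[ys, xs, drop = FALSE]
        tsub[disc] <- TRUE
        tumor_mask[ys, xs] <- tsub
        nnuc <- round(0.045 * sum(disc))
        pts <- which(disc)
        pick <- sample(pts, nnuc, replace = TRUE)
        ny <- ys[(pick - 1) %% length(ys) + 1]
        nx <- xs[(pick - 1) %/% length(ys) + 1]
        tum <- sample_nuclei(ny, nx, a_mean = 4.5,
                             ecc_mean = max(0.75, spec$nucleus_eccentricity_mean),
                             ecc_sd = 0.05)
        tum$type <- "tumor"
        nuclei_all[[paste0("tumor", ci)]] <- tum
        ok <- TRUE
        break
      }
      if (!ok) warning("could not place all tumor clusters disjointly")
    }
  }
  # sparse resident stromal nuclei with the class eccentricity signature
  n_stroma <- round(120 * marrow_mm2)
  if (n_stroma > 0 && length(cell_zone_px) > 0) {
    idx <- sample(cell_zone_px, n_stroma, replace = TRUE)
    stro <- sample_nuclei((idx - 1) %% H + 1, (idx - 1) %/% H + 1,
                          a_mean = 3.6,
                          ecc_mean = spec$nucleus_eccentricity_mean)
    stro$type <- "stromal"
    nuclei_all$stroma <- stro
  }
  nuclei <- if (length(nuclei_all)) do.call(rbind, nuclei_all) else
    data.frame(y = numeric(), x = numeric(), a = numeric(), b = numeric(),
               theta = numeric(), ecc = numeric(), type = character())

  # --- compose stain concentrations ---
  ch <- matrix(0, H, W); ce <- matrix(0, H, W); cc <- matrix(0, H, W)
  ce[marrow] <- 0.22; ch[marrow] <- 0.05
  ce[bone] <- 0.85; ch[bone] <- 0.07
  ce[lac_mask] <- 0.12
  ce[collagen] <- 0.10; cc[collagen] <- 0.55
  ce[fat] <- 0.015; ch[fat] <- 0.005; cc[fat] <- 0
  if (any(cleft)) { ce[cleft] <- 0.05; ch[cleft] <- 0.015 }
  # multiplicative texture noise
  ce <- ce * exp(rnorm(H * W, 0, 0.05))
  ch <- ch * exp(rnorm(H * W, 0, 0.05))
  painted <- paint_ellipses(ch, nuclei, 0.85, jitter_sd = 0.06)
  ch <- painted$field
  nuc_mask <- painted$mask
  ce[nuc_mask] <- pmin(ce[nuc_mask], 0.15)   # nuclei displace cytoplasm/matrix

  V <- he_reference_stains()
  od <- rbind(as.numeric(ch), as.numeric(ce), as.numeric(cc))
  rgb_od <- V %*% od                                    # 3 x (H*W)
  i8 <- round(clamp(255 * 10^(-rgb_od) - 1, 0, 255))    # OD convention: I0=255
  img <- array(0, c(H, W, 3))
  img[, , 1] <- matrix(i8[1, ] / 255, H, W)
  img[, , 2] <- matrix(i8[2, ] / 255, H, W)
  img[, , 3] <- matrix(i8[3, ] / 255, H, W)
  # background border stays paper-white
  for (chn in 1:3) {
    plane <- img[, , chn]
    plane[!tissue] <- 254 / 255
    img[, , chn] <- plane
  }

  disc <- tumor_mask | cleft
  truth <- list(
    fracture_class = spec$fracture_class,
    class_code = spec$class_code,
    microns_per_pixel = mpp,
    masks = list(tissue = tissue, bone = bone, marrow = marrow, fat = fat,
                 collagen = collagen, lacunae = lac_mask, nuclei = nuc_mask,
                 discriminative = disc),
    nuclei = nuclei,
    bone_fraction = sum(bone) / sum(tissue),
    trabecular_thickness_px = w,
    trabecular_spacing_px = s,
    adiposity_fraction = sum(fat) / max(1, sum(marrow)),
    collagen_fraction = sum(collagen) / max(1, sum(marrow)),
    lacunae_count = nrow(lacunae),
    inflammatory_count = n_inf,
    tumor_cluster_count = spec$tumor_cluster_count,
    nucleus_eccentricity_mean = if (nrow(nuclei)) mean(nuclei$ecc) else NA_real_
  )
  list(image = img, truth = truth, spec = spec)
}

# deterministic Poisson-ish count from the active RNG stream
rpois_det <- function(lambda) as.integer(round(lambda * exp(rnorm(1, 0, 0.2))))

#' Render a single small tile for MIL experiments
#'
#' Desk-scale 64 x 64 (default) tiles carrying one tile phenotype each:
#' `"marrow"` (shared background), `"osteo"` (thin fragmented strands plus
#' fat), `"trauma"` (fracture cleft band with dense small nuclei) and
#' `"tumor"` (a dense cluster of elongated nuclei; its pixel mask is the
#' planted discriminative region).
#'
#' @param type tile phenotype.
#' @param px tile side in pixels.
#' @param seed integer seed.
#' @return list(image, mask) where mask marks planted discriminative pixels
#'   (non-empty only for "tumor" and "trauma" tiles).
#' @export
render_tile <- function(type = c("marrow", "osteo", "trauma", "tumor"),
                        px = 64, seed = 1L) {
  type <- match.arg(type)
  with_seed(seed, {
    H <- px; W <- px
    tissue <- matrix(TRUE, H, W)
    ch <- matrix(0.05, H, W); ce <- matrix(0.22, H, W); cc <- matrix(0, H, W)
    mask <- matrix(FALSE, H, W)
    if (type == "osteo") {
      bone <- trabecular_lattice(H, W, w = 5, s = 28, tissue)$mask
      ce[bone] <- 0.85; ch[bone] <- 0.07
      # a few fat vacuoles
      for (i in 1:6) {
        cy <- runif(1, 6, H - 6); cx <- runif(1, 6, W - 6)
        r <- runif(1, 4, 7)
        dy <- outer(seq_len(H) - cy, rep(1, W))
        dx <- outer(rep(1, H), seq_len(W) - cx)
        disc <- (dy^2 + dx^2) <= r^2 & !bone
        ce[disc] <- 0.015; ch[disc] <- 0.005
      }
    } else if (type == "trauma") {
      path <- cumsum(rnorm(W, 0, 1.2))
      path <- path - mean(path) + H / 2
      y <- matrix(seq_len(H), H, W)
      ctr <- matrix(path, H, W, byrow = TRUE)
      cleft <- abs(y - ctr) <= 5
      ce[cleft] <- 0.05; ch[cleft] <- 0.015
      near <- dilate_mask(cleft, 8) & !cleft
      pts <- which(near)
      idx <- sample(pts, min(60, length(pts)))
      nuc <- sample_nuclei((idx - 1) %% H + 1, (idx - 1) %/% H + 1,
                           a_mean = 2.2, ecc_mean = 0.3)
      ch <- paint_ellipses(ch, nuc, 0.85, jitter_sd = 0.05)$field
      mask <- cleft
    } else if (type == "tumor") {
      cy <- runif(1, H * 0.3, H * 0.7); cx <- runif(1, W * 0.3, W * 0.7)
      r <- runif(1, 0.22, 0.30) * px
      dy <- outer(seq_len(H) - cy, rep(1, W))
      dx <- outer(rep(1, H), seq_len(W) - cx)
      disc <- (dy^2 + dx^2) <= r^2
      pts <- which(disc)
      idx <- sample(pts, round(0.08 * length(pts)), replace = TRUE)
      nuc <- sample_nuclei((idx - 1) %% H + 1, (idx - 1) %/% H + 1,
                           a_mean = 3.8, ecc_mean = 0.85, ecc_sd = 0.04)
      ch <- paint_ellipses(ch, nuc, 0.9, jitter_sd = 0.04)$field
      mask <- disc
    } else {
      # plain marrow: sparse small nuclei
      idx <- sample(H * W, 10)
      nuc <- sample_nuclei((idx - 1) %% H + 1, (idx - 1) %/% H + 1,
                           a_mean = 2.5, ecc_mean = 0.3)
      ch <- paint_ellipses(ch, nuc, 0.8, jitter_sd = 0.05)$field
    }
    ce <- ce * exp(rnorm(H * W, 0, 0.04))
    ch <- ch * exp(rnorm(H * W, 0, 0.04))
    V <- he_reference_stains()
    od <- V %*% rbind(as.numeric(ch), as.numeric(ce), as.numeric(cc))
    i8 <- round(clamp(255 * 10^(-od) - 1, 0, 255))
    img <- array(0, c(H, W, 3))
    for (chn in 1:3) img[, , chn] <- matrix(i8[chn, ] / 255, H, W)
    list(image = img, mask = mask, type = type)
  })
}
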