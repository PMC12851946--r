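# Slide preprocessing: tissue segmentation (Otsu), Macenko stain estimation
# and normalization, overlapping tiling with blank/artifact QC.
#
# Conventions (used everywhere): optical density OD = -log10((I8 + 1) / 255)
# with I8 the 8-bit intensity (the +1 offset avoids log 0); tile coordinates
# are 0-based (row, col) top-left positions over half-open intervals
# [row, row + T) x [col, col + T).

#' Optical density conversions
#' @param img H x W x 3 RGB array in \[0,1\].
#' @return `od_from_rgb`: H x W x 3 array of optical densities.
#' @export
od_from_rgb <- function(img) {
  i8 <- round(clamp(img, 0, 1) * 255)
  -log10((i8 + 1) / 255)
}

#' @rdname od_from_rgb
#' @param od optical density array.
#' @export
rgb_from_od <- function(od) {
  clamp((255 * 10^(-od) - 1) / 255, 0, 1)
}

#' Stain profile (Macenko)
#'
#' @param stain_matrix 3 x 2 matrix of unit-norm, non-negative OD stain
#'   vectors, hematoxylin first.
#' @param max_concentrations length-2 vector of the robust (99th percentile)
#'   per-stain concentrations.
#' @return object of class `stain_profile`.
#' @export
stain_profile <- function(stain_matrix, max_concentrations) {
  stopifnot(is.matrix(stain_matrix), dim(stain_matrix) == c(3, 2))
  abort_if(any(stain_matrix < -1e-8), "stain vectors must be non-negative")
  nrm <- sqrt(colSums(stain_matrix^2))
  abort_if(any(abs(nrm - 1) > 1e-6), "stain vectors must be unit norm")
  structure(list(stain_matrix = stain_matrix,
                 max_concentrations = as.numeric(max_concentrations)),
            class = "stain_profile")
}

#' Packaged reference stain profile
#'
#' The fixed H&E reference used by the synthetic renderer, so Macenko
#' estimation has a known ground truth.
#' @return a [stain_profile()].
#' @export
reference_stain_profile <- function() {
  v <- he_reference_stains()[, 1:2]
  stain_profile(v, c(0.9, 0.9))
}

#' Preprocessing configuration
#'
#' @param tile_size_px tile side (default 512).
#' @param overlap_fraction fractional overlap between neighbouring tiles
#'   (default 0.5).
#' @param blank_fraction_max tiles with blank fraction above this are dropped
#'   (default 0.5, i.e. ">50% blank").
#' @param od_background_threshold OD norm below which a pixel is background
#'   for stain estimation (default 0.15).
#' @param macenko_alpha robust angle percentile (default 1; extremes at the
#'   1st/99th percentiles).
#' @param blur_variance_min variance-of-Laplacian below this flags blur.
#' @param reference_stain reference [stain_profile()].
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(tile_size_px = 512L,
                              overlap_fraction = 0.5,
                              blank_fraction_max = 0.5,
                              od_background_threshold = 0.15,
                              macenko_alpha = 1,
                              blur_variance_min = 1e-4,
                              reference_stain = reference_stain_profile()) {
  abort_if(tile_size_px < 64, "tile_size_px must be >= 64")
  abort_if(overlap_fraction <= 0 || overlap_fraction >= 1,
           "overlap_fraction must be in (0, 1)")
  structure(list(tile_size_px = as.integer(tile_size_px),
                 overlap_fraction = overlap_fraction,
                 blank_fraction_max = blank_fraction_max,
                 od_background_threshold = od_background_threshold,
                 macenko_alpha = macenko_alpha,
                 blur_variance_min = blur_variance_min,
                 reference_stain = reference_stain),
            class = "preprocess_config")
}

#' Segment tissue from background
#'
#' Otsu thresholding on a tissue-sensitivity channel
#' `(1 - saturation-weighted complement of intensity)` chosen so that faintly
#' eosinophilic tissue is kept, followed by morphological opening and closing.
#'
#' @param image H x W x 3 RGB array in \[0,1\].
#' @param clean_radius disc radius for morphological cleanup (px).
#' @return logical mask, TRUE = tissue.
#' @export
segment_tissue <- function(image, clean_radius = 2) {
  stopifnot(length(dim(image)) == 3)
  gray <- rgb_to_gray(image)
  sat <- rgb_saturation(image)
  # background is bright AND unsaturated; faint eosin tissue is bright but
  # saturated, so score on the saturation-weighted intensity complement
  score <- clamp(1 - gray * (1 - sat), 0, 1)
  thr <- suppressWarnings(otsu_threshold(score))
  if (is.na(thr)) {
    warning("no tissue found (uniform image)")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  mask <- score > thr
  # guard against inverted splits on near-empty slides
  if (mean(score[mask]) < mean(score[!mask])) mask <- !mask
  mask <- open_close_mask(mask, clean_radius)
  # fat vacuoles are enclosed white holes, not background
  fill_small_holes(mask, max_hole = round(0.01 * length(mask)))
}

#' Estimate stain vectors by the Macenko method
#'
#' Converts to optical density, keeps pixels with OD norm above the
#' background threshold, projects them onto the plane of the top two
#' singular directions and takes the extreme-angle directions at the
#' (alpha, 100 - alpha) percentiles as the stain vectors. Hematoxylin (the
#' larger blue-channel OD vector) is ordered first. The 99th-percentile
#' per-stain concentrations are stored for normalization.
#'
#' @param image RGB array; pass tissue-only pixels for best results.
#' @param mask optional logical matrix restricting the pixels used.
#' @param od_threshold background OD norm cutoff.
#' @param alpha robust percentile (default 1).
#' @return a [stain_profile()].
#' @export
estimate_stains <- function(image, mask = NULL, od_threshold = 0.15,
                            alpha = 1) {
  od <- od_from_rgb(image)
  odm <- cbind(as.numeric(od[, , 1]), as.numeric(od[, , 2]),
               as.numeric(od[, , 3]))
  if (!is.null(mask)) odm <- odm[as.logical(mask), , drop = FALSE]
  keep <- sqrt(rowSums(odm^2)) > od_threshold
  abort_if(sum(keep) < 100,
           "too few tissue pixels above the OD threshold; segment tissue first")
  x <- odm[keep, , drop = FALSE]
  sv <- svd(x, nu = 0, nv = 3)
  abort_if(sv$d[2] < 0.05 * sv$d[1],
           "rank-deficient OD cloud: image appears to contain a single stain")
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  # orient the plane so projections on e1 are positive
  if (mean(x %*% e1) < 0) e1 <- -e1
  p1 <- x %*% e1; p2 <- x %*% e2
  phi <- atan2(p2, p1)
  lo <- quantile(phi, alpha / 100); hi <- quantile(phi, 1 - alpha / 100)
  v1 <- cos(lo) * e1 + sin(lo) * e2
  v2 <- cos(hi) * e1 + sin(hi) * e2
  fixv <- function(v) {
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    v / sqrt(sum(v^2))
  }
  v1 <- fixv(v1); v2 <- fixv(v2)
  # hematoxylin has the larger blue-channel OD
  V <- if (v1[3] >= v2[3]) cbind(v1, v2) else cbind(v2, v1)
  colnames(V) <- c("hematoxylin", "eosin")
  conc <- nnls_two(V, t(odm[keep, , drop = FALSE]))
  stain_profile(V, c(quantile(conc[1, ], 0.99), quantile(conc[2, ], 0.99)))
}

# closed-form non-negative least squares for a 3 x 2 design, vectorized over
# pixel columns of od (3 x N). Returns 2 x N concentrations.
nnls_two <- function(V, od) {
  G <- crossprod(V)            # 2 x 2
  b <- crossprod(V, od)        # 2 x N
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  c1 <- (G[2, 2] * b[1, ] - G[1, 2] * b[2, ]) / det
  c2 <- (G[1, 1] * b[2, ] - G[1, 2] * b[1, ]) / det
  neg1 <- c1 < 0; neg2 <- c2 < 0
  # project onto the admissible axes when unconstrained solution is negative
  c1[neg1] <- 0
  c2[neg1] <- pmax(0, b[2, neg1] / G[2, 2])
  c2[neg2 & !neg1] <- 0
  c1[neg2 & !neg1] <- pmax(0, b[1, neg2 & !neg1] / G[1, 1])
  rbind(c1, c2)
}

#' Normalize an image to a reference stain profile
#'
#' Unmixes per-pixel stain concentrations against the source profile
#' (non-negative least squares), rescales each stain by the ratio of
#' reference to source 99th-percentile concentrations, and recomposes with
#' the reference stain matrix.
#'
#' @param image RGB array in \[0,1\].
#' @param source [stain_profile()] of the image (estimate with
#'   [estimate_stains()]).
#' @param reference target [stain_profile()].
#' @return normalized RGB array, clipped to \[0,1\].
#' @export
normalize_stains <- function(image, source, reference) {
  stopifnot(inherits(source, "stain_profile"),
            inherits(reference, "stain_profile"))
  H <- dim(image)[1]; W <- dim(image)[2]
  od <- od_from_rgb(image)
  odm <- rbind(as.numeric(od[, , 1]), as.numeric(od[, , 2]),
               as.numeric(od[, , 3]))
  conc <- nnls_two(source$stain_matrix, odm)
  scale <- reference$max_concentrations /
    pmax(source$max_concentrations, 1e-8)
  conc <- conc * scale
  od_new <- reference$stain_matrix %*% conc
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) out[, , ch] <- matrix(rgb_from_od(od_new[ch, ]), H, W)
  out
}

#' Artifact QC flags for one tile
#'
#' Flags: `blur` (variance of the Laplacian below threshold), `fold` (dark,
#' highly saturated area above 5% of the tile), `blank` (blank fraction above
#' the configured maximum). Any raised flag excludes the tile.
#'
#' @param tile RGB array.
#' @param config a [preprocess_config()].
#' @return named logical vector (blur, fold, blank).
#' @export
detect_artifacts <- function(tile, config = preprocess_config()) {
  gray <- rgb_to_gray(tile)
  sat <- rgb_saturation(tile)
  blank_frac <- mean(gray > 0.92 & sat < 0.12)
  # folds are double-thickness tissue: much darker than even dense nuclei
  fold_frac <- mean(gray < 0.12 & sat > 0.4)
  c(blur = laplacian_variance(gray) < config$blur_variance_min,
    fold = fold_frac > 0.05,
    blank = blank_frac > config$blank_fraction_max)
}

#' Tile a slide into an overlapping grid of QC-passing tiles
#'
#' The grid covers the bounding box of the tissue mask with stride
#' `tile_size * (1 - overlap_fraction)`; the final row/column is shifted
#' inward so tiles always lie fully inside the image (no padding). A tile's
#' blank fraction is `1 - tissue pixels / tile area`; tiles blanked beyond
#' `blank_fraction_max` or failing artifact checks are dropped. All QC
#' decisions are returned in the log.
#'
#' @param image RGB array.
#' @param mask logical tissue mask of the same height/width.
#' @param config a [preprocess_config()].
#' @param slide_id identifier stored in the bag.
#' @param artifact_checks run [detect_artifacts()] per tile (default TRUE).
#' @return object of class `tile_bag`: list(slide_id, tiles, coords,
#'   qc_log); `coords` is a data.frame of 0-based (row, col).
#' @export
tile_slide <- function(image, mask, config = preprocess_config(),
                       slide_id = "slide", artifact_checks = TRUE) {
  stopifnot(all(dim(mask) == dim(image)[1:2]))
  T_ <- config$tile_size_px
  S <- max(1L, as.integer(round(T_ * (1 - config$overlap_fraction))))
  if (!any(mask)) {
    warning("empty tissue mask: returning empty bag")
    return(structure(list(slide_id = slide_id, tiles = list(),
                          coords = data.frame(row = integer(), col = integer()),
                          qc_log = data.frame()), class = "tile_bag"))
  }
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  H <- nrow(mask); W <- ncol(mask)
  grid_axis <- function(lo, hi, limit) {
    # 0-based start positions; inward-shifted final tile
    span <- hi - lo + 1
    start0 <- lo - 1L
    if (span <= T_) return(min(start0, limit - T_))
    pos <- seq(start0, start0 + span - T_, by = S)
    last <- start0 + span - T_
    if (tail(pos, 1) < last) pos <- c(pos, last)
    pmin(pos, limit - T_)
  }
  rows <- unique(grid_axis(rr[1], rr[2], H))
  cols <- unique(grid_axis(cc[1], cc[2], W))
  rows <- rows[rows >= 0]; cols <- cols[cols >= 0]
  if (!length(rows) || !length(cols)) {
    warning("image smaller than tile size: returning empty bag")
    return(structure(list(slide_id = slide_id, tiles = list(),
                          coords = data.frame(row = integer(), col = integer()),
                          qc_log = data.frame()), class = "tile_bag"))
  }
  tiles <- list(); coords <- list(); log <- list()
  k <- 0
  for (r0 in rows) {
    for (c0 in cols) {
      sub_mask <- mask[(r0 + 1):(r0 + T_), (c0 + 1):(c0 + T_)]
      blank <- 1 - mean(sub_mask)
      tile <- image[(r0 + 1):(r0 + T_), (c0 + 1):(c0 + T_), , drop = FALSE]
      flags <- c(blur = FALSE, fold = FALSE, blank = FALSE)
      if (blank <= config$blank_fraction_max && artifact_checks) {
        flags <- detect_artifacts(tile, config)
      }
      keep <- blank <= config$blank_fraction_max && !any(flags)
      log[[length(log) + 1]] <- data.frame(
        slide_id = slide_id, row = r0, col = c0, blank_fraction = blank,
        blur = flags[["blur"]], fold = flags[["fold"]],
        blank_flag = flags[["blank"]], kept = keep)
      if (keep) {
        k <- k + 1
        tiles[[k]] <- tile
        coords[[k]] <- c(row = r0, col = c0)
      }
    }
  }
  structure(list(
    slide_id = slide_id,
    tiles = tiles,
    coords = if (k) as.data.frame(do.call(rbind, coords)) else
      data.frame(row = integer(), col = integer()),
    qc_log = do.call(rbind, log)
  ), class = "tile_bag")
}

#' @export
print.tile_bag <- function(x, ...) {
  cat(sprintf("<tile_bag> %s: %d QC-passing tiles (%d considered)\n",
              x$slide_id, length(x$tiles),
              if (is.null(x$qc_log)) 0L else nrow(x$qc_log)))
  invisible(x)
}

#' Full preprocessing of one slide
#'
#' Runs the five-step workflow: tissue segmentation, stain estimation,
#' Macenko normalization to the reference profile, tiling, artifact QC.
#'
#' @param image RGB array.
#' @param config a [preprocess_config()].
#' @param slide_id identifier.
#' @return list(bag, mask, normalized, stains).
#' @export
preprocess_slide <- function(image, config = preprocess_config(),
                             slide_id = "slide") {
  mask <- segment_tissue(image)
  stains <- tryCatch(
    estimate_stains(image, mask,
                    od_threshold = config$od_background_threshold,
                    alpha = config$macenko_alpha),
    error = function(e) config$reference_stain)
  norm <- normalize_stains(image, stains, config$reference_stain)
  bag <- tile_slide(norm, mask, config, slide_id = slide_id)
  list(bag = bag, mask = mask, normalized = norm, stains = stains)
}
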