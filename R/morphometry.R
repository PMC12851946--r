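# Handcrafted bone histomorphometry: trabecular architecture, marrow
# adiposity, collagen/fibrosis, nuclear morphometry. All operate on
# stain-normalized RGB arrays plus binary masks; physical scale enters only
# through microns_per_pixel.

HISTO_FEATURES <- c(
  "trabecular_bone_fraction", "trabecular_thickness_um",
  "trabecular_separation_um", "osteocyte_density_per_mm2",
  "marrow_adiposity_fraction", "collagen_density_fraction",
  "inflammatory_cell_density_per_mm2", "nucleus_eccentricity_mean",
  "trabecular_disruption_score", "marrow_fibrosis_score",
  "microns_per_pixel")

# 2-stain concentration maps (H, E) via closed-form NNLS unmixing
stain_concentrations <- function(image, stains = reference_stain_profile()) {
  od <- od_from_rgb(image)
  odm <- rbind(as.numeric(od[, , 1]), as.numeric(od[, , 2]),
               as.numeric(od[, , 3]))
  conc <- nnls_two(stains$stain_matrix, odm)
  H <- dim(image)[1]; W <- dim(image)[2]
  list(hematoxylin = matrix(conc[1, ], H, W),
       eosin = matrix(conc[2, ], H, W))
}

# fill holes in a mask whose area is below max_hole (e.g. osteocyte lacunae)
fill_small_holes <- function(mask, max_hole = 120) {
  inv <- !mask
  lab <- label_components(inv, 4)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  fill_ids <- which(sizes <= max_hole & !(seq_along(sizes) %in% border))
  mask | matrix(lab %in% fill_ids, nrow(mask), ncol(mask))
}

#' Segment trabecular bone
#'
#' Thresholds the eosin concentration channel (Otsu within tissue), removes
#' speckle components and fills osteocyte-lacuna-sized holes. The complement
#' within tissue is the marrow mask.
#'
#' @param image stain-normalized RGB array.
#' @param tissue logical tissue mask (default: [segment_tissue()]).
#' @param min_size smallest bone component kept (px).
#' @return list(bone, marrow) logical masks.
#' @export
segment_bone <- function(image, tissue = NULL, min_size = 60) {
  if (is.null(tissue)) tissue <- segment_tissue(image)
  if (!any(tissue)) return(list(bone = tissue, marrow = tissue))
  conc <- stain_concentrations(image)
  e <- conc$eosin
  thr <- suppressWarnings(
    otsu_threshold(clamp(matrix(e / max(e), nrow(e), ncol(e)), 0, 1)))
  if (is.na(thr)) {
    # uniform eosin: fall back to the absolute concentration midpoint
    # between marrow-level (~0.2) and bone-level (~0.85) staining
    bone <- e > 0.5 & tissue
  } else {
    bone <- e / max(e) > thr & tissue
  }
  lab <- label_components(bone, 8)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    bone <- bone & matrix(lab %in% which(sizes >= min_size),
                          nrow(bone), ncol(bone))
  }
  bone <- fill_small_holes(bone)
  list(bone = bone, marrow = tissue & !bone)
}

#' Trabecular metrics from a bone mask
#'
#' Thickness is twice the mean Euclidean distance-transform value sampled on
#' the bone skeleton (the standard maximal-inscribed-disc surrogate);
#' separation is the same statistic on the marrow between trabeculae. The
#' disruption score counts skeleton endpoints plus (components - 1) per mm^2
#' of bone: fragmented, free-ended trabeculae score high.
#'
#' @param bone logical bone mask.
#' @param microns_per_pixel physical scale.
#' @param tissue logical tissue mask (default: whole frame) used for the
#'   bone fraction denominator and the separation domain.
#' @return list(bone_fraction, thickness_um, separation_um,
#'   disruption_score, n_components, n_endpoints).
#' @export
trabecular_metrics <- function(bone, microns_per_pixel = 4, tissue = NULL) {
  if (is.null(tissue)) tissue <- matrix(TRUE, nrow(bone), ncol(bone))
  if (!any(bone)) {
    return(list(bone_fraction = 0, thickness_um = NA_real_,
                separation_um = NA_real_, disruption_score = NA_real_,
                n_components = 0L, n_endpoints = 0L))
  }
  mpp <- microns_per_pixel
  px_per_mm2 <- (1000 / mpp)^2
  skel <- skeletonize(bone)
  edt <- distance_transform(bone)
  thickness <- 2 * mean(edt[skel]) * mpp
  marrow <- tissue & !bone
  separation <- if (any(marrow)) {
    skel_m <- skeletonize(marrow)
    edt_m <- distance_transform(marrow)
    if (any(skel_m)) 2 * mean(edt_m[skel_m]) * mpp else NA_real_
  } else NA_real_
  n_comp <- max(label_components(bone, 8))
  n_end <- count_skeleton_endpoints(skel)
  bone_mm2 <- sum(bone) / px_per_mm2
  list(bone_fraction = sum(bone) / sum(tissue),
       thickness_um = thickness,
       separation_um = separation,
       disruption_score = (n_end + n_comp - 1) / bone_mm2,
       n_components = n_comp, n_endpoints = n_end)
}

# endpoints: skeleton pixels with exactly one 8-neighbour on the skeleton
count_skeleton_endpoints <- function(skel) {
  H <- nrow(skel); W <- ncol(skel)
  s <- matrix(0, H + 2, W + 2)
  s[2:(H + 1), 2:(W + 1)] <- skel
  nb <- s[1:H, 1:W] + s[1:H, 2:(W + 1)] + s[1:H, 3:(W + 2)] +
        s[2:(H + 1), 1:W] + s[2:(H + 1), 3:(W + 2)] +
        s[3:(H + 2), 1:W] + s[3:(H + 2), 2:(W + 1)] + s[3:(H + 2), 3:(W + 2)]
  sum(skel & nb == 1)
}

#' Marrow adiposity fraction
#'
#' Adipocyte vacuoles are near-white, low-saturation regions inside marrow,
#' filtered to roughly circular components (area over maximal-inscribed-disc
#' area at least `circularity_min`).
#'
#' @param image RGB array.
#' @param marrow logical marrow mask.
#' @param circularity_min roundness cutoff (default 0.6).
#' @param min_size smallest vacuole kept (px).
#' @return area fraction of marrow occupied by vacuoles; `NA` when the
#'   marrow mask is empty.
#' @export
marrow_adiposity <- function(image, marrow, circularity_min = 0.6,
                             min_size = 25) {
  if (!any(marrow)) return(NA_real_)
  gray <- rgb_to_gray(image)
  sat <- rgb_saturation(image)
  cand <- gray > 0.85 & sat < 0.25 & marrow
  if (!any(cand)) return(0)
  # adjacent vacuoles merge; split them on the distance transform first,
  # then apply the roundness filter per watershed piece
  edt <- distance_transform(cand)
  markers <- local_maxima_markers(edt, min_height = 3)
  lab <- if (max(markers) > 0) cpp_watershed(-edt, markers, cand) else
    label_components(cand, 8)
  if (max(lab) == 0) return(0)
  area <- tabulate(lab[lab > 0])
  ids <- which(area > 0)
  rmax <- vapply(ids, function(i) max(edt[lab == i]), numeric(1))
  circ <- area[ids] / (pi * pmax(rmax, 0.5)^2)
  keep <- ids[area[ids] >= min_size & circ >= circularity_min & circ <= 1.6]
  sum(area[keep]) / sum(marrow)
}

#' Collagen fraction of the marrow (fibrosis)
#'
#' Unmixes optical densities against a 3-stain basis (hematoxylin, eosin,
#' collagen-toned vector) and reports the fraction of marrow pixels where the
#' collagen channel dominates. The fibrosis score saturates at
#' `min(1, fraction / f_ref)`.
#'
#' @param image RGB array.
#' @param marrow logical marrow mask.
#' @param f_ref saturation point of the fibrosis score (default 0.5).
#' @return list(collagen_fraction, fibrosis_score).
#' @export
collagen_fraction <- function(image, marrow, f_ref = 0.5) {
  if (!any(marrow)) {
    return(list(collagen_fraction = NA_real_, fibrosis_score = NA_real_))
  }
  V3 <- he_reference_stains()
  od <- od_from_rgb(image)
  odm <- rbind(as.numeric(od[, , 1]), as.numeric(od[, , 2]),
               as.numeric(od[, , 3]))
  conc <- pmax(solve(V3, odm), 0)
  H <- dim(image)[1]; W <- dim(image)[2]
  cc <- matrix(conc[3, ], H, W)
  ce <- matrix(conc[2, ], H, W)
  # collagen beats eosin; hematoxylin is ignored so that nuclei sitting on
  # fibrotic stroma do not mask the collagen beneath them
  dom <- cc > ce & cc > 0.15
  f <- sum(dom & marrow) / sum(marrow)
  list(collagen_fraction = f, fibrosis_score = min(1, f / f_ref))
}

#' Nuclear morphometry
#'
#' Hematoxylin-channel thresholding, watershed splitting of touching nuclei
#' on the distance transform, and per-nucleus ellipse fit by second moments:
#' eccentricity e = sqrt(1 - (b/a)^2). Osteocyte lacunae are small bright
#' holes inside bone, counted per bone mm^2; inflammatory cells are small
#' round nuclei in marrow per marrow mm^2.
#'
#' @param image stain-normalized RGB array.
#' @param bone logical bone mask.
#' @param marrow logical marrow mask.
#' @param microns_per_pixel physical scale.
#' @param h_threshold hematoxylin concentration cutoff for nucleus pixels.
#' @return list(nuclei (per-nucleus data.frame: area, ecc, cy, cx,
#'   in_marrow), eccentricity_mean, eccentricity_p90, osteocyte_density_per_mm2,
#'   inflammatory_cell_density_per_mm2).
#' @export
nuclei_morphometry <- function(image, bone, marrow, microns_per_pixel = 4,
                               h_threshold = 0.4) {
  mpp <- microns_per_pixel
  px_per_mm2 <- (1000 / mpp)^2
  conc <- stain_concentrations(image)
  nuc_mask <- conc$hematoxylin > h_threshold
  nuclei <- data.frame()
  if (any(nuc_mask)) {
    edt <- distance_transform(nuc_mask)
    markers <- local_maxima_markers(edt, min_height = 1.2)
    lab <- if (max(markers) > 0) {
      cpp_watershed(-edt, markers, nuc_mask)
    } else label_components(nuc_mask, 8)
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids)) {
      idx <- which(lab > 0)
      l <- lab[idx]
      ys <- (idx - 1) %% nrow(lab) + 1
      xs <- (idx - 1) %/% nrow(lab) + 1
      area <- tabulate(l)
      sy <- rowsum_vec(ys, l); sx <- rowsum_vec(xs, l)
      cy <- sy / area; cx <- sx / area
      syy <- rowsum_vec(ys^2, l) / area - cy^2
      sxx <- rowsum_vec(xs^2, l) / area - cx^2
      sxy <- rowsum_vec(ys * xs, l) / area - cy * cx
      tr <- syy + sxx
      det <- syy * sxx - sxy^2
      l1 <- tr / 2 + sqrt(pmax(0, tr^2 / 4 - det))
      l2 <- tr / 2 - sqrt(pmax(0, tr^2 / 4 - det))
      ecc <- sqrt(pmax(0, 1 - l2 / pmax(l1, 1e-9)))
      in_marrow <- marrow[cbind(round(cy), round(cx))]
      nuclei <- data.frame(id = seq_along(area), area = area, ecc = ecc,
                           cy = cy, cx = cx, in_marrow = in_marrow)
      nuclei <- nuclei[nuclei$area >= 6, ]
    }
  }
  # osteocyte lacunae: bright holes within bone (low in BOTH stains; nuclei
  # overhanging the bone boundary are dark and must not count)
  lac_cand <- conc$eosin < 0.4 & conc$hematoxylin < 0.3 & bone
  lac_lab <- label_components(lac_cand, 8)
  n_lac <- 0L
  if (max(lac_lab) > 0) {
    sz <- tabulate(lac_lab[lac_lab > 0])
    n_lac <- sum(sz >= 4 & sz <= 120)
  }
  bone_mm2 <- sum(bone) / px_per_mm2
  marrow_mm2 <- sum(marrow) / px_per_mm2
  small_round <- if (nrow(nuclei)) {
    nuclei$in_marrow & nuclei$area <= 35 & nuclei$ecc <= 0.65
  } else logical(0)
  list(
    nuclei = nuclei,
    eccentricity_mean = if (nrow(nuclei)) mean(nuclei$ecc) else NA_real_,
    eccentricity_p90 = if (nrow(nuclei))
      unname(quantile(nuclei$ecc, 0.9)) else NA_real_,
    osteocyte_density_per_mm2 = if (bone_mm2 > 0) n_lac / bone_mm2 else
      NA_real_,
    inflammatory_cell_density_per_mm2 = if (marrow_mm2 > 0)
      sum(small_round) / marrow_mm2 else NA_real_
  )
}

rowsum_vec <- function(x, g) as.numeric(rowsum(x, g))

# 3x3 local maxima of a field, labeled as watershed markers
local_maxima_markers <- function(edt, min_height = 1.2) {
  H <- nrow(edt); W <- ncol(edt)
  p <- matrix(-Inf, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- edt
  mx <- pmax(p[1:H, 1:W], p[1:H, 2:(W + 1)], p[1:H, 3:(W + 2)],
             p[2:(H + 1), 1:W], p[2:(H + 1), 3:(W + 2)],
             p[3:(H + 2), 1:W], p[3:(H + 2), 2:(W + 1)], p[3:(H + 2), 3:(W + 2)])
  peaks <- edt >= mx & edt >= min_height
  # merge plateau/adjacent peaks into single markers
  label_components(dilate_mask(peaks, 1.5), 8)
}

#' Full histomorphometry of one slide
#'
#' @param image stain-normalized RGB array.
#' @param microns_per_pixel physical scale.
#' @param tissue optional tissue mask; segmented when NULL.
#' @return one-row data.frame with the 11 handcrafted features (explicit NA
#'   for undefined quantities, never silent zeros).
#' @export
compute_histomorphometry <- function(image, microns_per_pixel = 4,
                                     tissue = NULL) {
  if (is.null(tissue)) tissue <- segment_tissue(image)
  seg <- segment_bone(image, tissue)
  trab <- trabecular_metrics(seg$bone, microns_per_pixel, tissue)
  adip <- marrow_adiposity(image, seg$marrow)
  coll <- collagen_fraction(image, seg$marrow)
  nuc <- nuclei_morphometry(image, seg$bone, seg$marrow, microns_per_pixel)
  data.frame(
    trabecular_bone_fraction = trab$bone_fraction,
    trabecular_thickness_um = trab$thickness_um,
    trabecular_separation_um = trab$separation_um,
    osteocyte_density_per_mm2 = nuc$osteocyte_density_per_mm2,
    marrow_adiposity_fraction = adip,
    collagen_density_fraction = coll$collagen_fraction,
    inflammatory_cell_density_per_mm2 = nuc$inflammatory_cell_density_per_mm2,
    nucleus_eccentricity_mean = nuc$eccentricity_mean,
    trabecular_disruption_score = trab$disruption_score,
    marrow_fibrosis_score = coll$fibrosis_score,
    microns_per_pixel = microns_per_pixel
  )
}

#' Histomorphometry feature table for a set of cases
#'
#' @param cases named list of RGB arrays (names are case ids), or a list of
#'   lists with elements `image` and optionally `microns_per_pixel`.
#' @param microns_per_pixel default scale for plain-array cases.
#' @return data.frame with one row per case (`case_id` first column).
#' @export
feature_table <- function(cases, microns_per_pixel = 4) {
  ids <- names(cases)
  abort_if(is.null(ids) || any(ids == ""), "cases must be a named list")
  abort_if(anyDuplicated(ids) > 0, "duplicate case ids")
  rows <- lapply(seq_along(cases), function(i) {
    x <- cases[[i]]
    if (is.list(x) && !is.null(x$image)) {
      compute_histomorphometry(x$image,
                               x$microns_per_pixel %||% microns_per_pixel)
    } else {
      compute_histomorphometry(x, microns_per_pixel)
    }
  })
  cbind(data.frame(case_id = ids), do.call(rbind, rows))
}
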