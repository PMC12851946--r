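# Low-level image operations shared by the generator, preprocessing and
# morphometry stages. Images are numeric arrays in [0, 1]: H x W matrices for
# grayscale, H x W x 3 arrays for RGB. Binary masks are logical matrices.

#' Otsu threshold of a grayscale image
#'
#' Picks the 8-bit threshold maximizing the between-class variance of the two
#' classes it induces. Pixels strictly greater than the returned threshold are
#' the "above" class. If the image has zero between-class variance everywhere
#' (uniform input) the threshold is returned as `NA` with a warning.
#'
#' @param gray numeric matrix in \[0, 1\].
#' @return scalar threshold in \[0, 1\] (bin midpoint convention: k/255), or
#'   `NA` for degenerate input.
#' @export
otsu_threshold <- function(gray) {
  stopifnot(is.matrix(gray))
  v <- as.integer(round(clamp(as.numeric(gray), 0, 1) * 255))
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  p <- h / n
  omega <- cumsum(p)                      # P(class0) for threshold k = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  k <- 1:255                              # class0 = {0..k-1}, class1 = {k..255}
  w0 <- omega[k]
  w1 <- 1 - w0
  num <- (mu_t * w0 - mu[k])^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, 0)
  if (all(sigma_b <= 0)) {
    warning("uniform image: Otsu threshold undefined")
    return(NA_real_)
  }
  # class0 = bins {0..k-1}; report the bin edge so that x > threshold on the
  # raw [0,1] image reproduces the bin split exactly. Ties: lowest wins.
  (which.max(sigma_b) - 0.5) / 255
}

#' Connected components of a binary mask
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  cpp_label_components(mask, as.integer(connectivity))
}

#' Euclidean distance transform
#'
#' Exact distance (in pixels) from every `TRUE` pixel to the nearest `FALSE`
#' pixel; 0 on `FALSE` pixels.
#' @param mask logical matrix.
#' @return numeric matrix.
#' @export
distance_transform <- function(mask) cpp_edt(mask)

#' Morphological skeleton (Zhang-Suen thinning)
#' @param mask logical matrix.
#' @return logical matrix, 1-px-wide skeleton.
#' @export
skeletonize <- function(mask) cpp_skeletonize(mask)

#' Binary dilation / erosion with a Euclidean disc
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @return logical matrix.
#' @export
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  mask | (cpp_edt(!mask) <= radius)
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  mask & (cpp_edt(mask) > radius)
}

#' Morphological opening then closing (disc structuring element)
#' @param mask logical matrix.
#' @param radius disc radius in pixels.
#' @return logical matrix.
#' @export
open_close_mask <- function(mask, radius = 2) {
  m <- dilate_mask(erode_mask(mask, radius), radius)   # opening
  erode_mask(dilate_mask(m, radius), radius)           # closing
}

#' Gaussian blur (border-renormalized)
#' @param x numeric matrix or H x W x 3 array.
#' @param sigma standard deviation in pixels.
#' @return same shape as `x`.
#' @export
blur_gaussian <- function(x, sigma) {
  k <- max(3L, 2L * as.integer(ceiling(2.5 * sigma)) + 1L)
  ax <- seq_len(k) - (k + 1) / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  g <- g / sum(g)
  kr <- matrix(g, ncol = 1)                # separable: two 1-D passes
  kc <- matrix(g, nrow = 1)
  blur1 <- function(m) {
    num <- cpp_conv2(cpp_conv2(m, kr), kc)
    ones <- matrix(1, nrow(m), ncol(m))
    den <- cpp_conv2(cpp_conv2(ones, kr), kc)
    num / den
  }
  if (is.matrix(x)) return(blur1(x))
  out <- x
  for (ch in seq_len(dim(x)[3])) out[, , ch] <- blur1(x[, , ch])
  out
}

#' Variance of the Laplacian (sharpness statistic)
#' @param gray numeric matrix in \[0,1\].
#' @return scalar; low values indicate blur.
#' @export
laplacian_variance <- function(gray) {
  kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- cpp_conv2(gray, kern)
  # drop the 1-px border affected by zero padding
  h <- nrow(lap); w <- ncol(lap)
  var(as.numeric(lap[2:(h - 1), 2:(w - 1)]))
}

#' RGB to grayscale (luminance)
#' @param img H x W x 3 array in \[0,1\].
#' @return numeric matrix.
#' @export
rgb_to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' HSV saturation channel of an RGB image
#' @param img H x W x 3 array in \[0,1\].
#' @return numeric matrix in \[0,1\].
#' @export
rgb_saturation <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

#' Read / write images (PNG)
#' @param path file path.
#' @return `read_image`: H x W x 3 array in \[0,1\]; grayscale PNGs are
#'   promoted to 3 channels.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3]
  if (dim(x)[3] == 2) x <- array(rep(x[, , 1], 3), c(dim(x)[1:2], 3))
  x
}

#' @rdname read_image
#' @param img image array or mask to write (logical masks become 0/1 gray).
#' @export
write_image <- function(img, path) {
  if (is.logical(img)) img <- matrix(as.numeric(img), nrow(img), ncol(img))
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

# nearest-neighbour upsampling of a matrix by an integer factor
upsample_nn <- function(m, factor) {
  m[rep(seq_len(nrow(m)), each = factor), rep(seq_len(ncol(m)), each = factor)]
}

# bilinear upsampling of a small matrix to (H, W)
upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  # map output pixel centers into input coordinate space
  ry <- (seq_len(H) - 0.5) / H * h + 0.5
  rx <- (seq_len(W) - 0.5) / W * w + 0.5
  y0 <- clamp(floor(ry), 1, h); y1 <- clamp(y0 + 1, 1, h)
  x0 <- clamp(floor(rx), 1, w); x1 <- clamp(x0 + 1, 1, w)
  fy <- ry - y0; fx <- rx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y1, x0, drop = FALSE]
  c_ <- m[y0, x1, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  fY <- matrix(fy, H, W); fX <- matrix(fx, H, W, byrow = TRUE)
  a * (1 - fY) * (1 - fX) + b * fY * (1 - fX) + c_ * (1 - fY) * fX + d * fY * fX
}
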