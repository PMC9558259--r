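#' Read an RGB image as integer channels
#'
#' @param path a PNG file.
#' @return integer array `height x width x 3` with channels in 0-255.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("cannot open image: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  as_rgb255(img[, , 1:3, drop = FALSE])
}

# normalize an image array to integer 0-255 channels
as_rgb255 <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("image must be a height x width x 3 array")
  image <- image[, , 1:3, drop = FALSE]
  if (max(image) <= 1 && min(image) >= 0) image <- image * 255
  storage.mode(image) <- "integer"
  image
}

#' Excess green (ExG) transform
#'
#' Pixelwise `2G - R - B`, unclamped: values lie in -510..510. Vegetation
#' pixels come out positive, achromatic and reddish/brown pixels at or
#' below zero.
#'
#' @param image `height x width x 3` RGB array (0-255, or 0-1 which is
#'   rescaled).
#' @return integer matrix `height x width` of ExG values.
#' @export
exg_transform <- function(image) {
  image <- as_rgb255(image)
  out <- 2L * image[, , 2] - image[, , 1] - image[, , 3]
  dim(out) <- dim(image)[1:2]  # keep matrix shape even for 1-pixel images
  out
}

#' Otsu threshold of a value matrix
#'
#' Maximizes the between-class variance of the integer histogram; the
#' returned threshold `t` is used as `value > t`. Ties resolve to the
#' lowest threshold.
#'
#' @param values integer matrix or vector (e.g. an ExG image).
#' @return the threshold.
#' @export
otsu_threshold <- function(values) {
  v <- as.integer(values)
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) stop("degenerate threshold: constant image")
  h <- as.numeric(tabulate(v - lo + 1L, nbins = hi - lo + 1L))
  lev <- as.numeric(seq.int(lo, hi))
  w0 <- cumsum(h)
  n <- w0[length(w0)]
  m0 <- cumsum(h * lev)
  mt <- m0[length(m0)]
  # classes: values <= t vs values > t, for t = lo .. hi-1
  w0 <- w0[-length(w0)]
  m0 <- m0[-length(m0)]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, length(w0))
  bcv[valid] <- (mt * w0[valid] / n - m0[valid])^2 /
    (w0[valid] / n * w1[valid] / n) / n^2
  lev[which.max(bcv)]
}

#' Binarize an ExG image
#'
#' @param exg ExG matrix from [exg_transform()].
#' @param threshold a number (mask is `exg > threshold`) or `"otsu"`
#'   (default) to pick the threshold by maximizing between-class variance.
#' @return logical mask of the same shape, with attribute `threshold`.
#' @export
binarize_exg <- function(exg, threshold = "otsu") {
  thr <- if (identical(threshold, "otsu")) otsu_threshold(exg) else {
    if (!is.numeric(threshold) || length(threshold) != 1L)
      stop("threshold must be a single number or \"otsu\"")
    threshold
  }
  mask <- exg > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Marker-calibrated area from pixel counts
#'
#' Converts a pixel count into a physical area using reference markers of
#' known total area lying in the same image plane:
#' `area = n_target / n_marker * marker_area_cm2`.
#'
#' @param n_target pixel count of the target (leaves).
#' @param n_marker pixel count of all visible markers, > 0.
#' @param marker_area_cm2 total true area of the visible markers (cm^2);
#'   e.g. four 20 x 20 mm squares give 16 cm^2.
#' @return area in cm^2.
#' @export
area_from_pixel_counts <- function(n_target, n_marker, marker_area_cm2 = 16) {
  if (marker_area_cm2 <= 0) stop("marker_area_cm2 must be > 0")
  if (n_marker <= 0) stop("calibration error: no marker pixels")
  if (n_target < 0) stop("n_target must be >= 0")
  n_target / n_marker * marker_area_cm2
}

#' Dark-marker mask inside user-supplied ROIs
#'
#' ExG cannot isolate black markers, so marker pixels are counted with a
#' low-intensity rule (`max(R, G, B) < intensity_threshold`) restricted to
#' caller-supplied marker regions.
#'
#' @param image RGB array (0-255).
#' @param rois list of ROIs, each `list(rows = c(r0, r1), cols = c(c0, c1))`
#'   (1-based, inclusive); `NULL` uses the whole image.
#' @param intensity_threshold darkness cutoff (default 60).
#' @return logical mask of marker pixels.
#' @export
marker_mask <- function(image, rois = NULL, intensity_threshold = 60) {
  image <- as_rgb255(image)
  dark <- pmax(image[, , 1], image[, , 2], image[, , 3]) < intensity_threshold
  if (is.null(rois)) return(dark)
  inroi <- matrix(FALSE, nrow(dark), ncol(dark))
  for (r in rois)
    inroi[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]] <- TRUE
  dark & inroi
}

#' Marker-calibrated reference area of the green region in an image
#'
#' End-to-end reference measurement: ExG transform, binarization,
#' marker-pixel counting in the supplied ROIs, and pixel-count calibration.
#'
#' @param image RGB array (0-255) or path to a PNG.
#' @param marker_rois ROIs of the reference markers (see [marker_mask()]).
#' @param marker_area_cm2 total true marker area (cm^2).
#' @param threshold passed to [binarize_exg()].
#' @return list with `area_cm2`, `n_target`, `n_marker`, `threshold`,
#'   `mask` (the leaf mask).
#' @export
measure_reference_area <- function(image, marker_rois,
                                   marker_area_cm2 = 16,
                                   threshold = "otsu") {
  if (is.character(image)) image <- read_rgb_image(image)
  image <- as_rgb255(image)
  mask <- binarize_exg(exg_transform(image), threshold)
  mk <- marker_mask(image, marker_rois)
  list(area_cm2 = area_from_pixel_counts(sum(mask), sum(mk), marker_area_cm2),
       n_target = sum(mask), n_marker = sum(mk),
       threshold = attr(mask, "threshold"), mask = mask)
}

#' Write a binary mask as a PNG
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
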