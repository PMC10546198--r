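#' Harmonization pipeline configuration
#'
#' Parameters of the fundus harmonization pipeline. Defaults follow the
#' published recipe where it is explicit (5x5 averaging filter with gain 3
#' for unsharp masking; 800x800 output) and common practice where it is not
#' (CLAHE relative clip 0.01 on an 8x8 tile grid; Gaussian sigma 1 px at the
#' pre-resize resolution; Hough radius search over 0.30-0.60 of the shorter
#' side).
#'
#' @param unsharp_kernel_side Side of the averaging filter (pixels).
#' @param unsharp_gain Gain multiplying the high-pass term.
#' @param clahe_clip Relative CLAHE clip limit (fraction of tile area at
#'   which histogram counts are clipped).
#' @param clahe_tiles CLAHE tile grid `c(rows, cols)`.
#' @param gaussian_sigma Gaussian smoothing sigma in pixels.
#' @param output_side Final square side in pixels.
#' @param hough_radius_frac `c(low, high)` radius search range as fractions
#'   of `min(height, width)`; requires `0 < low < high <= 0.5 * sqrt(2)`.
#' @param hough_edge_quantile Gradient-magnitude quantile above which pixels
#'   vote as edges.
#' @param hough_min_score Normalized accumulator score below which the
#'   detection falls back to a full-frame mask (with a warning).
#' @param hough_downsample Working side (pixels) the image is reduced to for
#'   the accumulator sweep; the circle is then refined at full resolution.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(unsharp_kernel_side = 5, unsharp_gain = 3,
                              clahe_clip = 0.01, clahe_tiles = c(8, 8),
                              gaussian_sigma = 1, output_side = 800,
                              hough_radius_frac = c(0.30, 0.60),
                              hough_edge_quantile = 0.90,
                              hough_min_score = 0.20,
                              hough_downsample = 192) {
  if (unsharp_gain <= 0 || output_side <= 0 || gaussian_sigma <= 0)
    abort("gain, sigma and output_side must be positive.",
          class = "fundusplus_parameter_error")
  lo <- hough_radius_frac[1]; hi <- hough_radius_frac[2]
  if (!(lo > 0 && lo < hi && hi <= 0.5 * sqrt(2)))
    abort("hough_radius_frac must satisfy 0 < low < high <= 0.5*sqrt(2).",
          class = "fundusplus_parameter_error")
  structure(list(unsharp_kernel_side = as.integer(unsharp_kernel_side),
                 unsharp_gain = unsharp_gain, clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 gaussian_sigma = gaussian_sigma,
                 output_side = as.integer(output_side),
                 hough_radius_frac = hough_radius_frac,
                 hough_edge_quantile = hough_edge_quantile,
                 hough_min_score = hough_min_score,
                 hough_downsample = as.integer(hough_downsample)),
            class = "preprocess_config")
}

#' Extract the green channel
#'
#' The green channel carries the highest vessel-to-fundus contrast in RGB
#' fundus photographs, so the whole pipeline operates on it.
#'
#' @param img H x W x 3 RGB array on `[0, 1]` (or a [generate_retina()]
#'   result).
#' @return The green channel as a numeric matrix, unchanged.
#' @export
extract_green <- function(img) {
  if (inherits(img, "synthetic_retina")) img <- img$image
  assert_rgb(img)
  img[, , 2]
}

#' Detect the circular fundus region
#'
#' Hough circular transform: strong gradient pixels vote for circle centers
#' at every candidate radius in the configured range; the best accumulator
#' peak, refined at full resolution, defines the fundus circle. If the peak
#' is weaker than `hough_min_score` (e.g. a constant image) the function
#' falls back to a full-frame mask and warns; the fallback is recorded on
#' the returned object.
#'
#' @param gray Grayscale matrix on `[0, 1]`.
#' @param cfg A [preprocess_config()].
#' @return A `circle_mask` list: `center` (row, col), `radius`, `score`,
#'   `fallback` flag and logical `mask` matrix (TRUE inside the circle).
#' @export
detect_fundus_circle <- function(gray, cfg = preprocess_config()) {
  assert_gray(gray)
  h <- nrow(gray); w <- ncol(gray); ms <- min(h, w)
  fallback <- function(msg) {
    warn(paste0("Fundus circle detection fell back to full frame: ", msg),
         class = "fundusplus_hough_fallback")
    structure(list(center = c((h + 1) / 2, (w + 1) / 2),
                   radius = sqrt(h^2 + w^2) / 2, score = 0, fallback = TRUE,
                   mask = matrix(TRUE, h, w)),
              class = "circle_mask")
  }
  if (max(gray) - min(gray) < 1e-9) return(fallback("constant image"))
  fac <- max(1, ceiling(ms / cfg$hough_downsample))
  small <- if (fac > 1) cpp_resize_bilinear(gray, h %/% fac, w %/% fac) else gray
  small <- cpp_gaussian_blur(small, 1) # denoise before edge voting
  rmin <- max(3L, floor(cfg$hough_radius_frac[1] * min(dim(small))))
  rmax <- max(rmin + 1L, ceiling(cfg$hough_radius_frac[2] * min(dim(small))))
  peak <- cpp_hough_circle(small, rmin, rmax, cfg$hough_edge_quantile)
  if (!is.finite(peak$score) || peak$score < cfg$hough_min_score)
    return(fallback(sprintf("accumulator score %.3f below %.3f",
                            peak$score, cfg$hough_min_score)))
  cy <- peak$cy * fac; cx <- peak$cx * fac; r <- peak$r * fac
  if (fac > 1) {
    ref <- cpp_ring_refine(gray, cy, cx, r, fac + 1L)
    cy <- ref$cy; cx <- ref$cx; r <- ref$r
  }
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  structure(list(center = c(cy, cx), radius = r, score = peak$score,
                 fallback = FALSE, mask = mask),
            class = "circle_mask")
}

#' Mask, crop and square
#'
#' Multiplies the image by the fundus mask, crops to the mask's bounding
#' box, and appends zero-valued rows or columns symmetrically (the extra
#' one on the bottom/right when odd) so the output is square.
#'
#' @param gray Grayscale matrix.
#' @param mask A `circle_mask` from [detect_fundus_circle()] (or any object
#'   with a logical `mask` matrix of matching size).
#' @return Square grayscale matrix.
#' @export
crop_and_square <- function(gray, mask) {
  assert_gray(gray)
  m <- if (is.list(mask)) mask$mask else mask
  if (!any(m))
    abort("Empty fundus mask.", class = "fundusplus_degenerate_error")
  x <- gray * m
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  x <- x[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  h <- nrow(x); w <- ncol(x); side <- max(h, w)
  out <- matrix(0, side, side)
  r0 <- (side - h) %/% 2; c0 <- (side - w) %/% 2
  out[r0 + seq_len(h), c0 + seq_len(w)] <- x
  out
}

#' Linear unsharp masking
#'
#' `out = clip(in + gain * (in - boxmean(in)), 0, 1)` with a
#' `unsharp_kernel_side` averaging filter and reflective borders.
#'
#' @inheritParams detect_fundus_circle
#' @return Sharpened grayscale matrix on `[0, 1]`.
#' @export
unsharp <- function(gray, cfg = preprocess_config()) {
  assert_gray(gray)
  k <- cfg$unsharp_kernel_side
  if (nrow(gray) < k || ncol(gray) < k)
    abort(sprintf("Image must be at least %dx%d for unsharp masking.", k, k),
          class = "fundusplus_degenerate_error")
  clamp01(gray + cfg$unsharp_gain * (gray - cpp_box_mean(gray, k)))
}

#' Contrast limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with relative clip limit
#' `clahe_clip` (fraction of the tile area) and bilinear interpolation of
#' the tile mappings, preventing noise over-amplification in uniform
#' regions. If the requested grid would give tiles smaller than 2 px the
#' grid is reduced with a warning.
#'
#' @inheritParams detect_fundus_circle
#' @param nbins Number of histogram bins.
#' @return Equalized grayscale matrix on `[0, 1]`.
#' @export
clahe <- function(gray, cfg = preprocess_config(), nbins = 256) {
  assert_gray(gray)
  tiles <- cfg$clahe_tiles
  tr <- min(tiles[1], nrow(gray) %/% 2)
  tc <- min(tiles[2], ncol(gray) %/% 2)
  if (tr < tiles[1] || tc < tiles[2])
    warn(sprintf("CLAHE tile grid reduced to %dx%d for a %dx%d image.",
                 tr, tc, nrow(gray), ncol(gray)))
  tr <- max(1L, tr); tc <- max(1L, tc)
  cpp_clahe(gray, as.integer(nbins), cfg$clahe_clip, tr, tc)
}

#' Gaussian smoothing
#'
#' Convolution with a normalized Gaussian kernel (reflective borders),
#' counteracting over-sharpening of non-vascular regions such as specular
#' reflections.
#'
#' @inheritParams detect_fundus_circle
#' @param sigma Optional sigma override (pixels); defaults to the config.
#' @return Smoothed grayscale matrix.
#' @export
gaussian_smooth <- function(gray, cfg = preprocess_config(), sigma = NULL) {
  assert_gray(gray)
  s <- if (is.null(sigma)) cfg$gaussian_sigma else sigma
  if (s <= 0) abort("sigma must be > 0.", class = "fundusplus_parameter_error")
  cpp_gaussian_blur(gray, s)
}

#' Bilinear resize of a square image
#'
#' @param gray Square grayscale matrix.
#' @param side Output side in pixels.
#' @return `side` x `side` matrix. A same-size input is returned unchanged.
#' @export
resize_square <- function(gray, side = 800) {
  assert_gray(gray)
  if (nrow(gray) != ncol(gray))
    abort("resize_square() expects a square input.",
          class = "fundusplus_contract_error")
  if (nrow(gray) == side) return(gray)
  clamp01(cpp_resize_bilinear(gray, as.integer(side), as.integer(side)))
}

#' Harmonize a fundus photograph
#'
#' The full enhancement pipeline: green channel, Hough fundus mask,
#' crop/square, unsharp masking, CLAHE, Gaussian smoothing, and resize to
#' `output_side` (800 px by default). All filtering happens at the native
#' cropped resolution; resizing is last. The pipeline is deterministic.
#'
#' @param img RGB array, [generate_retina()] result, or a grayscale matrix
#'   (treated as an already-extracted green channel).
#' @param cfg A [preprocess_config()].
#' @return A `harmonized_image`: list with `image` (square matrix on
#'   `[0, 1]`) and `provenance` (steps applied, detected circle, fallback
#'   flag, config and its hash).
#' @export
harmonize <- function(img, cfg = preprocess_config()) {
  g <- if (is.matrix(img)) { assert_gray(img); img } else extract_green(img)
  circ <- detect_fundus_circle(g, cfg)
  x <- crop_and_square(g, circ)
  x <- unsharp(x, cfg)
  x <- clahe(x, cfg)
  x <- gaussian_smooth(x, cfg)
  x <- resize_square(x, cfg$output_side)
  structure(list(
    image = x,
    provenance = list(
      steps = c("extract_green", "detect_fundus_circle", "crop_and_square",
                "unsharp", "clahe", "gaussian_smooth", "resize_square"),
      circle = list(center = circ$center, radius = circ$radius,
                    score = circ$score, fallback = circ$fallback),
      config = unclass(cfg),
      config_hash = rlang::hash(unclass(cfg))
    )
  ), class = "harmonized_image")
}

#' @export
print.harmonized_image <- function(x, ...) {
  circ <- x$provenance$circle
  cat(sprintf("<harmonized_image> %dx%d; circle (%.0f, %.0f) r=%.0f%s\n",
              nrow(x$image), ncol(x$image), circ$center[1], circ$center[2],
              circ$radius, if (circ$fallback) " [fallback mask]" else ""))
  invisible(x)
}

#' Harmonize every image of a cohort
#'
#' @param cohort Cohort tibble with an `image` list-column (RGB arrays).
#' @param cfg A [preprocess_config()].
#' @param keep_image Keep the original RGB arrays in the result? Dropping
#'   them (default) bounds memory for large cohorts.
#' @return The cohort with a `harmonized` list-column of matrices and a
#'   `mask_fallback` logical column.
#' @export
harmonize_cohort <- function(cohort, cfg = preprocess_config(),
                             keep_image = FALSE) {
  hs <- purrr::map(cohort$image, harmonize, cfg = cfg)
  cohort$harmonized <- purrr::map(hs, "image")
  cohort$mask_fallback <- purrr::map_lgl(hs, function(h) h$provenance$circle$fallback)
  if (!keep_image) cohort$image <- NULL
  cohort
}
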