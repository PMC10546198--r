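#' Mean local contrast
#'
#' Sweeps a 3x3 window over every fully interior position and averages the
#' Michelson-style local contrast `(max - min) / (max + min)`; windows with
#' `max + min == 0` contribute 0. The statistic lies in `[0, 1]`, is 0 for
#' a constant image and invariant to multiplying a strictly positive image
#' by a constant.
#'
#' @param gray Grayscale matrix on `[0, 1]`, at least 3x3.
#' @param mask Optional logical matrix: only windows whose center lies in
#'   the mask are included (e.g. restrict to the fundus disc).
#' @return Scalar mean local contrast, with the number of windows included
#'   as attribute `n_windows`.
#' @export
local_contrast <- function(gray, mask = NULL) {
  assert_gray(gray)
  if (nrow(gray) < 3 || ncol(gray) < 3)
    abort("local_contrast() needs at least a 3x3 image.",
          class = "fundusplus_degenerate_error")
  if (is.null(mask)) {
    r <- cpp_local_contrast(gray)
    return(structure(r$C, n_windows = r$n_windows))
  }
  # masked variant: brute-force sweep (used for the fundus-only option)
  h <- nrow(gray); w <- ncol(gray)
  acc <- 0; n <- 0
  for (j in 2:(w - 1)) for (i in 2:(h - 1)) {
    if (!mask[i, j]) next
    win <- gray[(i - 1):(i + 1), (j - 1):(j + 1)]
    mx <- max(win); mn <- min(win)
    if (mx + mn > 0) acc <- acc + (mx - mn) / (mx + mn)
    n <- n + 1
  }
  structure(if (n > 0) acc / n else 0, n_windows = n)
}

#' Contrast improvement index
#'
#' Ratio of the mean local contrast of a processed image to that of the
#' original: `CII = C_proposed / C_original`. Values above 1 indicate
#' enhancement. The two images may have different sizes (each contributes a
#' per-image mean).
#'
#' @param proposed Processed grayscale matrix (or [harmonize()] result).
#' @param original Original grayscale matrix.
#' @return A `contrast_report` tibble row with columns `c_original`,
#'   `c_proposed`, `cii`, `n_windows_original`, `n_windows_proposed`.
#' @export
cii <- function(proposed, original) {
  if (inherits(proposed, "harmonized_image")) proposed <- proposed$image
  cp <- local_contrast(proposed)
  co <- local_contrast(original)
  if (co == 0)
    abort("C of the original image is 0: CII undefined.",
          class = "fundusplus_degenerate_error")
  out <- tibble::tibble(
    c_original = as.numeric(co), c_proposed = as.numeric(cp),
    cii = as.numeric(cp) / as.numeric(co),
    n_windows_original = attr(co, "n_windows"),
    n_windows_proposed = attr(cp, "n_windows")
  )
  class(out) <- c("contrast_report", class(out))
  out
}
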