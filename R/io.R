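#' Read a fundus photograph
#'
#' Reads a PNG or JPEG file into an RGB array with values on `[0, 1]`.
#' Grayscale files are replicated to three channels; an alpha channel, if
#' present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An H x W x 3 numeric array with values in `[0, 1]`.
#' @export
read_fundus_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        abort("Reading JPEG requires the 'jpeg' package.")
      jpeg::readJPEG(path)
    },
    abort(sprintf("Unsupported image format '%s' (expect png/jpeg).", ext),
          class = "fundusplus_format_error")
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- array(rep(img[, , 1], 3L), c(dim(img)[1:2], 3L))
  assert_rgb(img, "image file")
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param gray Numeric matrix with values in `[0, 1]`, or a
#'   [harmonize()] result.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(gray, path) {
  if (inherits(gray, "harmonized_image")) gray <- gray$image
  assert_gray(gray)
  png::writePNG(gray, path)
  invisible(path)
}

#' Write an RGB image as 8-bit PNG
#'
#' @param img H x W x 3 array with values in `[0, 1]`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  assert_rgb(img)
  png::writePNG(img, path)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Renders every image of a cohort to PNG and writes a CSV manifest with
#' columns `filename`, `label`, `image_side`, `seed`.
#'
#' @param cohort A cohort tibble from [generate_cohort()] with an `image`
#'   list-column.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!"image" %in% names(cohort) || any(vapply(cohort$image, is.null, logical(1))))
    abort("Cohort has no rendered images; call generate_cohort(render = TRUE).")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(
    filename = sprintf("retina_%04d_%s.png", seq_len(nrow(cohort)),
                       as.character(cohort$label)),
    label = as.character(cohort$label),
    image_side = cohort$image_side,
    seed = cohort$seed
  )
  purrr::walk2(cohort$image, manifest$filename,
               function(img, f) write_rgb_png(img, file.path(dir, f)))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param path Path to a `manifest.csv` written by [write_cohort()] (or of
#'   the same shape: at least `filename` and `label` columns).
#' @return A tibble with the manifest columns and `label` as a
#'   `no_plus`/`plus` factor.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("filename", "label") %in% names(m)))
    abort("Manifest must have 'filename' and 'label' columns.",
          class = "fundusplus_format_error")
  m$label <- as_plus_factor(m$label)
  m
}

# JSON provenance sidecar for a harmonized image
write_provenance <- function(h, path) {
  jsonlite::write_json(h$provenance, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
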