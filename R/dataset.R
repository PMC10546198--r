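#' Merge the pre-plus grade into no-plus
#'
#' Collapses the three clinical plus-disease grades to the binary task that
#' triggers treatment: `no plus` and `pre plus` become `no_plus`; `plus`
#' stays `plus`. Grade strings are matched case-insensitively with spaces,
#' hyphens or underscores accepted.
#'
#' @param x A data frame with a grade column, or a character/factor vector
#'   of grades.
#' @param grade Column holding the grades when `x` is a data frame
#'   (tidy-eval; default `grade`).
#' @return For a data frame: the same frame with a `label` factor column
#'   (`no_plus`/`plus`). For a vector: the label factor.
#' @export
merge_preplus <- function(x, grade = grade) {
  if (is.data.frame(x)) {
    g <- dplyr::pull(x, {{ grade }})
    x$label <- merge_grade_vector(g)
    return(tibble::as_tibble(x))
  }
  merge_grade_vector(x)
}

merge_grade_vector <- function(g) {
  g0 <- as.character(g)
  key <- gsub("[ _-]+", "_", tolower(trimws(g0)))
  map <- c(no_plus = "no_plus", pre_plus = "no_plus", plus = "plus")
  out <- unname(map[key])
  bad <- which(is.na(out) & !is.na(g0))
  if (length(bad))
    abort(paste0("Unknown plus-disease grade(s): ",
                 paste(sprintf("'%s' (record %d)", g0[bad], bad), collapse = ", "),
                 ". Expected 'no plus', 'pre plus' or 'plus'."),
          class = "fundusplus_validation_error")
  as_plus_factor(out)
}

#' Stratified k-fold assignment
#'
#' Partitions each class as evenly as possible across `k` folds (fold ids
#' `0 .. k-1`), deterministically given the seed. With a 385/55
#' class split and `k = 5`, every test fold holds exactly 77 no-plus and 11
#' plus images and every training set 308 and 44.
#'
#' @param data Tibble with a `label` column (`no_plus`/`plus` factor or
#'   coercible).
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed Integer seed.
#' @return `data` with an integer `fold` column added.
#' @export
stratified_kfold <- function(data, k, seed) {
  if (k < 2) abort("k must be >= 2.", class = "fundusplus_parameter_error")
  lab <- as_plus_factor(data$label)
  cnt <- table(lab)
  if (any(cnt < k))
    abort(sprintf("Class '%s' has fewer members (%d) than folds (%d).",
                  names(cnt)[which.min(cnt)], min(cnt), k),
          class = "fundusplus_parameter_error")
  fold <- integer(nrow(data))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(lab)) {
      idx <- which(lab == cl)
      idx <- sample(idx)
      fold[idx] <- (seq_along(idx) - 1L) %% as.integer(k)
    }
  })
  data$fold <- fold
  tibble::as_tibble(data)
}

#' Eightfold geometric augmentation of one image
#'
#' The eight label-preserving transforms used to inflate each class:
#' identity, five rotations (60, 120, 180, 240, 300 degrees by default,
#' bilinear with zero fill — safe because the harmonized fundus is a
#' centered disc on black), reflection over the x-axis and reflection over
#' the y-axis.
#'
#' @param img Square grayscale matrix (or [harmonize()] result).
#' @param angles The five rotation angles in degrees.
#' @return Named list of 8 matrices (`identity`, `rot60`, ..., `flip_x`,
#'   `flip_y`), all the shape of the input.
#' @export
augment_eightfold <- function(img, angles = c(60, 120, 180, 240, 300)) {
  if (inherits(img, "harmonized_image")) img <- img$image
  assert_gray(img)
  if (nrow(img) != ncol(img))
    abort("Augmentation expects a square image.",
          class = "fundusplus_contract_error")
  if (length(angles) != 5)
    abort("Exactly five rotation angles are required.",
          class = "fundusplus_parameter_error")
  out <- c(list(identity = img),
           lapply(angles, function(a) clamp01(cpp_rotate_bilinear(img, a))),
           list(flip_x = img[nrow(img):1, , drop = FALSE],
                flip_y = img[, ncol(img):1, drop = FALSE]))
  names(out)[2:6] <- paste0("rot", angles)
  out
}

# apply one named transform (tag from augmentation_tags()) to a square image
apply_augmentation <- function(img, tag, angles = c(60, 120, 180, 240, 300)) {
  switch(tag,
    identity = img,
    flip_x = img[nrow(img):1, , drop = FALSE],
    flip_y = img[, ncol(img):1, drop = FALSE],
    {
      a <- as.numeric(sub("^rot", "", tag))
      if (is.na(a)) abort(sprintf("Unknown augmentation tag '%s'.", tag))
      clamp01(cpp_rotate_bilinear(img, a))
    })
}

augmentation_tags <- function(angles = c(60, 120, 180, 240, 300)) {
  c("identity", paste0("rot", angles), "flip_x", "flip_y")
}

#' Expand a dataset eightfold with augmentation tags
#'
#' Produces one row per (image, transform) pair with provenance columns
#' `parent_id` and `augmentation`, inheriting label and fold. Pixel data are
#' not duplicated: transforms are applied lazily (at training resolution)
#' by the classifier, and the provenance tags double as the
#' train/test-leakage guard — augmented descendants of a test-fold image
#' are never eligible for training.
#'
#' @param data Tibble with `id` and `label` columns (and optionally `fold`,
#'   `harmonized`).
#' @param angles The five rotation angles.
#' @return Tibble with 8x the rows: `id`, `parent_id`, `augmentation`, and
#'   the inherited columns.
#' @export
augment_dataset <- function(data, angles = c(60, 120, 180, 240, 300)) {
  tags <- augmentation_tags(angles)
  out <- tidyr::crossing(parent_id = data$id, augmentation = tags)
  out <- dplyr::left_join(out,
                          dplyr::rename(data, parent_id = "id"),
                          by = "parent_id")
  out$id <- paste(out$parent_id, out$augmentation, sep = "/")
  dplyr::relocate(out, "id", "parent_id", "augmentation")
}

#' Randomized balanced selection
#'
#' Draws `total / 2` rows uniformly without replacement from each class of
#' an (augmented) pool, giving a class-balanced training set —
#' deterministic given the seed.
#'
#' @param data Pool tibble with a `label` column.
#' @param total Even total size of the selection.
#' @param seed Integer seed.
#' @return Tibble of `total` rows, exactly `total / 2` per class.
#' @export
balance_select <- function(data, total, seed) {
  if (total %% 2 != 0)
    abort("`total` must be even.", class = "fundusplus_parameter_error")
  per <- total %/% 2
  lab <- as_plus_factor(data$label)
  cnt <- table(lab)
  low <- names(cnt)[cnt < per]
  if (length(low))
    abort(sprintf("Class '%s' pool (%d) smaller than requested %d per class.",
                  low[1], cnt[low[1]], per),
          class = "fundusplus_parameter_error")
  keep <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(lab), function(cl) sample(which(lab == cl), per)))
  })
  tibble::as_tibble(data[sort(keep), , drop = FALSE])
}
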