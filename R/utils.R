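# shared validation helpers (internal)

is_gray <- function(x) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) && min(x) >= 0 && max(x) <= 1
}

assert_gray <- function(x, arg = "gray") {
  if (!is.matrix(x) || !is.numeric(x))
    abort(sprintf("`%s` must be a numeric matrix.", arg), class = "fundusplus_format_error")
  if (!all(is.finite(x)))
    abort(sprintf("`%s` contains non-finite values.", arg), class = "fundusplus_format_error")
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    abort(sprintf("`%s` must have values in [0, 1].", arg), class = "fundusplus_format_error")
  invisible(x)
}

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    abort(sprintf("`%s` must be an H x W x 3 RGB array.", arg),
          class = "fundusplus_format_error")
  if (!all(is.finite(img)) || min(img) < -1e-9 || max(img) > 1 + 1e-9)
    abort(sprintf("`%s` must have finite values in [0, 1].", arg),
          class = "fundusplus_format_error")
  invisible(img)
}

# label handling: binary labels are a factor with levels no_plus < plus
plus_levels <- c("no_plus", "plus")

as_plus_factor <- function(x) {
  factor(as.character(x), levels = plus_levels)
}

label_to_y <- function(label) as.integer(as_plus_factor(label) == "plus")

# deterministic child seeds below 2^31 derived from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

round_half_up <- function(x) floor(x + 0.5)

clamp01 <- function(x) pmin(pmax(x, 0), 1) # x first: keeps dim attributes
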