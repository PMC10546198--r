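#' Real-world cost weights
#'
#' Marginal dollar costs of the two error types. The default operating
#' point prices a missed case of plus disease (lifelong blindness) at
#' $1,700,000 and an unnecessary treatment at $17,000 — a 100:1 ratio, with
#' 50:1 and 200:1 as sensitivity alternates.
#'
#' @param w_fn Cost of a false negative (dollars), > 0.
#' @param w_fp Cost of a false positive (dollars), > 0.
#' @return A `cost_weights` list.
#' @export
cost_weights <- function(w_fn = 1700000, w_fp = 17000) {
  if (!(w_fn > 0 && w_fp > 0))
    abort("Both cost weights must be > 0.", class = "fundusplus_parameter_error")
  structure(list(w_fn = w_fn, w_fp = w_fp), class = "cost_weights")
}

check_batch <- function(h, y) {
  if (length(h) == 0)
    abort("Empty prediction batch.", class = "fundusplus_parameter_error")
  if (length(h) != length(y))
    abort("Predictions and targets differ in length.",
          class = "fundusplus_validation_error")
  if (!all(y %in% c(0, 1)))
    abort("Targets must be binary (0/1).", class = "fundusplus_validation_error")
}

#' Real-world-weight cross-entropy loss
#'
#' Binary cross-entropy with distinct marginal costs on the two error
#' directions:
#' `J = -(1/M) * sum( w_fn * y * log(h) + w_fp * (1 - y) * log(1 - h) )`,
#' with predictions clamped to `[eps, 1 - eps]`. With unit weights this is
#' exactly the standard binary cross-entropy; scaling both weights scales
#' the loss (and leaves its optimum unchanged).
#'
#' @param h Predicted plus-probabilities.
#' @param y Binary targets (1 = plus).
#' @param w A [cost_weights()] object.
#' @param eps Clamping constant for log stability.
#' @return Scalar loss.
#' @export
rwwce <- function(h, y, w = cost_weights(), eps = 1e-7) {
  check_batch(h, y)
  hc <- pmin(1 - eps, pmax(eps, h))
  -mean(w$w_fn * y * log(hc) + w$w_fp * (1 - y) * log(1 - hc))
}

#' Standard binary cross-entropy
#'
#' [rwwce()] with unit weights.
#'
#' @inheritParams rwwce
#' @return Scalar loss.
#' @export
cross_entropy <- function(h, y, eps = 1e-7) {
  rwwce(h, y, cost_weights(1, 1), eps)
}

# analytic dJ/dh for the (possibly weighted) cross-entropy; h pre-clamped
rwwce_grad <- function(h, y, w = cost_weights(), eps = 1e-7) {
  check_batch(h, y)
  hc <- pmin(1 - eps, pmax(eps, h))
  -(w$w_fn * y / hc - w$w_fp * (1 - y) / (1 - hc)) / length(h)
}

#' Loss specification for training
#'
#' Bundles the loss choice and weights for the classifier. With
#' `normalize_weights = TRUE` (default) both dollar weights are divided by
#' `w_fp` before optimization — the 100:1 ratio, and hence the optimum, is
#' preserved while keeping gradient magnitudes sane; set it to `FALSE` to
#' optimize on raw dollars.
#'
#' @param name `"ce"` or `"rwwce"`.
#' @param weights A [cost_weights()] (ignored for `"ce"`).
#' @param normalize_weights Rescale weights by `1 / w_fp`?
#' @return A `loss_spec` list with the effective weights in `$w`.
#' @export
loss_spec <- function(name = c("ce", "rwwce"), weights = cost_weights(),
                      normalize_weights = TRUE) {
  name <- match.arg(name)
  w <- if (name == "ce") cost_weights(1, 1)
       else if (normalize_weights)
         cost_weights(weights$w_fn / weights$w_fp, 1)
       else weights
  structure(list(name = name, w = w, weights_in = weights,
                 normalize_weights = normalize_weights),
            class = "loss_spec")
}
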