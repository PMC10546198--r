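#' Tidy a ROC curve
#'
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @return The `(fpr, tpr, threshold)` points as a tibble with a `method`
#'   column.
#' @export
tidy.roc_curve <- function(x, ...) {
  dplyr::mutate(x$points, method = x$method)
}

#' @rdname tidy.roc_curve
#' @return `glance()`: one row with `auc`, `method`, class sizes.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, method = x$method, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot a ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s ROC, AUC = %.3f", object$method, object$auc)) +
    ggplot2::theme_minimal()
}

#' Tidy a trained classifier
#'
#' @param x A `fundus_cnn`.
#' @param ... Unused.
#' @return One row per parameter tensor: `term`, `n_parameters`, `mean`,
#'   `sd`.
#' @export
tidy.fundus_cnn <- function(x, ...) {
  purrr::imap_dfr(x$net, function(p, nm) {
    tibble::tibble(term = nm, n_parameters = length(p),
                   mean = mean(p), sd = if (length(p) > 1) sd(as.numeric(p)) else 0)
  })
}

#' @rdname tidy.fundus_cnn
#' @return `glance()`: one-row training summary.
#' @export
glance.fundus_cnn <- function(x, ...) {
  tibble::tibble(backbone = x$config$backbone, input_side = x$config$input_side,
                 epochs = x$config$epochs, loss = x$loss$name,
                 initial_loss = x$initial_loss, final_loss = x$final_loss,
                 n_train = x$n_train, seed = x$config$seed)
}

#' Plot the training loss history
#'
#' @param object A `fundus_cnn`.
#' @param ... Unused.
#' @return A ggplot of loss versus epoch.
#' @export
autoplot.fundus_cnn <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Epoch", y = sprintf("%s loss", object$loss$name)) +
    ggplot2::theme_minimal()
}

#' Display a grayscale image or activation map
#'
#' @param img Matrix on `[0, 1]` (e.g. a harmonized image or a [cam()]
#'   map), or a `harmonized_image`.
#' @param title Optional plot title.
#' @return A ggplot raster plot.
#' @export
plot_gray <- function(img, title = NULL) {
  if (inherits(img, "harmonized_image")) img <- img$image
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}
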