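#' Classifier configuration
#'
#' The desk-scale backbone (`small_cnn`) is a 4-block convolutional network
#' — 3x3 convolutions with 8/16/32/32 channels, ReLU, 2x2 max pooling after
#' the first three blocks — followed by global average pooling and a 2-unit
#' softmax head, trained with Adam. Harmonized 800x800 images are
#' downscaled to `input_side` inside the model adapter. The
#' `transfer_inception` mode mirrors the published transfer-learning setup
#' (ImageNet-pretrained 22-layer inception network with the first 20 layers
#' frozen and the head replaced); it requires pretrained weights and a deep
#' learning runtime that are not available in this build, so selecting it
#' raises an informative error.
#'
#' @param backbone `"small_cnn"` or `"transfer_inception"`.
#' @param input_side Network input side in pixels (multiple of 8; default
#'   128).
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Integer seed governing initialization and shuffling.
#' @param channels Channel widths of the four conv blocks.
#' @param frozen_depth Frozen layer blocks (transfer mode only).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(backbone = c("small_cnn", "transfer_inception"),
                              input_side = 128, epochs = 10, batch_size = 32,
                              learning_rate = 1e-3, seed = 1,
                              channels = c(8, 16, 32, 32), frozen_depth = 20) {
  backbone <- match.arg(backbone)
  if (input_side <= 0 || input_side %% 8 != 0)
    abort("input_side must be a positive multiple of 8.",
          class = "fundusplus_parameter_error")
  if (epochs < 1) abort("epochs must be >= 1.", class = "fundusplus_parameter_error")
  structure(list(backbone = backbone, input_side = as.integer(input_side),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 channels = as.integer(channels),
                 frozen_depth = as.integer(frozen_depth)),
            class = "classifier_config")
}

cnn_init <- function(cfg) {
  ch <- c(1L, cfg$channels)
  net <- list()
  for (b in 1:4) {
    fanin <- 9L * ch[b]
    net[[paste0("W", b)]] <- matrix(rnorm(fanin * ch[b + 1], sd = sqrt(2 / fanin)),
                                    fanin, ch[b + 1])
    net[[paste0("b", b)]] <- rep(0, ch[b + 1])
  }
  net$Wd <- matrix(rnorm(ch[5] * 2, sd = sqrt(2 / ch[5])), ch[5], 2)
  net$bd <- rep(0, 2)
  net
}

cnn_forward <- function(net, x, keep = FALSE) {
  a <- array(x, c(nrow(x), ncol(x), 1L))
  acts <- list(a0 = a)
  for (b in 1:4) {
    z <- cpp_conv_fwd(a, net[[paste0("W", b)]], net[[paste0("b", b)]])
    r <- pmax(z, 0)
    if (b < 4) {
      p <- cpp_maxpool_fwd(r)
      if (keep) acts[[paste0("z", b)]] <- z
      if (keep) acts[[paste0("idx", b)]] <- p$idx
      if (keep) acts[[paste0("in", b + 1)]] <- p$y
      a <- p$y
    } else {
      if (keep) acts$z4 <- z
      a <- r
    }
  }
  feat <- a # final conv feature maps (S/8 x S/8 x C)
  g <- apply(feat, 3, mean)
  z <- as.vector(crossprod(net$Wd, g) + net$bd)
  e <- exp(z - max(z))
  hvec <- e / sum(e)
  out <- list(p = hvec[2], g = g, feat = feat)
  if (keep) out$acts <- acts
  out
}

cnn_backward <- function(net, fwd, dJdp) {
  acts <- fwd$acts
  p <- fwd$p
  dz <- dJdp * p * (1 - p) * c(-1, 1)
  gr <- list(Wd = fwd$g %o% dz, bd = dz)
  dg <- as.vector(net$Wd %*% dz)
  feat <- fwd$feat
  sp <- dim(feat)[1] * dim(feat)[2]
  df <- array(rep(dg / sp, each = sp), dim(feat))
  dcur <- df * (acts$z4 > 0)
  for (b in 4:1) {
    xin <- if (b == 1) acts$a0 else acts[[paste0("in", b)]]
    bw <- cpp_conv_bwd(xin, net[[paste0("W", b)]], dcur)
    gr[[paste0("W", b)]] <- bw$dW
    gr[[paste0("b", b)]] <- as.vector(bw$db)
    if (b > 1) {
      hprev <- dim(xin)[1] * 2L
      dpool <- cpp_maxpool_bwd(bw$dx, acts[[paste0("idx", b - 1)]], hprev, hprev)
      dcur <- dpool * (acts[[paste0("z", b - 1)]] > 0)
    }
  }
  gr
}

prepare_input <- function(img, side) {
  if (inherits(img, "harmonized_image")) img <- img$image
  if (!is.matrix(img)) abort("Expected a grayscale matrix input.",
                             class = "fundusplus_format_error")
  if (nrow(img) != ncol(img))
    abort("Classifier inputs must be square.", class = "fundusplus_contract_error")
  if (nrow(img) == side) img else cpp_resize_bilinear(img, side, side)
}

# resolve the image + transform for each dataset row at network resolution,
# caching the downscaled parent so eightfold variants share one resize
resolve_images <- function(data, side) {
  imgs <- data[[if ("harmonized" %in% names(data)) "harmonized" else "image"]]
  if (is.null(imgs))
    abort("Dataset needs a 'harmonized' (or grayscale 'image') list-column.",
          class = "fundusplus_format_error")
  keys <- if ("parent_id" %in% names(data)) data$parent_id else
    if ("id" %in% names(data)) data$id else as.character(seq_len(nrow(data)))
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    key <- keys[i]
    small <- if (!is.null(cache[[key]])) cache[[key]] else {
      v <- prepare_input(imgs[[i]], side)
      cache[[key]] <- v
      v
    }
    tag <- if ("augmentation" %in% names(data)) data$augmentation[i] else "identity"
    out[[i]] <- apply_augmentation(small, tag)
  }
  out
}

#' Train the plus-disease classifier
#'
#' Minibatch Adam on the small CNN with either standard cross-entropy or
#' the real-world-weight loss. Training is deterministic given
#' `cfg$seed` (all randomness flows through R's RNG; the numerics are
#' single-threaded).
#'
#' @param data Training tibble: a `label` column plus a `harmonized` (or
#'   grayscale `image`) list-column; rows from [augment_dataset()] /
#'   [balance_select()] carry their transform tags and are materialized
#'   lazily at network resolution.
#' @param cfg A [classifier_config()].
#' @param loss A [loss_spec()].
#' @param test_ids Optional character vector of held-out image ids; training
#'   aborts if any training row (or its augmentation parent) is among them
#'   (leakage guard).
#' @return A `fundus_cnn` model with the learned parameters, the epoch loss
#'   history and provenance (config, loss, seed, hashes).
#' @export
train_classifier <- function(data, cfg = classifier_config(),
                             loss = loss_spec("ce"), test_ids = NULL) {
  if (cfg$backbone == "transfer_inception")
    abort(paste("The transfer_inception backbone needs pretrained inception",
                "weights and a deep-learning runtime that are not available",
                "in this build; use backbone = 'small_cnn'."),
          class = "fundusplus_unsupported_backbone")
  if (nrow(data) == 0)
    abort("Empty training dataset.", class = "fundusplus_parameter_error")
  y <- label_to_y(data$label)
  if (length(unique(y)) < 2)
    abort("Training data contain a single class.",
          class = "fundusplus_parameter_error")
  if (!is.null(test_ids)) {
    parents <- if ("parent_id" %in% names(data)) data$parent_id else data$id
    leaked <- intersect(unique(parents), test_ids)
    if (length(leaked))
      abort(paste0("Train/test leakage: augmented descendants of held-out ",
                   "image(s) ", paste(head(leaked, 5), collapse = ", "),
                   " appear in the training set."),
            class = "fundusplus_leakage_error")
  }
  xs <- resolve_images(data, cfg$input_side)
  n <- length(xs)
  withr::with_seed(cfg$seed, {
    net <- cnn_init(cfg)
    mstate <- lapply(net, function(p) p * 0)
    vstate <- mstate
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0
    epoch_loss <- numeric(cfg$epochs)
    h0 <- vapply(xs, function(x) cnn_forward(net, x)$p, numeric(1))
    initial_loss <- rwwce(h0, y, loss$w)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      bl <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        fwds <- lapply(xs[idx], cnn_forward, net = net, keep = TRUE)
        h <- vapply(fwds, `[[`, numeric(1), "p")
        dJdh <- rwwce_grad(h, y[idx], loss$w)
        gacc <- NULL
        for (m in seq_along(idx)) {
          g1 <- cnn_backward(net, fwds[[m]], dJdh[m])
          gacc <- if (is.null(gacc)) g1 else purrr::map2(gacc, g1, `+`)
        }
        t_step <- t_step + 1
        for (nm in names(net)) {
          g <- gacc[[nm]]
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
          mhat <- mstate[[nm]] / (1 - beta1^t_step)
          vhat <- vstate[[nm]] / (1 - beta2^t_step)
          net[[nm]] <- net[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        }
        bl <- c(bl, rwwce(h, y[idx], loss$w))
      }
      epoch_loss[ep] <- mean(bl)
    }
  })
  structure(list(
    net = net, config = cfg, loss = loss,
    history = tibble::tibble(epoch = seq_len(cfg$epochs), loss = epoch_loss),
    initial_loss = initial_loss, final_loss = epoch_loss[cfg$epochs],
    n_train = n,
    provenance = list(seed = cfg$seed, loss_name = loss$name,
                      config_hash = rlang::hash(unclass(cfg)))
  ), class = "fundus_cnn")
}

#' @export
print.fundus_cnn <- function(x, ...) {
  cat(sprintf(
    "<fundus_cnn> %s @ %dpx, %d epochs, loss %s: %.4f -> %.4f (n=%d)\n",
    x$config$backbone, x$config$input_side, x$config$epochs, x$loss$name,
    x$initial_loss, x$final_loss, x$n_train))
  invisible(x)
}

#' Predict plus-disease probabilities
#'
#' @param object A trained `fundus_cnn`.
#' @param newdata A tibble with a `harmonized`/`image` list-column, a list
#'   of grayscale matrices, or a single matrix.
#' @param ... Unused.
#' @return Numeric vector of plus-probabilities in `(0, 1)`, one per image.
#' @export
predict.fundus_cnn <- function(object, newdata, ...) {
  imgs <- if (is.matrix(newdata)) list(newdata)
          else if (is.data.frame(newdata)) resolve_images(newdata, object$config$input_side)
          else if (is.list(newdata)) newdata
          else abort("Unsupported newdata type.", class = "fundusplus_format_error")
  vapply(imgs, function(im) {
    cnn_forward(object$net, prepare_input(im, object$config$input_side))$p
  }, numeric(1))
}

#' Class activation map
#'
#' Weighted sum of the final convolutional feature maps using the head
#' weights of the requested class, rectified, bilinearly upsampled to the
#' input image and normalized so the maximum is 1 (unless the map is
#' all-zero). Highlights the regions driving the classification.
#'
#' @param model A trained `fundus_cnn`.
#' @param img Grayscale matrix (any square size) or [harmonize()] result.
#' @param class Which head unit to explain (default `"plus"`).
#' @return Matrix of the same size as `img` with values in `[0, 1]`.
#' @export
cam <- function(model, img, class = c("plus", "no_plus")) {
  class <- match.arg(class)
  if (inherits(img, "harmonized_image")) img <- img$image
  x <- prepare_input(img, model$config$input_side)
  fwd <- cnn_forward(model$net, x)
  wcls <- model$net$Wd[, if (class == "plus") 2 else 1]
  feat <- fwd$feat
  map <- matrix(0, dim(feat)[1], dim(feat)[2])
  for (ch in seq_along(wcls)) map <- map + wcls[ch] * feat[, , ch]
  map <- pmax(map, 0)
  up <- cpp_resize_bilinear(map, nrow(img), ncol(img))
  if (max(up) > 0) up <- up / max(up)
  up
}
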