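# shared fixtures and independent oracles

# brute-force mean local contrast, independent of the C++ sweep
local_contrast_bf <- function(m) {
  h <- nrow(m); w <- ncol(m)
  vals <- c()
  for (j in 2:(w - 1)) for (i in 2:(h - 1)) {
    win <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    mx <- max(win); mn <- min(win)
    vals <- c(vals, if (mx + mn > 0) (mx - mn) / (mx + mn) else 0)
  }
  mean(vals)
}

# Mann-Whitney pair-counting AUC (ties count one half)
auc_pairs <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# a bright disc on black, for circle-detection tests
disc_image <- function(side, cy, cx, r, value = 0.8) {
  yy <- matrix(seq_len(side), side, side)
  xx <- matrix(seq_len(side), side, side, byrow = TRUE)
  value * ((yy - cy)^2 + (xx - cx)^2 <= r^2)
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# one small trained model shared across classifier tests (built once)
.fixture_env <- new.env(parent = emptyenv())

demo_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  ds <- generate_cohort(24, 24, seed = 77, side_range = c(300L, 500L))
  ds <- harmonize_cohort(ds)
  tr <- dplyr::slice(ds, c(1:16, 25:40))
  te <- dplyr::slice(ds, c(17:24, 41:48))
  pool <- augment_dataset(tr)
  trb <- balance_select(pool, 240, seed = 5)
  model <- train_classifier(
    trb, classifier_config(input_side = 64, epochs = 8, seed = 9),
    loss_spec("ce"), test_ids = te$id)
  .fixture_env$fit <- list(model = model, train = trb, test = te)
  .fixture_env$fit
}
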