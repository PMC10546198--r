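#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations for [run_pipeline()]. The defaults
#' describe a desk-scale demonstration: a synthetic cohort at the
#' screening program's 12.5% plus prevalence, harmonization to 800x800, a stratified 5-fold
#' split with fold 0 held out, eightfold augmentation with randomized
#' balanced selection, and the small CNN trained with the cost-weighted
#' loss.
#'
#' @param n_no_plus,n_plus Synthetic cohort class counts.
#' @param effect_size Class-separation multiplier of the generator.
#' @param k Number of folds; fold 0 is the held-out test fold.
#' @param balance_total Balanced training-set size; `NULL` picks the
#'   largest even size the augmented pools support (capped at the default
#'   600).
#' @param preprocess A [preprocess_config()].
#' @param classifier A [classifier_config()].
#' @param loss A [loss_spec()].
#' @param threshold Decision threshold for evaluation.
#' @param seed Global seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_no_plus = 88, n_plus = 12, effect_size = 1,
                            k = 5, balance_total = NULL,
                            preprocess = preprocess_config(),
                            classifier = classifier_config(),
                            loss = loss_spec("rwwce"),
                            threshold = 0.5, seed = 1) {
  structure(list(n_no_plus = n_no_plus, n_plus = n_plus,
                 effect_size = effect_size, k = k,
                 balance_total = balance_total, preprocess = preprocess,
                 classifier = classifier, loss = loss, threshold = threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening workflow
#'
#' Simulate (or accept) a labeled cohort, harmonize every image, split into
#' stratified folds, augment and balance the training folds, train the
#' classifier, and evaluate on the held-out unaugmented fold. Every stage
#' seed derives from the global seed, so reports are reproducible.
#'
#' @param cfg A [pipeline_config()].
#' @param cohort Optional pre-built cohort tibble (with `image` or
#'   `harmonized` list-column and `label`); when `NULL` a synthetic cohort
#'   is generated.
#' @param out_dir Optional directory; when given, `report.json` is written
#'   there.
#' @return A report list: counts, confusion matrix, metrics, empirical and
#'   binormal AUC, real-world cost, and provenance (config hash, seeds).
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  seeds <- derive_seeds(cfg$seed, 4L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "fundusplus_stage_error")
    })
  }
  if (is.null(cohort))
    cohort <- stage("simulate",
      generate_cohort(cfg$n_no_plus, cfg$n_plus, seed = seeds[1],
                      effect_size = cfg$effect_size))
  if (!"harmonized" %in% names(cohort))
    cohort <- stage("harmonize", harmonize_cohort(cohort, cfg$preprocess))
  cohort <- stage("split", stratified_kfold(cohort, cfg$k, seed = seeds[2]))
  test_set <- dplyr::filter(cohort, .data$fold == 0)
  train_parents <- dplyr::filter(cohort, .data$fold != 0)
  pool <- stage("augment", augment_dataset(train_parents))
  total <- cfg$balance_total
  if (is.null(total)) {
    cnt <- table(as_plus_factor(pool$label))
    total <- min(600, 2 * min(cnt))
  }
  train_set <- stage("balance", balance_select(pool, total, seed = seeds[3]))
  cfg$classifier$seed <- seeds[4]
  model <- stage("train",
    train_classifier(train_set, cfg$classifier, cfg$loss,
                     test_ids = test_set$id))
  probs <- stage("evaluate", predict(model, test_set))
  cc <- confusion_counts(probs, test_set$label, cfg$threshold)
  mets <- classification_metrics(cc)
  roc_e <- roc_empirical(probs, test_set$label)
  roc_b <- tryCatch(roc_binormal(probs, test_set$label),
                    error = function(e) NULL)
  report <- list(
    config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
    stage_seeds = seeds,
    counts = list(total = nrow(cohort), train = nrow(train_set),
                  test = nrow(test_set),
                  test_plus = sum(test_set$label == "plus")),
    loss = cfg$loss$name,
    normalize_weights = cfg$loss$normalize_weights,
    confusion = as.list(cc[, c("tp", "fp", "tn", "fn")]),
    metrics = as.list(mets),
    auc_empirical = roc_e$auc,
    auc_binormal = if (!is.null(roc_b)) roc_b$auc else NA,
    real_world_cost = real_world_cost(cc, cfg$loss$weights_in),
    final_training_loss = model$final_loss
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}
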