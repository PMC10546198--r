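test_that("merge_preplus groups pre-plus with no-plus", {
  expect_equal(as.character(merge_preplus(c("no plus", "pre plus", "plus"))),
               c("no_plus", "no_plus", "plus"))
  expect_equal(as.character(merge_preplus(rep("pre plus", 4))), rep("no_plus", 4))
  expect_length(merge_preplus(character()), 0)
  expect_error(merge_preplus(c("plus", "maybe plus")),
               class = "fundusplus_validation_error")
  expect_error(merge_preplus(c("plus", "severe")), "record 2")
  df <- tibble::tibble(file = c("a", "b"), grade = c("Pre-Plus", "plus"))
  out <- merge_preplus(df)
  expect_equal(as.character(out$label), c("no_plus", "plus"))
})

test_that("stratified folds reproduce the 385/55 worked arithmetic and partition", {
  ds <- generate_cohort(385, 55, seed = 2, render = FALSE)
  ds <- stratified_kfold(ds, 5, seed = 3)
  tab <- table(ds$fold, ds$label)
  expect_true(all(tab[, "no_plus"] == 77))
  expect_true(all(tab[, "plus"] == 11))
  expect_setequal(unique(ds$fold), 0:4)
  # partition: union is everything, folds disjoint by construction
  expect_equal(sort(unname(unlist(split(ds$id, ds$fold)))), sort(ds$id))
  # small case and determinism
  tiny <- tibble::tibble(id = letters[1:8],
                         label = rep(c("no_plus", "plus"), each = 4))
  f1 <- stratified_kfold(tiny, 2, seed = 1)
  expect_true(all(table(f1$fold, f1$label) == 2))
  expect_identical(f1, stratified_kfold(tiny, 2, seed = 1))
  expect_error(stratified_kfold(tiny, 5, seed = 1),
               class = "fundusplus_parameter_error")
})

test_that("per-fold class proportions deviate by less than one image", {
  ds <- generate_cohort(103, 29, seed = 4, render = FALSE)
  ds <- stratified_kfold(ds, 5, seed = 5)
  tab <- table(ds$fold, ds$label)
  for (cl in colnames(tab)) {
    expect_lt(max(tab[, cl]) - min(tab[, cl]), 2) # as even as possible
  }
})

test_that("augment_eightfold yields 8 distinct shape-preserving variants", {
  withr::with_seed(10, img <- matrix(runif(64 * 64), 64, 64))
  aug <- augment_eightfold(img)
  expect_length(aug, 8)
  expect_named(aug, c("identity", "rot60", "rot120", "rot180", "rot240",
                      "rot300", "flip_x", "flip_y"))
  for (a in aug) expect_equal(dim(a), dim(img))
  # pairwise distinct for a generic asymmetric input
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(identical(aug[[i]], aug[[j]]))
  # flips are involutions
  expect_identical(aug$flip_x[64:1, ], img)
  expect_identical(aug$flip_y[, 64:1], img)
  expect_error(augment_eightfold(matrix(0.1, 10, 20)),
               class = "fundusplus_contract_error")
})

test_that("augment_dataset expands 8x with provenance", {
  ds <- tibble::tibble(id = sprintf("i%03d", 1:308),
                       label = "no_plus", fold = rep(0:3, 77))
  aug <- augment_dataset(ds)
  expect_equal(nrow(aug), 2464)
  expect_equal(length(unique(aug$parent_id)), 308)
  expect_true(all(table(aug$parent_id) == 8))
  expect_true(all(aug$fold == rep(ds$fold[order(ds$id)], each = 8)[1] |
                    aug$fold %in% 0:3)) # fold inherited
  expect_setequal(unique(aug$augmentation),
                  c("identity", "rot60", "rot120", "rot180", "rot240",
                    "rot300", "flip_x", "flip_y"))
})

test_that("balance_select draws equal classes without duplicates", {
  pool <- tibble::tibble(
    id = c(sprintf("n%04d", 1:2464), sprintf("p%04d", 1:352)),
    label = c(rep("no_plus", 2464), rep("plus", 352)))
  sel <- balance_select(pool, 600, seed = 6)
  expect_equal(nrow(sel), 600)
  expect_true(all(table(as.character(sel$label)) == c(300, 300)))
  expect_false(any(duplicated(sel$id)))
  expect_identical(sel, balance_select(pool, 600, seed = 6))
  # exhaustive draw
  tiny <- tibble::tibble(id = 1:16, label = rep(c("no_plus", "plus"), each = 8))
  expect_equal(sort(balance_select(tiny, 16, seed = 1)$id), 1:16)
  expect_error(balance_select(tiny, 20, seed = 1), "plus",
               class = "fundusplus_parameter_error")
  expect_error(balance_select(tiny, 15, seed = 1),
               class = "fundusplus_parameter_error")
})

test_that("rotation fill stays black and augmentation preserves range", {
  withr::with_seed(11, img <- matrix(runif(32 * 32, 0.2, 1), 32, 32))
  aug <- augment_eightfold(img)
  for (a in aug) expect_true(all(a >= 0 & a <= 1))
  expect_equal(aug$rot60[1, 1], 0) # corners rotate out of the fundus
})
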