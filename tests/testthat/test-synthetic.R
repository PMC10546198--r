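test_that("rendering is deterministic given (params, seed)", {
  p <- retina_params(image_side = 320, n_specular = 0, illumination_tilt = 0)
  a <- generate_retina(p, 3)
  b <- generate_retina(p, 3)
  expect_identical(a$image, b$image)
  p2 <- retina_params(image_side = 320, n_specular = 2, illumination_tilt = 0.2)
  expect_identical(generate_retina(p2, 11)$image, generate_retina(p2, 11)$image)
  expect_false(identical(generate_retina(p2, 11)$image,
                         generate_retina(p2, 12)$image))
})

test_that("fundus geometry: black outside the disc, brighter inside", {
  r <- generate_retina(retina_params(image_side = 300), 4)
  side <- dim(r$image)[1]
  yy <- matrix(seq_len(side), side, side)
  xx <- matrix(seq_len(side), side, side, byrow = TRUE)
  d <- sqrt((yy - r$fundus$center[1])^2 + (xx - r$fundus$center[2])^2)
  outside <- d > r$fundus$radius
  for (k in 1:3) expect_true(all(r$image[, , k][outside] == 0))
  expect_gt(mean(r$image[, , 2][!outside]), 0.1)
})

test_that("a vessel-free retina has a smooth green channel", {
  p0 <- retina_params(image_side = 320, n_vessels = 0, n_specular = 0)
  p1 <- retina_params(image_side = 320, n_vessels = 8, n_specular = 0)
  g0 <- extract_green(generate_retina(p0, 5))
  g1 <- extract_green(generate_retina(p1, 5))
  expect_lt(local_contrast(g0), local_contrast(g1))
  expect_length(generate_retina(p0, 5)$centerlines, 0)
})

test_that("radius fraction >= 0.5 is rejected", {
  expect_error(retina_params(fundus_radius_frac = 0.5),
               class = "fundusplus_parameter_error")
})

test_that("tortuosity_index: straight line, half circle, lower bound", {
  straight <- cbind(seq(0, 10, length.out = 11), 0)
  expect_equal(tortuosity_index(straight), 1.0)
  th <- seq(0, pi, length.out = 2000)
  half <- cbind(5 * cos(th), 5 * sin(th))
  expect_equal(tortuosity_index(half), pi / 2, tolerance = 1e-3)
  withr::with_seed(8, {
    for (i in 1:20) {
      poly <- cbind(cumsum(rnorm(10)), cumsum(rnorm(10)))
      expect_gte(tortuosity_index(poly), 1)
    }
  })
  expect_error(tortuosity_index(rbind(c(1, 1), c(1, 1))),
               class = "fundusplus_degenerate_error")
  expect_error(tortuosity_index(cbind(1, 1)),
               class = "fundusplus_degenerate_error")
})

test_that("plus draws render more tortuous centerlines than no_plus", {
  ds <- generate_cohort(50, 50, seed = 11, side_range = c(300L, 600L))
  ti <- purrr::map_dbl(ds$centerlines,
                       function(cl) mean(vapply(cl, tortuosity_index, numeric(1))))
  expect_gt(mean(ti[ds$label == "plus"]) - mean(ti[ds$label == "no_plus"]), 0)
})

test_that("generate_cohort honours counts, emptiness and the seed", {
  ds <- generate_cohort(385, 55, seed = 1, render = FALSE)
  expect_equal(nrow(ds), 440)
  expect_equal(as.integer(table(ds$label)), c(385, 55))
  expect_equal(nrow(generate_cohort(0, 0, seed = 1)), 0)
  d1 <- generate_cohort(10, 10, seed = 9, side_range = c(300L, 400L))
  d2 <- generate_cohort(10, 10, seed = 9, side_range = c(300L, 400L))
  expect_identical(d1$label, d2$label)
  expect_identical(d1$image, d2$image)
})

test_that("cohorts round-trip through PNG + manifest", {
  skip_if_not_installed("png")
  ds <- generate_cohort(2, 1, seed = 3, side_range = c(300L, 320L))
  dir <- withr::local_tempdir()
  man <- write_cohort(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m2), 3)
  back <- read_fundus_image(file.path(dir, man$filename[1]))
  expect_equal(dim(back), dim(ds$image[[1]]))
  # 8-bit quantization only
  expect_lt(max(abs(back - ds$image[[1]])), 1 / 255)
})
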