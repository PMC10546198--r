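test_that("extract_green returns exactly the green channel", {
  img <- array(0, c(4, 4, 3)); img[, , 2] <- 1
  expect_equal(extract_green(img), matrix(1, 4, 4))
  img2 <- array(0, c(4, 4, 3)); img2[, , 1] <- 1
  expect_equal(extract_green(img2), matrix(0, 4, 4))
  expect_error(extract_green(matrix(0, 4, 4)), class = "fundusplus_format_error")
})

test_that("green channel shows more vessel contrast than red", {
  r <- generate_retina(retina_params(image_side = 400, n_specular = 0), 2)
  expect_gt(local_contrast(r$image[, , 2]), local_contrast(r$image[, , 1]))
})

test_that("Hough detection recovers a known disc within 3 px", {
  img <- disc_image(400, 200, 200, 150)
  circ <- detect_fundus_circle(img)
  expect_false(circ$fallback)
  expect_lt(max(abs(circ$center - c(200, 200))), 3)
  expect_lt(abs(circ$radius - 150), 3)
  # 90 degree rotation invariance (square frame, centered disc)
  circ2 <- detect_fundus_circle(rot90cw(img))
  expect_lt(max(abs(circ2$center - c(200, 200))), 3)
  expect_lt(abs(circ2$radius - 150), 3)
})

test_that("constant image takes the fallback path with a warning", {
  expect_warning(circ <- detect_fundus_circle(matrix(0.5, 64, 64)),
                 class = "fundusplus_hough_fallback")
  expect_true(circ$fallback)
  expect_true(all(circ$mask))
})

test_that("crop_and_square geometry", {
  # disc of diameter 200 px (center on a half-pixel, radius 100)
  img <- disc_image(400, 200.5, 200.5, 100, value = 0.6)
  circ <- list(mask = disc_image(400, 200.5, 200.5, 100, value = 1) > 0)
  out <- crop_and_square(img, circ)
  expect_equal(dim(out), c(200, 200))
  # circle clipped by the left frame edge: bbox 150 wide x 200 tall
  mask2 <- disc_image(400, 200.5, 50.5, 100, value = 1) > 0
  mask2[, 151:400] <- FALSE # keep the clipped lobe: cols 1..150
  img2 <- matrix(0.5, 400, 400)
  out2 <- crop_and_square(img2 * mask2, list(mask = mask2))
  expect_equal(dim(out2), c(200, 200))
  expect_true(all(out2[, 1:25] == 0))
  expect_true(all(out2[, 176:200] == 0))
  # everything outside the mask is exactly zero
  inside <- crop_and_square(matrix(1, 400, 400), circ)
  m_sq <- crop_and_square(circ$mask * 1, circ)
  expect_true(all(inside[m_sq == 0] == 0))
  expect_error(crop_and_square(img, list(mask = matrix(FALSE, 400, 400))),
               class = "fundusplus_degenerate_error")
})

test_that("unsharp masking matches the closed form", {
  const <- matrix(0.4, 16, 16)
  expect_equal(unsharp(const), const)
  imp <- matrix(0, 11, 11); imp[6, 6] <- 0.25
  out <- unsharp(imp)
  # 5x5 mean at center = 0.25/25 = 0.01; 0.25 + 3*(0.25-0.01) = 0.97
  expect_equal(out[6, 6], 0.97, tolerance = 1e-12)
  # overshoot bright side, undershoot dark side of a step edge
  step <- cbind(matrix(0.2, 12, 6), matrix(0.8, 12, 6))
  so <- unsharp(step)
  expect_gt(max(so[, 7:12]), 0.8)
  expect_lt(min(so[6, 5:6]), 0.2)
})

test_that("clahe: constants stay constant, contrast rises, bounds hold", {
  cst <- clahe(matrix(0.3, 64, 64))
  expect_equal(max(cst) - min(cst), 0)
  r <- generate_retina(retina_params(image_side = 400, n_specular = 0), 6)
  g <- extract_green(r)
  low <- g * 0.3 + 0.35 # squeeze dynamic range
  expect_gt(local_contrast(clahe(low)), local_contrast(low))
  withr::with_seed(2, {
    sp <- matrix(sample(c(0, 1), 64 * 64, TRUE), 64, 64)
    for (img in list(matrix(0, 32, 32), matrix(1, 32, 32), sp)) {
      out <- clahe(img)
      expect_true(all(out >= 0 & out <= 1))
    }
  })
  expect_warning(clahe(matrix(runif(64), 8, 8)), "tile grid reduced")
})

test_that("gaussian_smooth is normalized and has the right spread", {
  cst <- matrix(0.7, 20, 20)
  expect_equal(gaussian_smooth(cst), cst, tolerance = 1e-9)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  out <- gaussian_smooth(imp, sigma = 1.5)
  expect_equal(sum(out), 1, tolerance = 1e-9) # kernel normalization
  idx <- seq_len(41) - 21
  m2_row <- sum(outer(idx^2, rep(1, 41)) * out) # second moment along rows
  expect_equal(m2_row, 1.5^2, tolerance = 0.02 * 1.5^2)
  expect_error(gaussian_smooth(imp, sigma = 0), class = "fundusplus_parameter_error")
})

test_that("resize_square shapes and identity", {
  x800 <- matrix(runif(800 * 800), 800, 800)
  expect_identical(resize_square(x800, 800), x800)
  expect_equal(resize_square(matrix(0.5, 400, 400), 800), matrix(0.5, 800, 800))
  expect_equal(dim(resize_square(matrix(runif(200 * 200), 200, 200), 800)),
               c(800, 800))
  expect_error(resize_square(matrix(0.5, 10, 20), 800),
               class = "fundusplus_contract_error")
})

test_that("harmonize always yields 800x800, deterministically", {
  for (side in c(300L, 517L)) {
    r <- generate_retina(retina_params(image_side = side), side)
    h <- harmonize(r)
    expect_equal(dim(h$image), c(800, 800))
    expect_false(h$provenance$circle$fallback)
  }
  r <- generate_retina(retina_params(image_side = 420), 1)
  expect_identical(harmonize(r)$image, harmonize(r)$image)
  expect_equal(harmonize(r)$provenance$steps[1], "extract_green")
})

test_that("harmonization commutes with a 90 degree rotation", {
  r <- generate_retina(retina_params(image_side = 360, n_specular = 0), 13)
  g <- extract_green(r)
  h1 <- harmonize(g)$image
  h2 <- harmonize(rot90cw(g))$image
  expect_lt(mean(abs(rot90cw(h1) - h2)), 0.02)
})
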