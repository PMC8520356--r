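test_that("Sobel gradient matches hand convolution", {
  ## constant image: no gradient anywhere
  g0 <- sobel_gradient(gray_image(matrix(7L, 5, 5)))
  expect_true(all(g0$S == 0))
  expect_equal(g0$S_avg, 0)
  expect_true(all(g0$S_mu == 0))

  ## vertical step 0|0|255: center Gx = 4 * 255, Gy = 0
  m <- matrix(c(0, 0, 0, 0, 0, 0, 255, 255, 255), 3, 3)
  expect_equal(sobel_gradient(gray_image(m))$S[2, 2], 1020)

  ## isolated bright center: both kernels have zero center weight
  imp <- matrix(0L, 3, 3); imp[2, 2] <- 255L
  expect_equal(sobel_gradient(gray_image(imp))$S[2, 2], 0)

  ## S_mu is a local mean: bounded by the window min/max of S
  set.seed(1)
  img <- gray_image(matrix(sample(0:255, 64, TRUE), 8, 8))
  gr <- sobel_gradient(img)
  expect_equal(gr$S_avg, mean(gr$S))
  for (i in 2:7) for (j in 2:7) {
    w <- gr$S[(i - 1):(i + 1), (j - 1):(j + 1)]
    expect_gte(gr$S_mu[i, j], min(w) - 1e-9)
    expect_lte(gr$S_mu[i, j], max(w) + 1e-9)
  }

  expect_error(sobel_gradient(matrix(0, 2, 2)), "3 x 3")
})

test_that("pixel classification marks edge bands and suppresses impulses", {
  ## constant image: strictly-greater rule puts every pixel in class 2
  g0 <- sobel_gradient(gray_image(matrix(100L, 8, 8)))
  expect_true(all(classify_pixels(g0) == 2L))

  ## vertical step on a 16x16 flat image: detail labels form a band around
  ## the edge columns; pixels far from the edge stay in class 2
  step <- matrix(0L, 16, 16); step[, 9:16] <- 200L
  lab <- classify_pixels(sobel_gradient(gray_image(step)))
  expect_true(all(lab[, c(1:5, 12:16)] == 2L))
  expect_true(any(lab[, 8:9] == 1L))

  ## a single impulse of the same amplitude produces no more detail pixels
  ## than the true step edge
  imp <- matrix(0L, 16, 16); imp[8, 8] <- 200L
  lab_imp <- classify_pixels(sobel_gradient(gray_image(imp)))
  expect_lte(sum(lab_imp == 1L), sum(lab == 1L))
})

test_that("Otsu threshold equals the exhaustive oracle, ties to smallest t", {
  expect_equal(otsu_threshold(c(0, 0, 255, 255))$threshold, 0)
  expect_equal(otsu_threshold(rep(c(50, 200), each = 10))$threshold, 50)
  degen <- otsu_threshold(rep(77L, 9))
  expect_equal(degen$threshold, 77)
  expect_true(degen$degenerate)
  expect_error(otsu_threshold(integer(256)), "empty")

  set.seed(202)
  for (i in 1:50) {
    counts <- integer(256)
    bins <- sample(0:255, sample(2:15, 1))
    counts[bins + 1] <- sample(1:40, length(bins), TRUE)
    expect_identical(otsu_threshold(counts)$threshold, otsu_brute(counts))
  }
})

test_that("between-class + within-class variance equals total variance", {
  set.seed(7)
  for (rep in 1:10) {
    counts <- integer(256)
    bins <- sample(0:255, 12)
    counts[bins + 1] <- sample(1:30, 12, TRUE)
    p <- counts / sum(counts); g <- 0:255
    mu_T <- sum(p * g); var_T <- sum(p * (g - mu_T)^2)
    sb <- otsu_threshold(counts)$between_var
    for (t in c(0, 63, 127, 200, 254)) {
      w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
      sw <- 0
      if (w0 > 0) {
        mu0 <- sum(p[1:(t + 1)] * g[1:(t + 1)]) / w0
        sw <- sw + sum(p[1:(t + 1)] * (g[1:(t + 1)] - mu0)^2)
      }
      if (w1 > 0) {
        mu1 <- sum(p[(t + 2):256] * g[(t + 2):256]) / w1
        sw <- sw + sum(p[(t + 2):256] * (g[(t + 2):256] - mu1)^2)
      }
      expect_equal(sb[t + 1] + sw, var_T, tolerance = 1e-9)
    }
  }
})

test_that("global and multi-threshold segmentation partition correctly", {
  img <- gray_image(matrix(c(0, 0, 255, 255, 100, 100, 200, 0, 50), 3, 3))
  expect_true(all(!global_segment(img, 255)))          # T = L-1: all zero
  expect_equal(sum(global_segment(img, 0)), 6)          # f > 0
  expect_error(global_segment(img, -1), "range")

  ## n = 1 multi-threshold agrees with the global rule
  expect_identical(multi_segment(img, 100) == 1L, global_segment(img, 100))

  lab <- multi_segment(gray_image(matrix(rep(c(0, 100, 200), each = 3), 3, 3)),
                       c(50, 150))
  expect_equal(lab[, 1], rep(0L, 3))
  expect_equal(lab[, 2], rep(1L, 3))
  expect_equal(lab[, 3], rep(2L, 3))
  expect_error(multi_segment(img, c(150, 50)), "ascending")

  ## three-level phantom with thresholds between the modes recovers the
  ## generator classes exactly in the noise-free case
  ph <- make_phantom(phantom_spec(noise_sigma = 0, bias_amplitude = 0))
  lab3 <- multi_segment(ph$image, c(40, 120))   # bg 20 | csf 60 | tissue 180
  expect_identical(lab3 == 2L, ph$tissue_mask)
  expect_identical(lab3 == 1L, ph$ventricle_mask)
  expect_identical(lab3 == 0L, !ph$brain_mask)
})

test_that("noise-free phantom segments to the ground-truth tissue mask", {
  ph <- make_phantom(phantom_spec(tissue_intensity = 180, csf_intensity = 60,
                                  noise_sigma = 0, bias_amplitude = 0))
  B <- global_segment(ph$image, 100)
  expect_identical(B, ph$tissue_mask)
  seg <- hvs_segment(ph$image)
  expect_gte(dice(seg$B, ph$tissue_mask), 0.99)
})

test_that("sub-image decomposition, thresholding, and merge are consistent", {
  set.seed(31)
  img <- gray_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  labels <- classify_pixels(sobel_gradient(img))
  T0 <- otsu_threshold(img)$threshold
  dec <- decompose_subimages(img, labels, T0)
  expect_true(all(xor(dec$I1_mask, dec$I2_mask)))
  expect_equal(sum(dec$I1_mask) + sum(dec$I2_mask), 400)

  ## whole-image membership reduces to plain Otsu + global segmentation
  full <- threshold_subimage(img, matrix(TRUE, 20, 20), T0)
  expect_equal(full$threshold, T0)
  expect_identical(full$binary, global_segment(img, T0))

  ## four-pixel sub-image: exhaustive oracle
  m4 <- matrix(100L, 4, 4); m4[1, 1:2] <- 0L; m4[2, 1:2] <- 255L
  mask4 <- matrix(FALSE, 4, 4); mask4[1:2, 1:2] <- TRUE
  s4 <- threshold_subimage(gray_image(m4), mask4, 50)
  expect_equal(s4$threshold, 0)
  expect_equal(sum(s4$binary), 2)
  expect_true(all(!s4$binary[!mask4]))

  ## degenerate membership falls back to the whole-image threshold
  mdeg <- matrix(100L, 4, 4); mdeg[4, 4] <- 0L
  maskdeg <- matrix(FALSE, 4, 4); maskdeg[1:2, ] <- TRUE
  sdeg <- threshold_subimage(gray_image(mdeg), maskdeg, 90)
  expect_true(sdeg$degenerate)
  expect_equal(sdeg$threshold, 90)
  expect_true(all(sdeg$binary[maskdeg]))   # 100 > 90 on every member

  expect_warning(threshold_subimage(img, matrix(FALSE, 20, 20), T0), "empty")

  ## merge semantics
  I1 <- matrix(FALSE, 3, 3); I1[1, ] <- TRUE
  B1 <- I1; B2 <- matrix(FALSE, 3, 3)
  expect_identical(merge_masks(B1, B2, I1, !I1), I1)
  expect_identical(merge_masks(matrix(FALSE, 3, 3), B2,
                               matrix(FALSE, 3, 3) | FALSE,
                               matrix(TRUE, 3, 3)), B2)
  expect_error(merge_masks(B1, B2, I1, I1), "overlap")
  expect_error(merge_masks(B1, B2, I1, matrix(FALSE, 3, 3)), "cover")
})

test_that("hybrid segmentation keeps every pixel's sub-image result", {
  for (seed in 1:20) {
    ph <- make_phantom(phantom_spec(noise_sigma = 12, bias_amplitude = 0.05,
                                    seed = seed))
    seg <- hvs_segment(ph$image)
    expect_identical(seg$B[seg$I1_mask], seg$B1[seg$I1_mask])
    expect_identical(seg$B[seg$I2_mask], seg$B2[seg$I2_mask])
    expect_true(all(!seg$B1[!seg$I1_mask]))
    expect_true(all(!seg$B2[!seg$I2_mask]))
  }
})

test_that("hybrid segmentation is deterministic and shift-invariant", {
  ph <- make_phantom(phantom_spec(noise_sigma = 8, seed = 4))
  s1 <- hvs_segment(ph$image)
  s2 <- hvs_segment(ph$image)
  expect_identical(s1$B, s2$B)
  expect_identical(s1$T1, s2$T1)

  ## adding a constant (no clipping) shifts every threshold but not B
  shifted <- gray_image(unclass(ph$image) + 20L,
                        pixel_spacing = ph$spec$pixel_spacing)
  s3 <- hvs_segment(shifted)
  expect_identical(s3$B, s1$B)
  expect_equal(s3$T_otsu, s1$T_otsu + 20)
})

test_that("monotone gray relabeling leaves the Otsu binary map unchanged", {
  set.seed(12)
  img <- gray_image(matrix(sample(0:127, 225, TRUE), 15, 15))
  T0 <- otsu_threshold(img)$threshold
  B0 <- global_segment(img, T0)
  relab <- function(g) 2L * g + 5L    # strictly increasing gray mapping
  img2 <- gray_image(relab(unclass(img)), gray_levels = 512L)
  B1 <- global_segment(img2, relab(T0))
  expect_identical(B0, B1)
})

test_that("tiled local baseline segments a clean phantom correctly", {
  ph <- make_phantom(phantom_spec(noise_sigma = 0, bias_amplitude = 0))
  B <- tiled_segment(ph$image, tile_size = 48)
  expect_gte(dice(B, ph$tissue_mask), 0.95)
})
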