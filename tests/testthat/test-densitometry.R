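rgb_of_red <- function(red) {
  img <- array(0, c(nrow(red), ncol(red), 3))
  img[, , 1] <- red
  img
}

test_that("red-channel inversion is 255 - x and an involution", {
  white <- rgb_of_red(matrix(255, 4, 4))
  expect_true(all(red_channel_inverted(white) == 0))
  r100 <- rgb_of_red(matrix(100, 4, 4))
  expect_true(all(red_channel_inverted(r100) == 155))
  red <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  inv <- red_channel_inverted(rgb_of_red(red))
  expect_equal(255 - inv, red)
  expect_error(red_channel_inverted(matrix(0, 4, 4)), "RGB")
})

test_that("background subtraction flattens constants and keeps small disks", {
  expect_true(all(subtract_background(matrix(80, 40, 40), 10) == 0))
  flat <- matrix(50, 80, 80)
  img <- draw_disk(flat, 40, 40, 5, 50 + 120)
  out <- subtract_background(img, 15)  # ball radius 3x disk radius
  disk <- draw_disk(matrix(FALSE, 80, 80), 40, 40, 5, TRUE)
  expect_lt(max(abs(out[disk] - 120)), 1)
  expect_lt(max(out[!disk]), 1)
  expect_error(subtract_background(flat, 0), "radius")
})

test_that("a linear shading gradient is recovered away from the border", {
  bg <- matrix(rep(seq(60, 110, length.out = 100), each = 100), 100, 100)
  img <- bg
  for (k in 1:5) img <- draw_disk(img, 15 * k, 10 * k + 5, 4, 200)
  ball <- 12
  resid <- subtract_background(img, ball)
  interior <- matrix(FALSE, 100, 100)
  interior[(ball + 1):(100 - ball), (ball + 1):(100 - ball)] <- TRUE
  objs <- matrix(FALSE, 100, 100)
  for (k in 1:5) objs <- draw_disk(objs, 15 * k, 10 * k + 5, 5, TRUE)
  flat <- resid[interior & !objs]  # residual = img - bg estimate
  expect_lt(sqrt(mean(flat^2)), 2)
})

test_that("Otsu separates a clean bimodal image between the modes", {
  img <- matrix(c(rep(20, 500), rep(220, 500)), 25, 40)
  thr <- otsu_threshold(img)
  expect_gt(thr, 20)
  expect_lt(thr, 220)
  expect_equal(sum(img > thr), 500)
  expect_error(otsu_threshold(matrix(7, 5, 5)), "single intensity")
})

test_that("Otsu equals the brute-force between-class variance search", {
  set.seed(77)
  for (i in 1:10) {
    px <- sample(0:255, 900, replace = TRUE, prob = stats::runif(256)^2)
    img <- matrix(px, 30, 30)
    expect_equal(otsu_threshold(img), brute_force_otsu(img))
  }
})

test_that("adding a constant shifts the Otsu threshold by that constant", {
  set.seed(3)
  img <- matrix(sample(10:150, 400, replace = TRUE), 20, 20)
  expect_equal(otsu_threshold(img + 40), otsu_threshold(img) + 40)
})

test_that("disjoint disks are found with correct centroids", {
  fg <- matrix(FALSE, 60, 60)
  fg <- draw_disk(fg, 20, 15, 6, TRUE)
  fg <- draw_disk(fg, 42, 44, 6, TRUE)
  red <- matrix(200, 60, 60)
  seg <- segment_nuclei(fg, red, illumination = 200)
  expect_equal(nrow(seg$objects), 2)
  cent <- seg$objects[order(seg$objects$row), ]
  expect_equal(cent$row + 1, c(20, 42), tolerance = 0.1)  # 0-based coords
  expect_equal(cent$col + 1, c(15, 44), tolerance = 0.1)
})

test_that("touching disks are split and foreground pixels conserved", {
  fg <- matrix(FALSE, 60, 60)
  fg <- draw_disk(fg, 30, 25, 8, TRUE)
  fg <- draw_disk(fg, 30, 37, 8, TRUE)  # centres 1.5 radii apart
  seg <- segment_nuclei(fg, matrix(100, 60, 60), illumination = 200)
  expect_equal(nrow(seg$objects), 2)
  expect_equal(sum(seg$labels > 0), sum(fg))
})

test_that("an empty foreground yields an empty object table", {
  seg <- segment_nuclei(matrix(FALSE, 10, 10), matrix(0, 10, 10),
                        illumination = 200)
  expect_equal(nrow(seg$objects), 0)
})

test_that("the full ISH pipeline recovers planted object counts and OD", {
  sim <- generate_stained_image(30, illumination = 220, object_od = 0.5,
                                object_radius_px = 6, noise_sd = 2,
                                dim = c(256, 256), seed = 12)
  res <- quantify_ish(sim$image, ball_radius = 15)
  expect_equal(nrow(res$objects), 30)
  expect_equal(res$illumination, 220, tolerance = 2)
  expect_lt(abs(mean(res$objects$od) - 0.5), 0.05)
})

test_that("deliberately touching planted pairs are separated", {
  sim <- generate_stained_image(12, illumination = 220, object_od = 0.6,
                                object_radius_px = 7, noise_sd = 1,
                                dim = c(220, 220), touching_pairs = 2,
                                seed = 14)
  res <- quantify_ish(sim$image, ball_radius = 18)
  expect_equal(nrow(res$objects), 12)
})

test_that("absorbance density is the log10 intensity ratio", {
  expect_equal(absorbance_density(200, 200), 0)
  expect_equal(absorbance_density(25.5, 255), 1)
  expect_equal(absorbance_density(3 * 25.5, 3 * 255), 1)  # scale invariant
  expect_error(absorbance_density(0, 255), "positive")
})

test_that("pooled t-test matches the hand computation and its symmetries", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), 4),
               tolerance = 1e-10)
  expect_equal(round(r$p_value, 3), 0.021)
  swapped <- compare_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -r$statistic)
  expect_equal(swapped$p_value, r$p_value)
  same <- compare_groups(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_warning(deg <- compare_groups(c(1, 1), c(2, 2)), "degenerate|zero")
  expect_equal(deg$p_value, 0)
})

test_that("region and band quantifications are plain arithmetic contracts", {
  r <- region_specific_intensity(120, 40, "AVPV")
  expect_equal(r$specific_intensity, 80)
  expect_equal(region_specific_intensity(50, 50)$specific_intensity, 0)
  # cell-body over fiber intensity ratio (c = b / a)
  expect_equal(band_ratio(4, 2), 2)
  expect_equal(band_ratio(30, 60), 0.5)
  expect_equal(band_ratio(c(10, 20), c(10, 20)), c(1, 1))
  expect_equal(band_ratio(2 * c(10, 20), 2 * c(5, 40)),
               band_ratio(c(10, 20), c(5, 40)))
  expect_error(band_ratio(10, 0, sample = "s7"), "s7")
})
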