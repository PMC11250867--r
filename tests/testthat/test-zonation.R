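make_ramp <- function(nrow = 40, ncol = 160) {
  matrix(rep(seq_len(ncol) - 1, each = nrow), nrow = nrow)
}

test_that("a constant image profiles to a constant", {
  g <- matrix(37, 30, 80)
  ax <- polyline_axis(tibble::tibble(x = c(10, 70), y = c(15, 15)),
                      width_um = 8, pixel_size_um = 1)
  p <- axis_profile(g, ax)
  expect_true(all(p$value == 37))
  expect_true(all(diff(p$position) > 0))
})

test_that("a column ramp profiles to the analytic ramp", {
  g <- make_ramp()
  ax <- polyline_axis(tibble::tibble(x = c(10, 150), y = c(20, 20)),
                      width_um = 10, pixel_size_um = 1)
  p <- axis_profile(g, ax)
  expected <- 9 + p$position * 140  # value = column - 1 along the axis
  expect_lt(max(abs(p$value - expected)), 0.5)
})

test_that("profiles track a planted tissue gradient monotonically", {
  out <- render_scene(simulate_gradient_scene(od0 = 0.1, od1 = 0.8,
                                              width_px = 240, height_px = 80))
  gray <- to_inverted_gray(unmix_stains(rescale_brightness(out$image))$dab)
  ax <- polyline_axis(tibble::tibble(x = c(20, 220), y = c(40, 40)),
                      width_um = 13.7, pixel_size_um = 0.5)
  p <- axis_profile(gray, ax)
  g_true <- out$truth$gradient$g(p$position)
  expect_gte(cor(p$value, g_true, method = "spearman"), 0.99)
})

test_that("inserting collinear vertices barely changes the profile", {
  g <- make_ramp()
  ax1 <- polyline_axis(tibble::tibble(x = c(10, 150), y = c(20, 20)),
                       width_um = 10, pixel_size_um = 1)
  ax2 <- polyline_axis(tibble::tibble(x = c(10, 60, 100, 150),
                                      y = c(20, 20, 20, 20)),
                       width_um = 10, pixel_size_um = 1)
  p1 <- axis_profile(g, ax1)
  p2 <- axis_profile(g, ax2)
  v2 <- approx(p2$position, p2$value, xout = p1$position)$y
  expect_lt(max(abs(p1$value - v2)), 0.5)
})

test_that("axes leaving the image or degenerate widths are errors", {
  g <- make_ramp()
  expect_error(
    axis_profile(g, polyline_axis(tibble::tibble(x = c(-20, 50), y = c(20, 20)),
                                  width_um = 4, pixel_size_um = 1)),
    "exits the image"
  )
  expect_error(
    axis_profile(g, polyline_axis(tibble::tibble(x = c(10, 50), y = c(20, 20)),
                                  width_um = 0.4, pixel_size_um = 1)),
    "below 1 pixel"
  )
  expect_error(polyline_axis(tibble::tibble(x = 1, y = 1)), "2 vertices")
  expect_error(polyline_axis(tibble::tibble(x = c(1, 1), y = c(2, 2))),
               "zero length")
})

test_that("averaging resamples to a common grid and respects symmetry", {
  ramp_up <- tibble::tibble(position = seq(0, 1, length.out = 50),
                            value = seq(0, 100, length.out = 50))
  # one profile averages to itself
  one <- average_profiles(list(ramp_up), grid_n = 25)
  expect_equal(one$value, seq(0, 100, length.out = 25))
  # mirror ramps average to a constant
  ramp_dn <- tibble::tibble(position = ramp_up$position,
                            value = rev(ramp_up$value))
  both <- average_profiles(list(ramp_up, ramp_dn), grid_n = 30)
  expect_equal(both$value, rep(50, 30))
  # scaling all inputs commutes with averaging
  tripled <- average_profiles(list(
    dplyr::mutate(ramp_up, value = value * 3),
    dplyr::mutate(ramp_dn, value = value * 3)
  ), grid_n = 30)
  expect_equal(tripled$value, both$value * 3)
})

test_that("noisy replicate profiles average toward the clean ramp", {
  set.seed(14)
  base <- tibble::tibble(position = seq(0, 1, length.out = 60),
                         value = seq(20, 180, length.out = 60))
  noisy <- lapply(1:10, function(i) {
    dplyr::mutate(base, value = value + rnorm(60, 0, 5))
  })
  avg <- average_profiles(noisy, grid_n = 60)
  expect_lt(max(abs(avg$value - base$value)), 3 * 5 / sqrt(10))
})

test_that("LOWESS reproduces lines and constants and denoises a sine", {
  x <- seq(0, 1, length.out = 80)
  lin <- lowess_fit(x, 3 + 2 * x, span = 0.3)
  expect_lt(max(abs(lin$fitted - (3 + 2 * lin$position))), 1e-6)
  const <- lowess_fit(x, rep(5, 80), span = 0.5)
  expect_equal(const$fitted, rep(5, 80))

  set.seed(21)
  truth <- sin(2 * pi * seq(0, 1, length.out = 100))
  yobs <- truth + rnorm(100, 0, 0.1)
  fit <- lowess_fit(seq(0, 1, length.out = 100), yobs, span = 0.3)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(fit$fitted, truth), rmse(yobs, truth))

  expect_error(lowess_fit(x[1:5], x[1:5], span = 0.3), "at least 10")
  expect_error(lowess_fit(x, x, span = 0.02), "span too small")
})

test_that("per-position t tests match the closed form and edge cases", {
  pr <- function(v) tibble::tibble(position = c(0, 1), value = v)
  a <- list(pr(c(1, 2)), pr(c(1.1, 2.1)))
  b <- list(pr(c(3, 4)), pr(c(3.1, 4.1)))
  res <- compare_profiles(a, b, grid_n = 2)
  # hand-computed pooled-variance t on 4 numbers per position:
  # means 1.05 vs 3.05, pooled var 0.005 -> t = -2 / sqrt(0.005 * (1/2+1/2))
  expect_equal(res$t, rep(-2 / sqrt(0.005), 2))
  expect_equal(res$p, rep(2 * pt(-2 / sqrt(0.005), 2), 2))

  ident <- compare_profiles(a, a, grid_n = 5)
  expect_true(all(ident$t == 0) && all(ident$p == 1))

  shifted <- compare_profiles(
    list(pr(c(0, 0)), pr(c(1e-4, 1e-4)), pr(c(-1e-4, -1e-4))),
    list(pr(c(100, 100)), pr(c(100.0001, 100.0001)), pr(c(99.9999, 99.9999))),
    grid_n = 4
  )
  expect_true(all(shifted$p < 1e-6))

  const_diff <- compare_profiles(list(pr(c(0, 0)), pr(c(0, 0))),
                                 list(pr(c(1, 1)), pr(c(1, 1))), grid_n = 3)
  expect_true(all(const_diff$flag == "undefined"))
})

test_that("the zonate chain yields a monotone fit for a monotone gradient", {
  out <- render_scene(simulate_gradient_scene(od0 = 0.1, od1 = 0.8,
                                              width_px = 240, height_px = 80))
  axes <- lapply(seq(8, 72, length.out = 20), function(yy) {
    polyline_axis(tibble::tibble(x = c(16, 224), y = c(yy, yy)),
                  width_um = 6, pixel_size_um = 0.5)
  })
  z <- zonate(out$image, axes, span = 0.3)
  expect_true(all(diff(z$fit$fitted) >= -1e-9))
  expect_equal(glance(z)$n_axes, 20)
  expect_s3_class(ggplot2::autoplot(z), "ggplot")
  # pooled mode exposes the per-axis datapoints to the smoother
  zp <- zonate(out$image, axes[1:3], span = 0.3, pooled = TRUE)
  expect_gt(nrow(zp$fit), nrow(zp$mean_profile))
})
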