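test_that("blank cells contain no puncta and missing cells are an error", {
  labels <- matrix(0L, 30, 30)
  labels[5:25, 5:25] <- 1L
  flat <- matrix(40L, 30, 30)
  expect_equal(nrow(detect_puncta(flat, labels)), 0)
  expect_error(detect_puncta(flat, matrix(0L, 30, 30)), "no cells")
})

test_that("well-separated planted puncta are each found within a pixel", {
  sc <- simulate_puncta_scene(n_cells = 1, true_per_cell = 5,
                              decoys_per_cell = 0, seed = 12)
  gray <- to_inverted_gray(unmix_stains(sc$image)$dab)
  cand <- detect_puncta(gray, sc$truth$label_cells)
  acc <- filter_puncta(cand, gray, sc$truth$label_cells)
  truth <- sc$truth$puncta
  expect_equal(nrow(acc), 5)
  d <- vapply(seq_len(nrow(truth)), function(i) {
    min(sqrt((acc$x - truth$x[i])^2 + (acc$y - truth$y[i])^2))
  }, numeric(1))
  expect_lte(max(d), 1)
})

test_that("two merged puncta collapse to a single detection", {
  # dense evaluation: two Gaussians 1 px apart have a single DoG maximum
  labels <- matrix(1L, 40, 40)
  xs <- col(labels)
  ys <- row(labels)
  spot <- function(cx, cy) 150 * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * 1.5^2))
  gray <- round(20 + spot(20, 20) + spot(21, 20))
  out <- detect_puncta(gray, labels, floor = 5)
  near <- out[sqrt((out$x - 20.5)^2 + (out$y - 20)^2) < 4, ]
  expect_equal(nrow(near), 1)
})

test_that("the 2x-cell-mean filter is strict and applies per parent cell", {
  labels <- matrix(1L, 20, 20)
  gray <- matrix(30L, 20, 20)
  puncta <- tibble::tibble(x = c(5L, 15L), y = c(5L, 15L), sigma_px = 1.2,
                           dog_value = 10, mean_amplitude = c(50, 70),
                           cell = 1L)
  kept <- filter_puncta(puncta, gray, labels)
  expect_equal(kept$mean_amplitude, 70)   # cell mean 30: keep only > 60

  exact <- dplyr::mutate(puncta[1, ], mean_amplitude = 60)
  expect_equal(nrow(filter_puncta(exact, gray, labels)), 0)  # 2x exactly: reject
})

test_that("calibrated true/decoy amplitudes straddle the acceptance rule", {
  hits <- 0L
  total_true <- 0L
  false_accepts <- 0L
  for (s in 1:8) {
    sc <- simulate_puncta_scene(n_cells = 3, seed = 100 + s)
    gray <- to_inverted_gray(unmix_stains(sc$image)$dab)
    acc <- filter_puncta(detect_puncta(gray, sc$truth$label_cells),
                         gray, sc$truth$label_cells)
    truth <- sc$truth$puncta
    true_p <- truth[!truth$decoy, ]
    total_true <- total_true + nrow(true_p)
    if (nrow(true_p)) {
      hits <- hits + sum(vapply(seq_len(nrow(true_p)), function(i) {
        any(sqrt((acc$x - true_p$x[i])^2 + (acc$y - true_p$y[i])^2) <= 1)
      }, logical(1)))
    }
    false_accepts <- false_accepts + (nrow(acc) - sum(vapply(
      seq_len(nrow(acc)), function(k) {
        any(sqrt((true_p$x - acc$x[k])^2 + (true_p$y - acc$y[k])^2) <= 1)
      }, logical(1))))
  }
  expect_equal(hits, total_true)
  expect_equal(false_accepts, 0L)
})

test_that("summaries preserve counts and compute percentages", {
  labels <- matrix(0L, 10, 50)
  for (i in 1:10) labels[, (5 * i - 4):(5 * i)] <- i
  acc <- tibble::tibble(x = c(3L, 8L, 13L), y = c(5L, 5L, 5L),
                        cell = c(1L, 2L, 2L))
  s <- summarize_puncta(acc, labels)
  expect_equal(s$n_cells, 10)
  expect_equal(s$percent_with_puncta, 20)
  expect_equal(sum(s$cells$n_puncta), nrow(acc))

  none <- summarize_puncta(acc[0, ], labels)
  expect_equal(none$percent_with_puncta, 0)
  expect_true(all(none$cells$n_puncta == 0))
})

test_that("planted per-cell counts are recovered as an exact multiset", {
  sc <- simulate_puncta_scene(n_cells = 5, true_per_cell = c(0, 0, 1, 2, 5),
                              decoys_per_cell = 0, seed = 9)
  gray <- to_inverted_gray(unmix_stains(sc$image)$dab)
  acc <- filter_puncta(detect_puncta(gray, sc$truth$label_cells),
                       gray, sc$truth$label_cells)
  s <- summarize_puncta(acc, sc$truth$label_cells)
  expect_equal(sort(s$cells$n_puncta), c(0, 0, 1, 2, 5))
})

test_that("per-100-cell rates aggregate by region and flag empty regions", {
  labels <- matrix(0L, 10, 50)
  for (i in 1:10) labels[, (5 * i - 4):(5 * i)] <- i
  acc <- tibble::tibble(cell = c(1L, rep(2L, 3)))   # 4 puncta
  mapping <- tibble::tibble(cell = 1:10,
                            region = rep(c(1L, 2L), each = 5))
  r <- puncta_per_100_cells(acc, labels, mapping)
  expect_equal(r$per_100_cells, c(80, 0))

  # region label image route, including a region with no cells
  regions <- matrix(3L, 10, 50)
  regions[, 1:25] <- 1L
  regions[1, 50] <- 2L  # tiny region not covering any full cell majority
  r2 <- puncta_per_100_cells(acc, labels, regions)
  expect_equal(r2$per_100_cells[r2$region == 1], 80)
  expect_true(is.na(r2$per_100_cells[r2$region == 2]))
  expect_equal(r2$flag[r2$region == 2], "no-cells")
})

test_that("adding a constant offset never increases the accepted count", {
  sc <- simulate_puncta_scene(n_cells = 3, seed = 42)
  gray <- to_inverted_gray(unmix_stains(sc$image)$dab)
  n_at <- vapply(c(0, 20, 60, 120), function(b) {
    g <- pmin(gray + b, 255)
    nrow(filter_puncta(detect_puncta(g, sc$truth$label_cells),
                       g, sc$truth$label_cells))
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})
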