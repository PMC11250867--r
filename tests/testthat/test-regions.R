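test_that("well-separated planted nuclei are all recovered with sub-pixel centroids", {
  out <- render_scene(simulate_nuclei_scene(15, 15, seed = 3))
  gray <- to_inverted_gray(unmix_stains(out$image)$hematoxylin)
  nuc <- segment_nuclei(gray, 0.5)
  truth <- out$truth$nuclei
  expect_equal(nrow(nuc), 30)
  idx <- vapply(seq_len(nrow(nuc)), function(i) {
    which.min((truth$x - nuc$x[i])^2 + (truth$y - nuc$y[i])^2)
  }, integer(1))
  expect_equal(sort(idx), 1:30)  # one-to-one match
  expect_lt(max(sqrt((truth$x[idx] - nuc$x)^2 + (truth$y[idx] - nuc$y)^2)), 1)
  # object count/area equal a brute-force flood fill via the label image
  labels <- attr(nuc, "labels")
  expect_equal(sort(unique(as.vector(labels[labels > 0]))), nuc$label)
  areas_px <- vapply(nuc$label, function(l) sum(labels == l), integer(1))
  expect_equal(nuc$area_um2, areas_px * 0.5^2)
})

test_that("a rasterized disk scores near-unit circularity", {
  g <- matrix(0L, 60, 60)
  g[(col(g) - 30)^2 + (row(g) - 30)^2 <= 400] <- 200L
  d <- segment_nuclei(g, 1)
  expect_equal(nrow(d), 1)
  expect_gte(d$circularity, 0.95)
  expect_lte(d$circularity, 1)
})

test_that("blank images give an empty record set, not an error", {
  empty <- segment_nuclei(matrix(0L, 20, 20), 0.5)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(classify_nuclei(empty)), 0)
})

test_that("morphometric classification follows the inclusive boundary rule", {
  recs <- tibble::tibble(
    label = 1:4,
    x = 0, y = 0,
    area_um2 = c(40, 39.9, 80, 20),
    perimeter_um = 1,
    circularity = c(0.8, 0.79, 0.95, 0.5)
  )
  cls <- classify_nuclei(recs, area_cut_um2 = 40, circ_cut = 0.8)
  expect_equal(cls$class, c("hepatocyte", "kupffer", "hepatocyte", "kupffer"))
  mixed <- classify_nuclei(dplyr::mutate(recs, circularity = c(0.9, 0.9, 0.5, 0.5)))
  expect_equal(mixed$class, c("hepatocyte", "other", "other", "kupffer"))
})

test_that("planted populations classify with full accuracy", {
  for (s in c(3, 9)) {
    out <- render_scene(simulate_nuclei_scene(10, 10, seed = s))
    gray <- to_inverted_gray(unmix_stains(out$image)$hematoxylin)
    nuc <- classify_nuclei(segment_nuclei(gray, 0.5))
    truth <- out$truth$nuclei
    idx <- vapply(seq_len(nrow(nuc)), function(i) {
      which.min((truth$x - nuc$x[i])^2 + (truth$y - nuc$y[i])^2)
    }, integer(1))
    expect_equal(nuc$class, truth$class[idx])
  }
})

test_that("cytosolic rings measure uniform fields exactly and rank planted ODs", {
  out <- render_scene(simulate_nuclei_scene(6, 6, seed = 4))
  gray_h <- to_inverted_gray(unmix_stains(out$image)$hematoxylin)
  nuc <- segment_nuclei(gray_h, 0.5)
  flat <- matrix(88, nrow(gray_h), ncol(gray_h))
  cs <- cytosolic_signal(flat, nuc, ring_um = 1.5)
  expect_true(all(cs$mean_signal == 88))
  expect_true(all(is.na(cs$flag)))

  # per-cell planted ODs: measured means must rank exactly as planted
  ods <- seq(0.1, 0.9, length.out = 12)
  spec <- simulate_nuclei_scene(6, 6, seed = 4, cyto_ods = ods)
  out2 <- render_scene(spec)
  ch <- unmix_stains(out2$image)
  nuc2 <- segment_nuclei(to_inverted_gray(ch$hematoxylin), 0.5)
  cs2 <- cytosolic_signal(to_inverted_gray(ch$dab), nuc2, ring_um = 1)
  truth <- out2$truth$nuclei
  idx <- vapply(seq_len(nrow(nuc2)), function(i) {
    which.min((truth$x - nuc2$x[i])^2 + (truth$y - nuc2$y[i])^2)
  }, integer(1))
  expect_equal(cor(cs2$mean_signal, truth$planted_dab_od[idx],
                   method = "spearman"), 1)
})

test_that("disjoint rings are unaffected by a neighbour's planted OD", {
  base_ods <- c(0.2, 0.6, 0.4, 0.3, 0.5, 0.7, 0.25, 0.45, 0.35, 0.55, 0.65, 0.15)
  pert_ods <- base_ods
  pert_ods[2] <- 0.9  # perturb one cell only
  measure <- function(ods) {
    out <- render_scene(simulate_nuclei_scene(6, 6, seed = 4, cyto_ods = ods))
    ch <- unmix_stains(out$image)
    nuc <- segment_nuclei(to_inverted_gray(ch$hematoxylin), 0.5)
    list(sig = cytosolic_signal(to_inverted_gray(ch$dab), nuc, ring_um = 1),
         nuc = nuc, truth = out$truth$nuclei)
  }
  a <- measure(base_ods)
  b <- measure(pert_ods)
  idx <- vapply(seq_len(nrow(a$nuc)), function(i) {
    which.min((a$truth$x - a$nuc$x[i])^2 + (a$truth$y - a$nuc$y[i])^2)
  }, integer(1))
  untouched <- idx != 2
  expect_equal(a$sig$mean_signal[untouched], b$sig$mean_signal[untouched])
  expect_gt(b$sig$mean_signal[!untouched], a$sig$mean_signal[!untouched])
})

test_that("endothelial bands rank planted vessel ODs and flag empty seeds", {
  sim <- simulate_vessel_scene(c(0.6, 0.1, 0), seed = 2)
  out <- render_scene(sim$spec)
  ch <- unmix_stains(out$image)
  ve <- vessel_endothelium(to_inverted_gray(ch$hematoxylin),
                           to_inverted_gray(ch$dab), sim$seeds,
                           pixel_size_um = 0.5)
  expect_true(all(is.na(ve$flag)))
  expect_true(ve$mean_signal[1] > ve$mean_signal[2])
  expect_true(ve$mean_signal[2] > ve$mean_signal[3])
  # zero planted endothelial OD stays at background level
  bg_gray <- 255 - round(255 * 10^-0.01)
  expect_lte(ve$mean_signal[3], bg_gray + 2)

  # a seed box with no stain is flagged and skipped
  blank <- vessel_endothelium(matrix(0L, 40, 40), matrix(0L, 40, 40),
                              tibble::tibble(x = 20, y = 20, half_px = 15),
                              pixel_size_um = 0.5)
  expect_false(is.na(blank$flag))
})

test_that("percent area counts windows exactly", {
  gray <- matrix(0L, 10, 20)
  gray[1:5, 1:10] <- 100L
  region <- matrix(TRUE, 10, 20)
  pa <- percent_area(gray, region)
  expect_equal(pa$percent_area, 25)
  expect_equal(percent_area(matrix(255L, 4, 4), matrix(TRUE, 4, 4))$percent_area,
               100)
  expect_error(percent_area(gray, matrix(FALSE, 10, 20)), "empty")
})

test_that("measures are invariant to image translation", {
  out <- render_scene(simulate_nuclei_scene(4, 4, seed = 6))
  gray <- to_inverted_gray(unmix_stains(out$image)$hematoxylin)
  pad <- matrix(0L, nrow(gray) + 10, ncol(gray) + 10)
  pad[6:(5 + nrow(gray)), 4:(3 + ncol(gray))] <- gray
  a <- segment_nuclei(gray, 0.5)
  b <- segment_nuclei(pad, 0.5)
  expect_equal(sort(a$area_um2), sort(b$area_um2))
  expect_equal(sort(a$circularity), sort(b$circularity))
  expect_equal(nrow(a), nrow(b))
})
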