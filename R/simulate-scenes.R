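#' Synthetic scene presets
#'
#' Ready-made [scene_spec()] builders that emulate the tissue
#' configurations the quantification modules are designed for: fields of
#' hepatocyte-like and Kupffer-like nuclei, tissue-axis DAB gradients,
#' vessel cross-sections, puncta-bearing cells and percent-area regions.
#' All randomness is driven by a single integer seed; the same seed
#' always yields a bit-identical scene.
#'
#' @name simulate_scenes
NULL

# deterministic jittered grid of object centers
grid_centers <- function(n, spacing_px, margin_px, jitter_px, seed) {
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  local_seeded(seed, {
    g <- tidyr::expand_grid(gy = seq_len(nrow_g), gx = seq_len(ncol_g))[seq_len(n), ]
    tibble::tibble(
      x = margin_px + (g$gx - 1) * spacing_px +
        stats::runif(n, -jitter_px, jitter_px),
      y = margin_px + (g$gy - 1) * spacing_px +
        stats::runif(n, -jitter_px, jitter_px),
      width_px = ceiling(margin_px * 2 + (ncol_g - 1) * spacing_px),
      height_px = ceiling(margin_px * 2 + (nrow_g - 1) * spacing_px)
    )
  })
}

#' @describeIn simulate_scenes Field of hepatocyte-like (large, round)
#'   and Kupffer-like (small, elongated) nuclei with optional per-cell
#'   cytoplasmic DAB.
#' @param n_hepatocyte,n_kupffer Numbers of nuclei of each class.
#' @param pixel_size_um Pixel size in micrometres.
#' @param hema_od Nuclear hematoxylin OD.
#' @param cyto_ods Optional per-nucleus cytoplasmic DAB ODs (length
#'   `n_hepatocyte + n_kupffer`); `NULL` plants no cytoplasmic signal.
#' @param seed Integer seed.
#' @return A `scene_spec`.
#' @export
simulate_nuclei_scene <- function(n_hepatocyte = 15, n_kupffer = 15,
                                  pixel_size_um = 0.5, hema_od = 0.8,
                                  cyto_ods = NULL, seed = 1L) {
  n <- n_hepatocyte + n_kupffer
  hep_r_um <- 4.5    # ~9 um diameter, round
  kup_r_um <- 1.73   # 2 x 6 um ellipse, geometric-mean radius
  spacing <- ceiling(2 * 2.2 * hep_r_um / pixel_size_um) + 8
  centers <- grid_centers(n, spacing, spacing / 2 + 4, 3, seed)
  cls <- local_seeded(seed + 1L, sample(rep(c("hepatocyte", "kupffer"),
                                            c(n_hepatocyte, n_kupffer))))
  angles <- local_seeded(seed + 2L, stats::runif(n, 0, pi))
  nuclei <- tibble::tibble(
    x = centers$x, y = centers$y,
    radius_um = ifelse(cls == "hepatocyte", hep_r_um, kup_r_um),
    eccentricity = ifelse(cls == "hepatocyte", 0, 0.943),
    angle = angles,
    hematoxylin_od = hema_od,
    class = cls,
    cell_radius_um = 2.2 * hep_r_um
  )
  cytoplasm <- cyto_constant(0)
  if (!is.null(cyto_ods)) {
    stopifnot(length(cyto_ods) == n)
    nuclei$cyto_od <- cyto_ods
    cytoplasm <- cyto_per_cell()
  }
  scene_spec(centers$width_px[1], centers$height_px[1],
             pixel_size_um = pixel_size_um, seed = seed,
             nuclei = nuclei, cytoplasm = cytoplasm)
}

#' @describeIn simulate_scenes Tissue with a linear DAB gradient along
#'   an axis (zonation-style), no discrete objects.
#' @param width_px,height_px Image size.
#' @param od0,od1 DAB OD at the start and end of the axis.
#' @param angle Gradient direction in radians (0 = along x).
#' @param noise_sd Additive intensity noise SD (8-bit units).
#' @export
simulate_gradient_scene <- function(width_px = 240, height_px = 120,
                                    od0 = 0.1, od1 = 0.9, angle = 0,
                                    pixel_size_um = 0.5, noise_sd = 0,
                                    seed = 1L) {
  scene_spec(width_px, height_px, pixel_size_um = pixel_size_um, seed = seed,
             cytoplasm = cyto_gradient(od0, od1, angle = angle),
             noise_sd = noise_sd)
}

#' @describeIn simulate_scenes Wild-type/knockout validation scene:
#'   counterstained nuclei with a uniform cytoplasmic DAB of amplitude
#'   `specific_od`, matched knockout obtained via [make_wt_ko_pair()].
#' @param specific_od Target-specific cytoplasmic DAB OD.
#' @param n_nuclei Number of nuclei.
#' @export
simulate_snr_scene <- function(specific_od = 0.5, n_nuclei = 25,
                               pixel_size_um = 0.5, seed = 1L) {
  r_um <- 3.5
  spacing <- ceiling(2 * 2.2 * r_um / pixel_size_um) + 6
  centers <- grid_centers(n_nuclei, spacing, spacing / 2 + 2, 2, seed)
  nuclei <- tibble::tibble(
    x = centers$x, y = centers$y, radius_um = r_um, eccentricity = 0,
    angle = 0, hematoxylin_od = 0.7, class = "other",
    cell_radius_um = 2.2 * r_um
  )
  scene_spec(centers$width_px[1], centers$height_px[1],
             pixel_size_um = pixel_size_um, seed = seed, nuclei = nuclei,
             cytoplasm = cyto_constant(specific_od))
}

#' @describeIn simulate_scenes Vessel cross-sections: SMA-like rings
#'   with an interior endothelial DAB band, one planted endothelial OD
#'   per vessel. Also returns per-vessel seed boxes for
#'   [vessel_endothelium()].
#' @param endothelial_ods Vector of planted endothelial DAB ODs, one
#'   vessel each.
#' @param ring_od SMA ring OD.
#' @return For the vessel preset, a list with `spec` and `seeds`
#'   (tibble `x`, `y`, `half_px`).
#' @export
simulate_vessel_scene <- function(endothelial_ods = c(0.6, 0.1),
                                  ring_od = 0.8, pixel_size_um = 0.5,
                                  seed = 1L) {
  n <- length(endothelial_ods)
  r_outer_um <- 10
  spacing <- ceiling(2 * r_outer_um / pixel_size_um) + 16
  centers <- grid_centers(n, spacing, spacing / 2 + 4, 2, seed)
  vessels <- tibble::tibble(
    x = centers$x, y = centers$y, r_inner_um = 7, r_outer_um = r_outer_um,
    ring_od = ring_od, endothelial_dab_od = endothelial_ods,
    endo_band_um = 2
  )
  spec <- scene_spec(centers$width_px[1], centers$height_px[1],
                     pixel_size_um = pixel_size_um, seed = seed,
                     vessels = vessels)
  list(spec = spec,
       seeds = tibble::tibble(x = centers$x, y = centers$y,
                              half_px = ceiling(r_outer_um / pixel_size_um) + 4))
}

#' @describeIn simulate_scenes Puncta benchmark: cells with a uniform
#'   cytoplasmic DAB base and planted puncta whose mean footprint
#'   amplitude is calibrated to a stated multiple of the cell's mean
#'   signal — true puncta at `ratio_true`, decoys at `ratio_decoy` —
#'   straddling the 2x-of-cell-mean acceptance rule. Returns the
#'   rendered scene with the punctum table annotated with `decoy` and
#'   the realized amplitude ratios.
#' @param n_cells Number of cells (grid layout).
#' @param true_per_cell,decoys_per_cell Integer vectors (recycled) of
#'   planted true puncta and decoy counts per cell; `NULL` samples
#'   0-3 true and 0-2 decoys per cell from the seed.
#' @param ratio_true,ratio_decoy Planted mean-amplitude to cell-mean
#'   ratios.
#' @param base_od Cytoplasmic DAB base OD.
#' @param sigma_um Planted punctum Gaussian sigma.
#' @export
simulate_puncta_scene <- function(n_cells = 4, true_per_cell = NULL,
                                  decoys_per_cell = NULL, ratio_true = 3,
                                  ratio_decoy = 1.5, base_od = 0.12,
                                  sigma_um = 0.75, pixel_size_um = 0.5,
                                  seed = 1L) {
  cell_r_um <- 11
  nuc_r_um <- 2
  spacing <- ceiling(2 * cell_r_um / pixel_size_um) + 6
  centers <- grid_centers(n_cells, spacing, spacing / 2 + 2, 2, seed)
  nuclei <- tibble::tibble(
    x = centers$x, y = centers$y, radius_um = nuc_r_um, eccentricity = 0,
    angle = 0, hematoxylin_od = 0.6, class = "other",
    cell_radius_um = cell_r_um
  )
  counts <- local_seeded(seed + 3L, {
    list(
      true = if (is.null(true_per_cell)) sample(0:3, n_cells, replace = TRUE)
             else rep_len(true_per_cell, n_cells),
      decoy = if (is.null(decoys_per_cell)) sample(0:2, n_cells, replace = TRUE)
              else rep_len(decoys_per_cell, n_cells)
    )
  })
  sigma_px <- sigma_um / pixel_size_um
  min_sep <- 4 * (2 * 1.2) + 1   # >= 4 sigma_large of the default detector
  pts <- place_puncta(centers, counts, nuc_r_um / pixel_size_um,
                      cell_r_um / pixel_size_um, min_sep, seed + 4L)
  if (nrow(pts) == 0L) {
    spec <- scene_spec(centers$width_px[1], centers$height_px[1],
                       pixel_size_um = pixel_size_um, seed = seed,
                       nuclei = nuclei, cytoplasm = cyto_constant(base_od))
    out <- render_scene(spec)
    out$truth$puncta$decoy <- logical()
    out$spec <- spec
    return(out)
  }
  pts$ratio <- ifelse(pts$decoy, ratio_decoy, ratio_true)
  pts$sigma_um <- sigma_um
  build <- function(peaks) {
    p <- tibble::tibble(x = pts$x, y = pts$y, sigma_um = sigma_um,
                       peak_dab_od = peaks, parent = pts$parent,
                       decoy = pts$decoy)
    scene_spec(centers$width_px[1], centers$height_px[1],
               pixel_size_um = pixel_size_um, seed = seed, nuclei = nuclei,
               cytoplasm = cyto_constant(base_od), puncta = p)
  }
  # calibrate peak ODs so footprint mean gray = ratio * cell mean gray;
  # two fixed-point passes (puncta feed back into the cell mean slightly)
  peaks <- rep(0.4, nrow(pts))
  for (pass in 1:2) {
    sc <- render_scene(build(peaks))
    gray <- to_inverted_gray(sc$truth$od_dab)
    cell_means <- vapply(seq_len(n_cells), function(i) {
      mean(gray[sc$truth$label_cells == i])
    }, numeric(1))
    peaks <- vapply(seq_len(nrow(pts)), function(i) {
      solve_peak_od(base_od, sigma_px,
                    target_gray = pts$ratio[i] * cell_means[pts$parent[i]],
                    footprint_r = 2 * 1.2)
    }, numeric(1))
  }
  spec <- build(peaks)
  out <- render_scene(spec)
  out$truth$puncta$decoy <- pts$decoy
  out$truth$puncta$target_ratio <- pts$ratio
  out$spec <- spec
  out
}

# rejection-sample punctum positions inside cytoplasm with min spacing
place_puncta <- function(centers, counts, nuc_r_px, cell_r_px, min_sep, seed) {
  local_seeded(seed, {
    rows <- list()
    placed <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(centers))) {
      n_i <- counts$true[i] + counts$decoy[i]
      decoy_i <- rep(c(FALSE, TRUE), c(counts$true[i], counts$decoy[i]))
      k <- 0L
      tries <- 0L
      while (k < n_i && tries < 500L) {
        tries <- tries + 1L
        r <- stats::runif(1, nuc_r_px + 4, cell_r_px - 5)
        th <- stats::runif(1, 0, 2 * pi)
        x <- round(centers$x[i] + r * cos(th))
        y <- round(centers$y[i] + r * sin(th))
        if (sqrt((x - centers$x[i])^2 + (y - centers$y[i])^2) <= nuc_r_px + 3) next
        if (nrow(placed) &&
            min(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2)) < min_sep) next
        k <- k + 1L
        placed <- rbind(placed, c(x, y))
        rows[[length(rows) + 1L]] <-
          tibble::tibble(x = x, y = y, parent = i, decoy = decoy_i[k])
      }
      if (k < n_i) stop("could not place puncta with required spacing", call. = FALSE)
    }
    if (!length(rows)) tibble::tibble(x = numeric(), y = numeric(),
                                      parent = integer(), decoy = logical())
    else dplyr::bind_rows(rows)
  })
}

# peak OD such that mean inverted gray over the detection footprint
# (disk of radius footprint_r px) hits target_gray on a base_od bed
solve_peak_od <- function(base_od, sigma_px, target_gray, footprint_r) {
  d <- seq(-ceiling(footprint_r), ceiling(footprint_r))
  off <- tidyr::expand_grid(dx = d, dy = d)
  off <- off[off$dx^2 + off$dy^2 <= footprint_r^2, ]
  g2 <- exp(-(off$dx^2 + off$dy^2) / (2 * sigma_px^2))
  f <- function(p) {
    mean(255 - round(255 * 10^(-pmin(base_od + p * g2, 3)))) - target_gray
  }
  if (f(3) < 0) return(3)
  stats::uniroot(f, c(0, 3), tol = 1e-4)$root
}

#' @describeIn simulate_scenes Percent-area region: a circular
#'   "white-pulp" region containing high-DAB blobs covering
#'   approximately `target_percent` of its area; the exact planted
#'   fraction is available through [planted_percent_area()]. Returns
#'   the rendered scene plus `region_mask`.
#' @param target_percent Planted supra-threshold percent of the region.
#' @param blob_od DAB OD inside blobs.
#' @export
simulate_area_scene <- function(target_percent = 7.5, blob_od = 0.5,
                                pixel_size_um = 0.5, seed = 1L) {
  w <- 200L
  h <- 200L
  region_r <- 90
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  region <- (xs - (w + 1) / 2)^2 + (ys - (h + 1) / 2)^2 <= region_r^2
  blob_r <- 7
  n_blobs <- floor(target_percent / 100 * sum(region) / (pi * blob_r^2))
  blobs <- local_seeded(seed, {
    placed <- matrix(numeric(0), ncol = 2)
    while (nrow(placed) < n_blobs) {
      x <- stats::runif(1, 1, w)
      y <- stats::runif(1, 1, h)
      if ((x - (w + 1) / 2)^2 + (y - (h + 1) / 2)^2 > (region_r - blob_r - 2)^2) next
      if (nrow(placed) &&
          min(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2)) < 2 * blob_r + 3) next
      placed <- rbind(placed, c(x, y))
    }
    placed
  })
  blob_field <- matrix(0, h, w)
  for (i in seq_len(nrow(blobs))) {
    blob_field[(xs - blobs[i, 1])^2 + (ys - blobs[i, 2])^2 <= blob_r^2] <- blob_od
  }
  # assemble via the standard mixing path so the render contract holds
  bg <- c(0.02, 0.01)
  a_d <- bg[2] + blob_field
  a_h <- matrix(bg[1], h, w)
  image <- mix_to_rgb(a_h, a_d, stain_matrix_hdab())
  truth <- structure(
    list(nuclei = tibble::tibble(), puncta = tibble::tibble(),
         vessels = tibble::tibble(), label_nuclei = matrix(0L, h, w),
         label_cells = matrix(0L, h, w), vessel_masks = list(),
         od_hematoxylin = a_h, od_dab = a_d, gradient = NULL,
         pixel_size_um = pixel_size_um, knockout = FALSE),
    class = "scene_truth"
  )
  list(image = image, truth = truth, region_mask = region)
}
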