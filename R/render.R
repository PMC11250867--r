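#' Render a synthetic scene to an 8-bit RGB image with ground truth
#'
#' Accumulates the planted per-stain OD fields, mixes them through the
#' Beer-Lambert model with the H-DAB stain matrix
#' (`I_c = round(255 * 10^(-(M A)_c))`, clipped to `[0, 255]`, OD
#' clamped at 3) and quantizes once to 8-bit. The returned ground truth
#' records every planted object, the nucleus and cell label images, the
#' axis gradient, and the planted OD fields themselves.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (height x width x 3 array in
#'   `[0, 255]`) and `truth` (class `scene_truth`: tibbles `nuclei`,
#'   `puncta`, `vessels`; matrices `label_nuclei`, `label_cells`;
#'   list `vessel_masks`; planted OD matrices `od_hematoxylin`,
#'   `od_dab`; gradient description `gradient`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  validate_scene_spec(spec)
  w <- spec$width_px
  h <- spec$height_px
  px <- spec$pixel_size_um
  xs <- matrix(rep(seq_len(w), each = h), nrow = h)   # column index
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)  # row index

  nuc <- spec$nuclei
  n_nuc <- nrow(nuc)
  label_nuclei <- matrix(0L, h, w)
  a_h <- matrix(spec$background_od[1], h, w)
  a_d <- matrix(spec$background_od[2], h, w)

  # nuclei: rotated ellipses carrying the hematoxylin counterstain
  for (i in seq_len(n_nuc)) {
    ax <- semi_axes(nuc$radius_um[i] / px, nuc$eccentricity[i])
    dx <- xs - nuc$x[i]
    dy <- ys - nuc$y[i]
    u <- dx * cos(nuc$angle[i]) + dy * sin(nuc$angle[i])
    v <- -dx * sin(nuc$angle[i]) + dy * cos(nuc$angle[i])
    inside <- (u / ax$a)^2 + (v / ax$b)^2 <= 1
    label_nuclei[inside] <- i
    a_h[inside] <- a_h[inside] + nuc$hematoxylin_od[i]
  }

  # cell bodies: disks around nuclei, overlaps resolved to nearest center
  label_cells <- matrix(0L, h, w)
  if (n_nuc) {
    best_d2 <- matrix(Inf, h, w)
    for (i in seq_len(n_nuc)) {
      d2 <- (xs - nuc$x[i])^2 + (ys - nuc$y[i])^2
      r2 <- (nuc$cell_radius_um[i] / px)^2
      take <- d2 <= r2 & d2 < best_d2
      label_cells[take] <- i
      best_d2[take] <- d2[take]
    }
  }
  cyto_region <- label_cells > 0L & label_nuclei == 0L

  # cytoplasmic DAB field
  cy <- spec$cytoplasm
  cyto_field <- matrix(0, h, w)
  if (cy$mode == "constant") {
    cyto_field[] <- cy$od
  } else if (cy$mode == "gradient") {
    t_axis <- gradient_position(xs, ys, cy$angle, w, h)
    cyto_field <- cy$od0 + (cy$od1 - cy$od0) * t_axis
  } else if (cy$mode == "per_cell") {
    if (n_nuc) cyto_field[] <- c(0, nuc$cyto_od)[label_cells + 1L]
  }
  extent_mask <- if (identical(cy$extent, "tissue")) TRUE else cyto_region
  cyto_applied <- cyto_field * (if (isTRUE(extent_mask)) 1 else extent_mask)

  # puncta: isotropic Gaussians in OD space, truncated at 4 sigma
  puncta_field <- matrix(0, h, w)
  pa <- spec$puncta
  for (i in seq_len(nrow(pa))) {
    s <- pa$sigma_um[i] / px
    d2 <- (xs - pa$x[i])^2 + (ys - pa$y[i])^2
    g <- pa$peak_dab_od[i] * exp(-d2 / (2 * s^2))
    g[d2 > (4 * s)^2] <- 0
    puncta_field <- puncta_field + g
  }

  # vessels: SMA-like ring on the hematoxylin vector, endothelial DAB band
  ves <- spec$vessels
  vessel_masks <- vector("list", nrow(ves))
  endo_field <- matrix(0, h, w)
  for (i in seq_len(nrow(ves))) {
    d <- sqrt((xs - ves$x[i])^2 + (ys - ves$y[i])^2)
    ring <- d >= ves$r_inner_um[i] / px & d <= ves$r_outer_um[i] / px
    band <- d < ves$r_inner_um[i] / px &
      d >= (ves$r_inner_um[i] - ves$endo_band_um[i]) / px
    a_h[ring] <- a_h[ring] + ves$ring_od[i]
    endo_field[band] <- endo_field[band] + ves$endothelial_dab_od[i]
    vessel_masks[[i]] <- list(ring = ring, endothelium = band)
  }

  specific <- cyto_applied + puncta_field + endo_field
  if (!spec$knockout) a_d <- a_d + specific

  stains <- stain_matrix_hdab()
  image <- mix_to_rgb(a_h, a_d, stains)

  if (spec$noise_sd > 0) {
    image <- local_seeded(spec$seed, {
      pmin(pmax(round(image + stats::rnorm(length(image), 0, spec$noise_sd)), 0), 255)
    })
    image <- array(image, dim = c(h, w, 3L))
  }

  truth <- structure(
    list(
      nuclei = dplyr::mutate(
        nuc,
        label = dplyr::row_number(),
        planted_dab_od = planted_cell_dab(nuc, cy, w, h)
      ),
      puncta = planted_puncta_truth(pa, px),
      vessels = ves,
      label_nuclei = label_nuclei,
      label_cells = label_cells,
      vessel_masks = vessel_masks,
      od_hematoxylin = a_h,
      od_dab = a_d,
      gradient = if (cy$mode == "gradient") {
        list(od0 = cy$od0, od1 = cy$od1, angle = cy$angle,
             g = function(t) cy$od0 + (cy$od1 - cy$od0) * t)
      } else NULL,
      pixel_size_um = px,
      knockout = spec$knockout
    ),
    class = "scene_truth"
  )
  list(image = image, truth = truth)
}

# normalized [0,1] projection of pixel coords along a direction
gradient_position <- function(xs, ys, angle, w, h) {
  proj <- xs * cos(angle) + ys * sin(angle)
  corners_x <- c(1, w, 1, w)
  corners_y <- c(1, 1, h, h)
  p <- corners_x * cos(angle) + corners_y * sin(angle)
  (proj - min(p)) / (max(p) - min(p))
}

planted_cell_dab <- function(nuc, cy, w, h) {
  if (!nrow(nuc)) return(numeric())
  switch(cy$mode,
    constant = rep(cy$od, nrow(nuc)),
    per_cell = nuc$cyto_od,
    gradient = {
      t0 <- gradient_position(matrix(nuc$x), matrix(nuc$y), cy$angle, w, h)
      as.numeric(cy$od0 + (cy$od1 - cy$od0) * t0)
    }
  )
}

planted_puncta_truth <- function(pa, px) {
  if (!nrow(pa)) {
    return(tibble::tibble(x = numeric(), y = numeric(), sigma_px = numeric(),
                          peak_dab_od = numeric(), parent = integer()))
  }
  tibble::tibble(x = pa$x, y = pa$y, sigma_px = pa$sigma_um / px,
                 peak_dab_od = pa$peak_dab_od, parent = as.integer(pa$parent))
}

# Beer-Lambert mixing of stain OD fields through a stain matrix
mix_to_rgb <- function(a_h, a_d, stains, a_r = 0) {
  h <- nrow(a_h)
  w <- ncol(a_h)
  conc <- cbind(as.vector(a_h), as.vector(a_d), as.vector(a_r * (a_h * 0 + 1)))
  od <- pmin(conc %*% t(stains), 3)
  img <- pmin(pmax(round(255 * 10^(-od)), 0), 255)
  array(img, dim = c(h, w, 3L))
}

#' Render raw OD fields to an 8-bit RGB image
#'
#' Low-level counterpart of [render_scene()]: mixes given per-stain OD
#' matrices directly through the Beer-Lambert model
#' (`I_c = round(255 * 10^(-(M A)_c))`, OD clamped at 3, intensities
#' clipped to `[0, 255]`) without any scene geometry. Useful for
#' round-trip checks of the unmixing contract.
#'
#' @param od_hematoxylin,od_dab Nonnegative OD matrices of equal shape.
#' @param od_residual Residual-stain OD (matrix or scalar, default 0).
#' @param stains Stain matrix.
#' @return RGB array (`height x width x 3`).
#' @export
render_od_fields <- function(od_hematoxylin, od_dab, od_residual = 0,
                             stains = stain_matrix_hdab()) {
  stopifnot(is.matrix(od_hematoxylin), all(dim(od_hematoxylin) == dim(od_dab)))
  if (min(od_hematoxylin) < 0 || min(od_dab) < 0 || min(od_residual) < 0) {
    stop("OD fields must be nonnegative", call. = FALSE)
  }
  mix_to_rgb(od_hematoxylin, od_dab, as_stain_matrix(stains), od_residual)
}

# evaluate expr with a temporary RNG state, restoring the caller's state
local_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render matched wild-type and knockout images of one scene
#'
#' Renders the scene as given (wild type) and again with
#' `knockout = TRUE` (all target-specific DAB zeroed, geometry,
#' counterstain, ring stain and background identical), emulating
#' staining of matched wild-type and knockout tissue on one slide.
#'
#' @param spec A [scene_spec()] with `knockout = FALSE`.
#' @return A list with `wt` (RGB array), `ko` (RGB array) and `truth`
#'   (ground truth of the wild-type render).
#' @export
make_wt_ko_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (spec$knockout) stop("spec must have knockout = FALSE", call. = FALSE)
  wt <- render_scene(spec)
  ko_spec <- spec
  ko_spec$knockout <- TRUE
  ko <- render_scene(ko_spec)
  list(wt = wt$image, ko = ko$image, truth = wt$truth)
}

#' Percent of region pixels whose planted DAB signal falls in a window
#'
#' Analytic ground-truth counterpart of [percent_area()]: uses the
#' planted (pre-quantization) DAB OD field, converted to the inverted
#' 8-bit gray convention, so synthetic percent-area recoveries can be
#' checked against the exact planted fraction.
#'
#' @param truth A `scene_truth`.
#' @param region_mask Logical matrix; `NULL` means the whole image.
#' @param lo,hi Inclusive 8-bit window (defaults 50-255).
#' @return Percent in `[0, 100]`.
#' @export
planted_percent_area <- function(truth, region_mask = NULL, lo = 50, hi = 255) {
  stopifnot(inherits(truth, "scene_truth"))
  gray <- to_inverted_gray(truth$od_dab)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(gray), ncol(gray))
  v <- gray[region_mask]
  100 * sum(v >= lo & v <= hi) / length(v)
}
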