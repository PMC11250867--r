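#' Specify a synthetic brightfield IHC scene
#'
#' Builds the full parametric description of a two-stain (hematoxylin +
#' DAB) brightfield scene: elliptical nuclei with a hematoxylin
#' counterstain, cytoplasmic DAB (constant, graded along a tissue axis,
#' or per cell), subresolution-to-small DAB puncta, vessel rings with an
#' endothelial DAB band, and small constant background OD per stain.
#' Rendering ([render_scene()]) mixes these OD fields through the
#' Beer-Lambert model and quantizes once to 8-bit, so every planted
#' quantity is known exactly.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param seed Integer seed used for the optional noise term.
#' @param nuclei Tibble with one row per nucleus: `x`, `y` (pixel
#'   coords, x = column, y = row), `radius_um` (geometric-mean radius),
#'   `eccentricity` in `[0, 1)`, `angle` (radians), `hematoxylin_od`,
#'   optional `class` (`"hepatocyte"`, `"kupffer"`, `"other"`), optional
#'   `cell_radius_um` (cytoplasm disk radius; default `2.2 * radius_um`)
#'   and optional `cyto_od` (per-cell cytoplasmic DAB OD).
#' @param cytoplasm Cytoplasmic DAB field: one of [cyto_constant()],
#'   [cyto_gradient()] or [cyto_per_cell()].
#' @param puncta Tibble with `x`, `y`, `sigma_um`, `peak_dab_od`,
#'   `parent` (row index into `nuclei`).
#' @param vessels Tibble with `x`, `y`, `r_inner_um`, `r_outer_um`,
#'   `ring_od` (smooth-muscle ring, planted on the hematoxylin vector),
#'   `endothelial_dab_od` and optional `endo_band_um` (default 2).
#' @param background_od Length-2 nonnegative vector
#'   `c(hematoxylin, dab)` of background OD constants.
#' @param knockout If `TRUE`, every target-specific DAB contribution
#'   (cytoplasm, puncta, endothelial band) is zeroed; background and the
#'   counterstain/ring are retained.
#' @param noise_sd Standard deviation of additive Gaussian intensity
#'   noise (8-bit units), applied after mixing; default 0 (exact
#'   renders).
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(width_px, height_px, pixel_size_um = 0.27, seed = 1L,
                       nuclei = NULL, cytoplasm = cyto_constant(0),
                       puncta = NULL, vessels = NULL,
                       background_od = c(hematoxylin = 0.02, dab = 0.01),
                       knockout = FALSE, noise_sd = 0) {
  spec <- structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      pixel_size_um = pixel_size_um, seed = as.integer(seed),
      nuclei = normalize_nuclei(nuclei),
      cytoplasm = cytoplasm,
      puncta = normalize_puncta(puncta),
      vessels = normalize_vessels(vessels),
      background_od = unname(background_od),
      knockout = isTRUE(knockout), noise_sd = noise_sd
    ),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
  spec
}

normalize_nuclei <- function(nuclei) {
  if (is.null(nuclei) || nrow(nuclei) == 0L) {
    return(tibble::tibble(
      x = numeric(), y = numeric(), radius_um = numeric(),
      eccentricity = numeric(), angle = numeric(), hematoxylin_od = numeric(),
      class = character(), cell_radius_um = numeric(), cyto_od = numeric()
    ))
  }
  nuclei <- tibble::as_tibble(nuclei)
  has <- function(col) col %in% names(nuclei)
  if (!has("eccentricity")) nuclei$eccentricity <- 0
  if (!has("angle")) nuclei$angle <- 0
  if (!has("class")) nuclei$class <- "other"
  if (!has("cell_radius_um")) nuclei$cell_radius_um <- 2.2 * nuclei$radius_um
  if (!has("cyto_od")) nuclei$cyto_od <- 0
  nuclei
}

normalize_puncta <- function(puncta) {
  if (is.null(puncta) || nrow(puncta) == 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(), sigma_um = numeric(),
                          peak_dab_od = numeric(), parent = integer()))
  }
  tibble::as_tibble(puncta)
}

normalize_vessels <- function(vessels) {
  if (is.null(vessels) || nrow(vessels) == 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(), r_inner_um = numeric(),
                          r_outer_um = numeric(), ring_od = numeric(),
                          endothelial_dab_od = numeric(), endo_band_um = numeric()))
  }
  vessels <- tibble::as_tibble(vessels)
  if (!"endo_band_um" %in% names(vessels)) vessels$endo_band_um <- 2
  vessels
}

#' Cytoplasmic DAB field specifications
#'
#' `cyto_constant()` plants a uniform cytoplasmic OD; `cyto_gradient()`
#' plants `od0 + (od1 - od0) * t` where `t` in `[0, 1]` is the
#' normalized projection of each pixel along a direction `angle`
#' (radians, 0 = left-to-right); `cyto_per_cell()` uses each nucleus's
#' `cyto_od`. `extent` controls whether the field fills the whole tissue
#' or only cytoplasm disks (`"cells"`, the default for constant and
#' per-cell fields; gradients default to `"tissue"`).
#'
#' @param od,od0,od1 Nonnegative OD values.
#' @param angle Gradient direction in radians.
#' @param extent `"cells"` or `"tissue"`.
#' @return A list describing the field, used by [scene_spec()].
#' @export
cyto_constant <- function(od, extent = "cells") {
  list(mode = "constant", od = od, extent = extent)
}

#' @rdname cyto_constant
#' @export
cyto_gradient <- function(od0, od1, angle = 0, extent = "tissue") {
  list(mode = "gradient", od0 = od0, od1 = od1, angle = angle, extent = extent)
}

#' @rdname cyto_constant
#' @export
cyto_per_cell <- function() {
  list(mode = "per_cell", extent = "cells")
}

validate_scene_spec <- function(spec) {
  w <- spec$width_px
  h <- spec$height_px
  if (w < 1L || h < 1L) stop("image dimensions must be positive", call. = FALSE)
  if (spec$pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  ods <- c(
    spec$background_od, spec$nuclei$hematoxylin_od, spec$nuclei$cyto_od,
    spec$puncta$peak_dab_od, spec$vessels$ring_od,
    spec$vessels$endothelial_dab_od,
    switch(spec$cytoplasm$mode,
           constant = spec$cytoplasm$od,
           gradient = c(spec$cytoplasm$od0, spec$cytoplasm$od1),
           per_cell = 0)
  )
  if (length(ods) && min(ods) < 0) {
    stop("all planted OD values must be >= 0", call. = FALSE)
  }
  nuc <- spec$nuclei
  if (nrow(nuc)) {
    a <- semi_axes(nuc$radius_um / spec$pixel_size_um, nuc$eccentricity)$a
    if (any(nuc$x - a < 0.5 | nuc$x + a > w + 0.5 |
            nuc$y - a < 0.5 | nuc$y + a > h + 0.5)) {
      stop("nucleus geometry extends outside the image bounds", call. = FALSE)
    }
    if (any(nuc$eccentricity < 0 | nuc$eccentricity >= 1)) {
      stop("eccentricity must lie in [0, 1)", call. = FALSE)
    }
  }
  if (nrow(spec$puncta)) {
    p <- spec$puncta
    if (any(p$x < 1 | p$x > w | p$y < 1 | p$y > h)) {
      stop("punctum centers must lie inside the image", call. = FALSE)
    }
    if (any(!(p$parent %in% seq_len(nrow(nuc))))) {
      stop("punctum parent ids must refer to existing nuclei", call. = FALSE)
    }
  }
  if (nrow(spec$vessels)) {
    v <- spec$vessels
    r <- v$r_outer_um / spec$pixel_size_um
    if (any(v$r_inner_um >= v$r_outer_um)) {
      stop("vessel inner radius must be smaller than outer radius", call. = FALSE)
    }
    if (any(v$x - r < 0.5 | v$x + r > w + 0.5 | v$y - r < 0.5 | v$y + r > h + 0.5)) {
      stop("vessel geometry extends outside the image bounds", call. = FALSE)
    }
  }
  invisible(spec)
}

# semi-axes of an ellipse with geometric-mean radius r and eccentricity e
semi_axes <- function(r_px, e) {
  s <- (1 - e^2)^(1 / 4)
  list(a = r_px / s, b = r_px * s)
}
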