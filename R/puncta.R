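#' Difference-of-Gaussian puncta detection within cells
#'
#' Band-pass filters the DAB inverted-gray image with a difference of
#' Gaussians (`G(sigma_small) * I - G(sigma_large) * I`), finds local
#' maxima of the response above an absolute floor inside labelled
#' cells, and reports each candidate punctum with its mean amplitude
#' over a disk footprint of radius `2 * sigma_small` on the original
#' image. Maxima falling on background (label 0) are discarded. The
#' default sigmas target 2-6 px spots near the resolution limit of
#' brightfield slide scanners.
#'
#' @param dab_gray 8-bit matrix (DAB inverted gray).
#' @param cell_labels Integer matrix of cell labels (0 = background);
#'   must contain at least one cell.
#' @param sigma_small_px,sigma_large_px DoG scales;
#'   `sigma_small_px < sigma_large_px` (defaults 1.2 and 2.4).
#' @param floor Absolute DoG floor in gray units (default 2),
#'   suppressing quantization maxima; the biological 2x-of-cell-mean
#'   filter is applied afterwards by [filter_puncta()].
#' @param min_distance_px Non-maximum suppression radius: of two
#'   candidate maxima closer than this, only the stronger survives
#'   (default `sigma_large_px`), so merged spots yield one detection.
#' @return Tibble of candidate puncta: `x`, `y` (pixel coords of the
#'   maximum), `sigma_px`, `dog_value`, `mean_amplitude`, `cell`.
#' @export
detect_puncta <- function(dab_gray, cell_labels, sigma_small_px = 1.2,
                          sigma_large_px = 2 * sigma_small_px, floor = 2,
                          min_distance_px = sigma_large_px) {
  stopifnot(is.matrix(dab_gray), is.matrix(cell_labels),
            all(dim(dab_gray) == dim(cell_labels)))
  if (sigma_small_px >= sigma_large_px) {
    stop("sigma_small_px must be smaller than sigma_large_px", call. = FALSE)
  }
  if (!any(cell_labels > 0)) stop("cell label image contains no cells", call. = FALSE)
  img <- matrix(as.numeric(dab_gray), nrow(dab_gray), ncol(dab_gray))
  dog <- EBImage::gblur(img, sigma_small_px) - EBImage::gblur(img, sigma_large_px)
  # non-max suppression over the 8-neighbourhood (grayscale dilation)
  local_max <- dog >= EBImage::dilate(dog, matrix(1, 3, 3)) - 1e-9
  cand <- which(local_max & dog >= floor & cell_labels > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(x = integer(), y = integer(), sigma_px = numeric(),
                          dog_value = numeric(), mean_amplitude = numeric(),
                          cell = integer()))
  }
  # suppress the weaker of any two candidates within min_distance_px
  # (handles quantization plateaus and merged spots)
  ord <- order(-dog[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))[-1]) {
    prev <- cand[seq_len(k - 1), , drop = FALSE][keep[seq_len(k - 1)], ,
                                                 drop = FALSE]
    if (nrow(prev) && min((prev[, 1] - cand[k, 1])^2 +
                          (prev[, 2] - cand[k, 2])^2) < min_distance_px^2) {
      keep[k] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  fp <- footprint_offsets(2 * sigma_small_px)
  rows <- purrr::map(seq_len(nrow(cand)), function(k) {
    y <- cand[k, 1]
    x <- cand[k, 2]
    yy <- pmin(pmax(y + fp$dy, 1L), nrow(img))
    xx <- pmin(pmax(x + fp$dx, 1L), ncol(img))
    tibble::tibble(x = x, y = y, sigma_px = sigma_small_px,
                   dog_value = dog[y, x],
                   mean_amplitude = mean(img[cbind(yy, xx)]),
                   cell = cell_labels[y, x])
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$dog_value))
}

footprint_offsets <- function(radius_px) {
  d <- seq(-ceiling(radius_px), ceiling(radius_px))
  off <- tidyr::expand_grid(dy = as.integer(d), dx = as.integer(d))
  off[off$dx^2 + off$dy^2 <= radius_px^2, ]
}

#' Filter puncta against twice the parent cell's mean signal
#'
#' Keeps a punctum only when its mean footprint amplitude is strictly
#' greater than twice the mean signal of the cell it appears on. The
#' cell mean is taken over the cell's full region including punctum
#' pixels (the literal convention); `exclude_puncta = TRUE` removes
#' the candidate footprints from the mean first.
#'
#' @param puncta Tibble from [detect_puncta()].
#' @param dab_gray,cell_labels As in [detect_puncta()].
#' @param exclude_puncta Exclude punctum footprints from the cell mean.
#' @return The accepted puncta, with a `cell_mean` column appended.
#' @export
filter_puncta <- function(puncta, dab_gray, cell_labels,
                          exclude_puncta = FALSE) {
  if (nrow(puncta) == 0L) {
    return(dplyr::mutate(puncta, cell_mean = numeric(0)))
  }
  stopifnot(all(puncta$cell %in% cell_labels))
  img <- matrix(as.numeric(dab_gray), nrow(dab_gray), ncol(dab_gray))
  excl <- matrix(FALSE, nrow(img), ncol(img))
  if (exclude_puncta) {
    fp <- footprint_offsets(2 * puncta$sigma_px[1])
    for (k in seq_len(nrow(puncta))) {
      yy <- pmin(pmax(puncta$y[k] + fp$dy, 1L), nrow(img))
      xx <- pmin(pmax(puncta$x[k] + fp$dx, 1L), ncol(img))
      excl[cbind(yy, xx)] <- TRUE
    }
  }
  cells <- sort(unique(puncta$cell))
  means <- vapply(cells, function(cl) {
    sel <- cell_labels == cl & !excl
    if (!any(sel)) sel <- cell_labels == cl
    mean(img[sel])
  }, numeric(1))
  out <- dplyr::mutate(puncta, cell_mean = means[match(.data$cell, cells)])
  dplyr::filter(out, .data$mean_amplitude > 2 * .data$cell_mean)
}

#' Per-cell puncta summary
#'
#' Counts accepted puncta per labelled cell (cells with none included)
#' and the percentage of cells bearing at least one punctum.
#'
#' @param accepted Tibble of accepted puncta (needs a `cell` column).
#' @param cell_labels Integer label matrix (nonempty).
#' @return Object of class `puncta_summary`: list with `cells` (tibble
#'   `cell`, `n_puncta`), `n_cells`, `n_cells_with_puncta`,
#'   `percent_with_puncta`, `n_puncta_total`.
#' @export
summarize_puncta <- function(accepted, cell_labels) {
  if (!any(cell_labels > 0)) stop("cell label image contains no cells", call. = FALSE)
  cells <- sort(unique(cell_labels[cell_labels > 0]))
  n_per <- vapply(cells, function(cl) sum(accepted$cell == cl), integer(1))
  structure(
    list(cells = tibble::tibble(cell = cells, n_puncta = n_per),
         n_cells = length(cells),
         n_cells_with_puncta = sum(n_per > 0),
         percent_with_puncta = 100 * sum(n_per > 0) / length(cells),
         n_puncta_total = sum(n_per)),
    class = "puncta_summary"
  )
}

#' @export
tidy.puncta_summary <- function(x, ...) x$cells

#' @export
glance.puncta_summary <- function(x, ...) {
  tibble::tibble(n_cells = x$n_cells,
                 n_cells_with_puncta = x$n_cells_with_puncta,
                 percent_with_puncta = x$percent_with_puncta,
                 n_puncta_total = x$n_puncta_total)
}

#' @export
print.puncta_summary <- function(x, ...) {
  cat(sprintf("Puncta summary: %d/%d cells with puncta (%.1f%%), %d puncta\n",
              x$n_cells_with_puncta, x$n_cells, x$percent_with_puncta,
              x$n_puncta_total))
  invisible(x)
}

#' Puncta per 100 cells by region
#'
#' Aggregates accepted puncta into per-region rates (e.g. one crypt per
#' region): `100 * puncta in region / cells in region`. Cells are
#' assigned to the region covering the majority of their pixels when a
#' region label image is given; a tibble mapping `cell` to `region`
#' may be supplied instead. Regions containing no cells are excluded
#' with a flag.
#'
#' @param accepted Tibble of accepted puncta.
#' @param cell_labels Integer cell label matrix.
#' @param regions Integer region label matrix (same shape) or a tibble
#'   with columns `cell`, `region`.
#' @return Tibble: `region`, `n_cells`, `n_puncta`, `per_100_cells`,
#'   `flag`.
#' @export
puncta_per_100_cells <- function(accepted, cell_labels, regions) {
  cells <- sort(unique(cell_labels[cell_labels > 0]))
  if (is.matrix(regions)) {
    stopifnot(all(dim(regions) == dim(cell_labels)))
    mapping <- tibble::tibble(
      cell = cells,
      region = vapply(cells, function(cl) {
        r <- regions[cell_labels == cl]
        as.integer(names(which.max(table(r))))
      }, integer(1))
    )
    all_regions <- sort(unique(regions[regions > 0]))
  } else {
    mapping <- tibble::as_tibble(regions)
    stopifnot(all(c("cell", "region") %in% names(mapping)))
    all_regions <- sort(unique(mapping$region))
  }
  counts <- dplyr::left_join(
    mapping,
    dplyr::count(accepted, .data$cell, name = "n_puncta"),
    by = "cell"
  )
  counts$n_puncta[is.na(counts$n_puncta)] <- 0L
  per_region <- dplyr::summarise(
    dplyr::group_by(counts, .data$region),
    n_cells = dplyr::n(), n_puncta = sum(.data$n_puncta), .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(region = all_regions), per_region,
                          by = "region")
  dplyr::mutate(
    out,
    n_cells = dplyr::coalesce(.data$n_cells, 0L),
    n_puncta = dplyr::coalesce(.data$n_puncta, 0L),
    per_100_cells = ifelse(.data$n_cells > 0,
                           100 * .data$n_puncta / .data$n_cells, NA_real_),
    flag = ifelse(.data$n_cells > 0, NA_character_, "no-cells")
  )
}
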