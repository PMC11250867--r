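# 8-connected component labelling: 4-connected pass, then union of
# diagonally adjacent labels
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  h <- nrow(lab)
  w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))   # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1])
    b <- find(pairs[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- matrix(0L, h, w)
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Corrected digital perimeter: perimeter of the moment-equivalent
# ellipse (second central moments with the 1/12 per-pixel variance
# term, Ramanujan's approximation). Rotation-invariant; exact for
# elliptical objects, so a rasterized disk's circularity is ~1 rather
# than the severe undershoot of a raw pixel-edge perimeter.
perimeter_px <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 1L) idxc <- matrix(0, 1, 2) else idxc <- scale(idx, scale = FALSE)
  cov <- crossprod(idxc) / n + diag(1 / 12, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  a <- 2 * sqrt(ev[1])
  b <- 2 * sqrt(ev[2])
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Segment nuclei from a hematoxylin inverted-gray image
#'
#' Auto-thresholds the channel, fills holes, labels 8-connected
#' components, filters by physical area and computes per-object
#' morphometrics. Circularity is \eqn{4\pi A / P^2} with a
#' projection-based (Cauchy-Crofton) perimeter estimator, so a
#' rasterized disk scores close to 1; values are clamped at 1.
#'
#' @param hema_gray 8-bit matrix (hematoxylin channel, inverted gray).
#' @param pixel_size_um Pixel size in micrometres.
#' @param min_area_um2,max_area_um2 Area filter bounds.
#' @return Tibble with one row per nucleus — `label`, `x`, `y`
#'   (centroid), `area_um2`, `perimeter_um`, `circularity` — with the
#'   relabelled nucleus label image in attribute `labels` and
#'   `pixel_size_um` attached. Empty tibble when nothing is found.
#' @export
segment_nuclei <- function(hema_gray, pixel_size_um, min_area_um2 = 5,
                           max_area_um2 = Inf) {
  mask <- tryCatch(auto_threshold(hema_gray), error = function(e) NULL)
  empty <- tibble::tibble(label = integer(), x = numeric(), y = numeric(),
                          area_um2 = numeric(), perimeter_um = numeric(),
                          circularity = numeric())
  finish <- function(tbl, labels) {
    attr(tbl, "labels") <- labels
    attr(tbl, "pixel_size_um") <- pixel_size_um
    tbl
  }
  if (is.null(mask) || !any(mask)) {
    return(finish(empty, matrix(0L, nrow(hema_gray), ncol(hema_gray))))
  }
  mask <- EBImage::fillHull(mask * 1) > 0.5
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) return(finish(empty, lab))
  xs <- matrix(rep(seq_len(ncol(lab)), each = nrow(lab)), nrow = nrow(lab))
  ys <- matrix(rep(seq_len(nrow(lab)), times = ncol(lab)), nrow = nrow(lab))
  rows <- purrr::map(seq_len(n), function(i) {
    sel <- lab == i
    area_px <- sum(sel)
    per <- perimeter_px(sel)
    tibble::tibble(
      label = i, x = mean(xs[sel]), y = mean(ys[sel]),
      area_um2 = area_px * pixel_size_um^2,
      perimeter_um = per * pixel_size_um,
      circularity = min(4 * pi * area_px / per^2, 1)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(out, .data$area_um2 >= min_area_um2,
                       .data$area_um2 <= max_area_um2)
  relab <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_len(nrow(out))) relab[lab == out$label[k]] <- k
  out$label <- seq_len(nrow(out))
  finish(out, relab)
}

#' Classify segmented nuclei by size and circularity
#'
#' Hepatocyte-like nuclei are large and near-circular; Kupffer-like
#' nuclei are small and elongated. A record is `hepatocyte` when both
#' `area_um2 >= area_cut_um2` and `circularity >= circ_cut` (inclusive
#' bounds), `kupffer` when both are strictly below their cut, `other`
#' otherwise.
#'
#' @param records Tibble from [segment_nuclei()].
#' @param area_cut_um2 Area cut (default 40).
#' @param circ_cut Circularity cut (default 0.8).
#' @return The records with a `class` column; attributes preserved.
#' @export
classify_nuclei <- function(records, area_cut_um2 = 40, circ_cut = 0.8) {
  cls <- dplyr::case_when(
    records$area_um2 >= area_cut_um2 & records$circularity >= circ_cut ~ "hepatocyte",
    records$area_um2 < area_cut_um2 & records$circularity < circ_cut ~ "kupffer",
    TRUE ~ "other"
  )
  out <- dplyr::mutate(records, class = cls)
  attr(out, "labels") <- attr(records, "labels")
  attr(out, "pixel_size_um") <- attr(records, "pixel_size_um")
  out
}

#' Cytosolic DAB signal around nuclei
#'
#' For each nucleus, measures the DAB signal in a perinuclear ring: the
#' nucleus mask dilated by `ring_um`, minus the nucleus itself and any
#' other nucleus. Reported both as mean intensity (`mean_signal`, the
#' "per unit area" convention used throughout) and as summed intensity
#' per square micrometre (`signal_per_um2`). Nuclei whose ring is
#' entirely swallowed by neighbours are flagged and excluded from the
#' means.
#'
#' @param dab_gray 8-bit matrix (DAB inverted gray).
#' @param nuclei Tibble from [segment_nuclei()] (needs its `labels`
#'   attribute), optionally classified.
#' @param ring_um Ring width in micrometres (default 1.5).
#' @return Tibble: `label`, `region`, `mean_signal`, `signal_per_um2`,
#'   `area_um2`, `flag`.
#' @export
cytosolic_signal <- function(dab_gray, nuclei, ring_um = 1.5) {
  labels <- attr(nuclei, "labels")
  px <- attr(nuclei, "pixel_size_um")
  if (is.null(labels) || is.null(px)) {
    stop("nuclei must carry `labels` and `pixel_size_um` attributes ",
         "(as produced by segment_nuclei())", call. = FALSE)
  }
  r_px <- max(1L, round(ring_um / px))
  any_nuc <- labels > 0L
  rows <- purrr::map(nuclei$label, function(l) {
    ring <- dilate_mask(labels == l, r_px) & !any_nuc
    if (!any(ring)) {
      return(tibble::tibble(label = l, region = "cytosolic-ring",
                            mean_signal = NA_real_, signal_per_um2 = NA_real_,
                            area_um2 = 0, flag = "empty-region"))
    }
    vals <- dab_gray[ring]
    tibble::tibble(label = l, region = "cytosolic-ring",
                   mean_signal = mean(vals),
                   signal_per_um2 = sum(vals) / (sum(ring) * px^2),
                   area_um2 = sum(ring) * px^2, flag = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Endothelial DAB signal inside SMA-positive vessel rings
#'
#' Within each user-supplied seed region (a square box around one
#' vessel cross-section), auto-thresholds the SMA channel, takes the
#' largest connected component, verifies it encloses a lumen, and
#' measures the DAB signal in a band of width `band_um` immediately
#' interior to the ring's inner boundary (the endothelium lies luminal
#' to the smooth muscle). Regions with no ring are flagged and skipped.
#'
#' @param sma_gray,dab_gray 8-bit matrices (inverted gray) of the
#'   smooth-muscle and target stains.
#' @param seeds Tibble with `x`, `y` (box centers) and `half_px` (box
#'   half-width).
#' @param band_um Endothelial band width (default 2).
#' @param pixel_size_um Pixel size in micrometres.
#' @return Tibble: `vessel`, `mean_signal`, `signal_per_um2`,
#'   `area_um2`, `flag`.
#' @export
vessel_endothelium <- function(sma_gray, dab_gray, seeds, band_um = 2,
                               pixel_size_um = 0.5) {
  stopifnot(all(c("x", "y", "half_px") %in% names(seeds)))
  band_px <- max(1L, round(band_um / pixel_size_um))
  rows <- purrr::map(seq_len(nrow(seeds)), function(i) {
    skip <- function(reason) {
      tibble::tibble(vessel = i, mean_signal = NA_real_,
                     signal_per_um2 = NA_real_, area_um2 = 0, flag = reason)
    }
    ys <- max(1, round(seeds$y[i] - seeds$half_px[i])):
      min(nrow(sma_gray), round(seeds$y[i] + seeds$half_px[i]))
    xs <- max(1, round(seeds$x[i] - seeds$half_px[i])):
      min(ncol(sma_gray), round(seeds$x[i] + seeds$half_px[i]))
    sub_sma <- sma_gray[ys, xs, drop = FALSE]
    mask <- tryCatch(auto_threshold(sub_sma), error = function(e) NULL)
    if (is.null(mask) || !any(mask)) return(skip("no stained pixels"))
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    comp <- lab == which.max(sizes)
    filled <- EBImage::fillHull(comp * 1) > 0.5
    interior <- filled & !comp
    if (!any(interior)) return(skip("no ring found"))
    band <- interior & dilate_mask(comp, band_px)
    if (!any(band)) return(skip("no ring found"))
    vals <- dab_gray[ys, xs, drop = FALSE][band]
    tibble::tibble(vessel = i, mean_signal = mean(vals),
                   signal_per_um2 = sum(vals) / (sum(band) * pixel_size_um^2),
                   area_um2 = sum(band) * pixel_size_um^2,
                   flag = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' Percent of a region above a fixed intensity window
#'
#' The fraction (as a percent) of region pixels whose 8-bit value lies
#' in the inclusive window `[lo, hi]` — the standard percent-positive-
#' area score with the predefined 50-255 window as default.
#'
#' @param dab_gray 8-bit matrix.
#' @param region_mask Logical matrix (nonempty).
#' @param lo,hi Window bounds (defaults 50 and 255).
#' @return One-row tibble: `percent_area`, `n_region`, `n_in_window`,
#'   `lo`, `hi`.
#' @export
percent_area <- function(dab_gray, region_mask, lo = 50, hi = 255) {
  stopifnot(is.matrix(dab_gray), is.matrix(region_mask),
            all(dim(dab_gray) == dim(region_mask)))
  if (!any(region_mask)) stop("region is empty", call. = FALSE)
  v <- dab_gray[region_mask]
  n_in <- sum(v >= lo & v <= hi)
  tibble::tibble(percent_area = 100 * n_in / length(v),
                 n_region = length(v), n_in_window = n_in, lo = lo, hi = hi)
}
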