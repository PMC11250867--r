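#' Histogram of masked 8-bit pixel intensities
#'
#' Tallies the intensities of the pixels selected by a mask into 256
#' bins (0-255). This is the per-image ingredient of the
#' knockout-controlled specificity index: the DAB inverted-gray
#' intensities inside the dilated nuclear mask.
#'
#' @param gray Integer/numeric matrix in `[0, 255]`.
#' @param mask Logical matrix of the same shape; must select at least
#'   one pixel.
#' @param source Optional tag (`"WT"` or `"KO"`).
#' @return An object of class `intensity_histogram`: list with `counts`
#'   (length 256, bins 0-255), `n_pixels`, `source`.
#' @export
masked_histogram <- function(gray, mask, source = NA_character_) {
  stopifnot(is.matrix(gray), is.matrix(mask), all(dim(gray) == dim(mask)))
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  v <- as.integer(round(gray[mask]))
  if (min(v) < 0 || max(v) > 255) stop("values must lie in [0, 255]", call. = FALSE)
  structure(
    list(counts = tabulate(v + 1L, nbins = 256L), n_pixels = length(v),
         source = source),
    class = "intensity_histogram"
  )
}

#' @export
tidy.intensity_histogram <- function(x, ...) {
  tibble::tibble(intensity = 0:255, count = x$counts,
                 frequency = x$counts / x$n_pixels)
}

#' Signal-to-noise curve and weighted specificity index
#'
#' Divides the wild-type intensity histogram by the matched knockout
#' histogram, bin by bin, to obtain the S/N curve, then integrates it
#' with intensity-proportional weights into a single scalar specificity
#' index. Both histograms are first normalized to frequencies so
#' section-area differences cancel; a shared pseudocount keeps the
#' ratio finite in empty knockout bins and makes the identical-input
#' case exact (`index = 1`).
#'
#' The index is \eqn{\sum_i w_i r_i} with \eqn{w_i = i / \sum_j j}
#' (\eqn{i = 0..255}) and
#' \eqn{r_i = (f^{WT}_i + \epsilon) / (f^{KO}_i + \epsilon)}: bins where
#' genuine stain accumulates (high intensity) dominate, and zero-
#' intensity bins carry no weight.
#'
#' @param wt,ko `intensity_histogram` objects with 256 bins each.
#' @param pseudocount Frequency pseudocount \eqn{\epsilon}; default
#'   `1 / min(n_wt, n_ko)`.
#' @return An object of class `sn_result`: list with `ratio` (256
#'   values), `index`, `pseudocount`, `weights`, `n_wt`, `n_ko`.
#' @export
sn_curve <- function(wt, ko, pseudocount = NULL) {
  stopifnot(inherits(wt, "intensity_histogram"),
            inherits(ko, "intensity_histogram"))
  if (length(wt$counts) != length(ko$counts)) {
    stop("histograms have mismatched bin counts", call. = FALSE)
  }
  if (is.null(pseudocount)) pseudocount <- 1 / min(wt$n_pixels, ko$n_pixels)
  f_wt <- wt$counts / wt$n_pixels
  f_ko <- ko$counts / ko$n_pixels
  ratio <- (f_wt + pseudocount) / (f_ko + pseudocount)
  i <- seq_along(ratio) - 1
  w <- i / sum(i)
  structure(
    list(ratio = ratio, index = sum(w * ratio), pseudocount = pseudocount,
         weights = w, n_wt = wt$n_pixels, n_ko = ko$n_pixels,
         f_wt = f_wt, f_ko = f_ko),
    class = "sn_result"
  )
}

#' @export
tidy.sn_result <- function(x, ...) {
  tibble::tibble(intensity = seq_along(x$ratio) - 1, wt_freq = x$f_wt,
                 ko_freq = x$f_ko, ratio = x$ratio, weight = x$weights)
}

#' @export
glance.sn_result <- function(x, ...) {
  tibble::tibble(index = x$index, pseudocount = x$pseudocount,
                 n_wt = x$n_wt, n_ko = x$n_ko)
}

#' @export
print.sn_result <- function(x, ...) {
  cat("Knockout-controlled S/N result\n")
  cat(sprintf("  specificity index: %.4f (pseudocount %.3g)\n",
              x$index, x$pseudocount))
  cat(sprintf("  masked pixels: WT %d, KO %d\n", x$n_wt, x$n_ko))
  invisible(x)
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.sn_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$intensity, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "DAB intensity (inverted gray)", y = "WT / KO ratio",
                  title = "Signal-to-noise curve") +
    ggplot2::theme_minimal()
}

#' Full S/N analysis of a matched WT/KO image pair
#'
#' Runs the complete specificity chain on two RGB micrographs: unmix
#' with the H-DAB matrix, auto-threshold the wild-type hematoxylin
#' channel, dilate it into the area-of-interest mask, histogram the DAB
#' inverted-gray intensities of both images inside that mask, and form
#' the S/N curve and index.
#'
#' @param wt_image,ko_image RGB arrays (`height x width x 3`, 8-bit).
#' @param stains Stain matrix (default H-DAB).
#' @param dilate_radius_px Nuclear-mask dilation radius in pixels
#'   (default 5).
#' @param pseudocount Passed to [sn_curve()].
#' @return An `sn_result` (see [sn_curve()]); the mask used is attached
#'   as attribute `mask`.
#' @export
sn_from_images <- function(wt_image, ko_image, stains = stain_matrix_hdab(),
                           dilate_radius_px = 5, pseudocount = NULL) {
  ch_wt <- unmix_stains(wt_image, stains)
  ch_ko <- unmix_stains(ko_image, stains)
  mask <- dilate_mask(auto_threshold(to_inverted_gray(ch_wt$hematoxylin)),
                      dilate_radius_px)
  wt_hist <- masked_histogram(to_inverted_gray(ch_wt$dab), mask, "WT")
  ko_hist <- masked_histogram(to_inverted_gray(ch_ko$dab), mask, "KO")
  res <- sn_curve(wt_hist, ko_hist, pseudocount = pseudocount)
  attr(res, "mask") <- mask
  res
}

#' Batch S/N indices over matched WT/KO pairs
#'
#' Processes a set of matched pairs with one shared parameter record
#' (stain matrix, dilation radius, pseudocount) — pairs must come from
#' comparable acquisitions — and reports the per-pair specificity index
#' together with a row-normalized relative index for heatmap-style
#' comparison. Per-pair failures are caught and reported, not fatal.
#'
#' @param pairs A list of `list(wt = , ko = )` RGB arrays, or a tibble
#'   with list-columns `wt` and `ko`; an optional `pair_id`
#'   column/name labels rows.
#' @inheritParams sn_from_images
#' @return A tibble with one row per pair: `pair_id`, `index`,
#'   `rel_index` (`index / max(index)` over successful pairs), `error`
#'   (`NA` on success).
#' @export
sn_batch <- function(pairs, stains = stain_matrix_hdab(),
                     dilate_radius_px = 5, pseudocount = NULL) {
  if (is.data.frame(pairs)) {
    ids <- if ("pair_id" %in% names(pairs)) pairs$pair_id else seq_len(nrow(pairs))
    pairs <- purrr::map2(pairs$wt, pairs$ko, ~list(wt = .x, ko = .y))
  } else {
    ids <- if (!is.null(names(pairs))) names(pairs) else seq_along(pairs)
  }
  rows <- purrr::map2(pairs, ids, function(p, id) {
    res <- tryCatch(
      sn_from_images(p$wt, p$ko, stains = stains,
                     dilate_radius_px = dilate_radius_px,
                     pseudocount = pseudocount),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(pair_id = id, index = NA_real_, error = conditionMessage(res))
    } else {
      tibble::tibble(pair_id = id, index = res$index, error = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  mx <- max(out$index, na.rm = TRUE)
  dplyr::mutate(out, rel_index = .data$index / mx, .after = "index")
}
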