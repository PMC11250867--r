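#' Standard H-DAB stain vector matrix
#'
#' Returns the 3x3 optical-density stain matrix for the classic
#' hematoxylin + DAB chromogen combination. Columns are unit-norm OD
#' vectors for hematoxylin, DAB and a residual stain (the normalized
#' cross product of the first two), in RGB row order. These are the
#' published preset vectors used by standard color-deconvolution tools
#' for H-DAB slides.
#'
#' @return A 3x3 numeric matrix with columns `hematoxylin`, `dab`,
#'   `residual` and rows `R`, `G`, `B`.
#' @export
#' @examples
#' stain_matrix_hdab()
stain_matrix_hdab <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- c(
    h[2] * d[3] - h[3] * d[2],
    h[3] * d[1] - h[1] * d[3],
    h[1] * d[2] - h[2] * d[1]
  )
  r <- r / sqrt(sum(r^2))
  m <- cbind(hematoxylin = h, dab = d, residual = r)
  rownames(m) <- c("R", "G", "B")
  m
}

#' Validate a stain vector matrix
#'
#' Checks that a candidate stain matrix is 3x3, that every column is a
#' unit-norm nonnegative-free OD vector, and that the matrix is well
#' conditioned enough to invert.
#'
#' @param m A 3x3 numeric matrix of stain OD column vectors.
#' @return The matrix, invisibly, with default dimnames filled in.
#' @export
as_stain_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m) || any(dim(m) != c(3L, 3L))) {
    stop("stain matrix must be a numeric 3x3 matrix", call. = FALSE)
  }
  norms <- sqrt(colSums(m^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("each stain vector must have unit Euclidean norm (+/- 1e-6)", call. = FALSE)
  }
  if (kappa(m) >= 1e6) {
    stop("stain matrix is near-singular (condition number >= 1e6)", call. = FALSE)
  }
  if (is.null(colnames(m))) colnames(m) <- c("hematoxylin", "dab", "residual")
  if (is.null(rownames(m))) rownames(m) <- c("R", "G", "B")
  invisible(m)
}

assert_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L ||
      !is.numeric(image)) {
    stop("expected an 8-bit RGB image: a numeric height x width x 3 array",
         call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("RGB intensities must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}

#' Unmix an RGB brightfield image into per-stain OD channels
#'
#' Converts each 8-bit RGB pixel to optical density,
#' \eqn{OD_c = -\log_{10}(\max(I_c, 1)/255)}, and solves the Beer-Lambert
#' mixing model \eqn{OD = M \cdot A} for the per-stain concentrations
#' \eqn{A} with the stain matrix \eqn{M}. Negative concentrations (noise
#' or off-model color) are clamped to zero.
#'
#' @param image Numeric `height x width x 3` array with values in
#'   `[0, 255]`.
#' @param stains 3x3 stain matrix; defaults to [stain_matrix_hdab()].
#' @param pixel_size_um Physical pixel size in micrometres, carried as an
#'   attribute on each channel.
#' @return A named list of class `stain_channels` with one nonnegative
#'   OD matrix per stain (named by the stain matrix columns), each with a
#'   `pixel_size_um` attribute, plus a `stains` attribute recording the
#'   matrix used.
#' @export
unmix_stains <- function(image, stains = stain_matrix_hdab(),
                         pixel_size_um = NULL) {
  assert_rgb_image(image)
  stains <- as_stain_matrix(stains)
  h <- dim(image)[1]
  w <- dim(image)[2]
  od <- -log10(pmax(image, 1) / 255)
  flat <- matrix(od, nrow = h * w, ncol = 3L)     # pixels x RGB
  conc <- flat %*% t(solve(stains))               # pixels x stains
  conc[conc < 0] <- 0
  out <- lapply(seq_len(3L), function(s) {
    m <- matrix(conc[, s], nrow = h, ncol = w)
    attr(m, "pixel_size_um") <- pixel_size_um
    m
  })
  names(out) <- colnames(stains)
  structure(out, stains = stains, class = "stain_channels")
}

#' Convert a stain OD map to an inverted 8-bit grayscale image
#'
#' Maps OD through the transmittance it would produce in isolation,
#' `gray = 255 * 10^(-OD)`, then inverts: `out = 255 - round(gray)`.
#' Larger output values therefore mean more stain; OD 0 maps to 0 and the
#' OD 3 saturation clamp maps to 255. This is the fixed scale on which
#' all downstream 8-bit "signal" histograms, thresholds and profiles
#' operate.
#'
#' @param od_map Nonnegative numeric matrix of optical densities.
#' @return Integer matrix with values in `[0, 255]`; `pixel_size_um`
#'   attribute is carried over if present.
#' @export
to_inverted_gray <- function(od_map) {
  if (!is.matrix(od_map) || min(od_map) < 0) {
    stop("od_map must be a nonnegative numeric matrix", call. = FALSE)
  }
  od <- pmin(od_map, 3)
  out <- 255L - as.integer(round(255 * 10^(-od)))
  out <- matrix(out, nrow = nrow(od_map), ncol = ncol(od_map))
  attr(out, "pixel_size_um") <- attr(od_map, "pixel_size_um")
  out
}

#' Global automatic threshold (Otsu)
#'
#' Picks the threshold `t` maximizing the between-class variance of the
#' 8-bit histogram (Otsu's criterion); foreground is the stained, i.e.
#' brighter-than-`t`, class of the inverted-gray convention used
#' throughout.
#'
#' @param gray Integer/numeric matrix with values in `[0, 255]`.
#' @return Logical matrix (`TRUE` = foreground, `gray > t`) with
#'   attributes `threshold` (the chosen `t`) and `provenance`
#'   (`"auto-threshold"`).
#' @export
auto_threshold <- function(gray) {
  if (!is.matrix(gray)) stop("gray must be a matrix", call. = FALSE)
  v <- as.integer(round(gray))
  if (min(v) < 0 || max(v) > 255) stop("values must lie in [0, 255]", call. = FALSE)
  if (min(v) == max(v)) {
    stop("image is constant: no threshold separates it", call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)                 # P(class <= t), t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254
  w0 <- omega[1:255]
  m0 <- mu[1:255]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t <- which.max(sigma_b) - 1L
  mask <- gray > t
  attr(mask, "threshold") <- t
  attr(mask, "provenance") <- "auto-threshold"
  mask
}

# Euclidean disc structuring element: offsets with dx^2 + dy^2 <= r^2
disc_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  stopifnot(r >= 0L)
  d <- seq(-r, r)
  outer(d, d, function(dy, dx) dx^2 + dy^2 <= radius_px^2) * 1
}

#' Morphological dilation of a mask with a Euclidean disc
#'
#' @param mask Logical matrix.
#' @param radius_px Nonnegative dilation radius in pixels; the
#'   structuring element contains every offset with
#'   `dx^2 + dy^2 <= radius_px^2`, so radius 0 is the identity.
#' @return Logical matrix of the same shape; `provenance` attribute set
#'   to `"dilated-nuclear"` when the input came from [auto_threshold()].
#' @export
dilate_mask <- function(mask, radius_px) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  if (radius_px < 0) stop("radius_px must be >= 0", call. = FALSE)
  if (radius_px == 0 || !any(mask)) {
    out <- mask
  } else {
    k <- disc_kernel(radius_px)
    out <- EBImage::dilate(mask * 1, k) > 0.5
  }
  prov <- attr(mask, "provenance")
  attr(out, "provenance") <-
    if (identical(prov, "auto-threshold")) "dilated-nuclear" else prov
  out
}

#' Linear brightness rescale of an RGB image
#'
#' Reproduces a display-range adjustment in which the range `[lo, hi]`
#' is linearly stretched to `[0, 255]` (values above `hi` clamp to 255).
#' The zonation workflow applies this with the default `0-235` range to
#' each RGB channel before unmixing; other quantification stages do not
#' rescale.
#'
#' @param image Numeric `height x width x 3` array in `[0, 255]`.
#' @param lo,hi Display range limits (defaults 0 and 235).
#' @return Rescaled RGB array, rounded back to integers in `[0, 255]`.
#' @export
rescale_brightness <- function(image, lo = 0, hi = 235) {
  assert_rgb_image(image)
  if (hi <= lo) stop("hi must exceed lo", call. = FALSE)
  out <- round((pmin(pmax(image, lo), hi) - lo) / (hi - lo) * 255)
  array(out, dim = dim(image))
}
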