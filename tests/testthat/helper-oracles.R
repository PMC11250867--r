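# Independent oracles used across tests. Deliberately naive: per-pixel
# loops and exhaustive enumeration, no shared code with the package
# internals they check.

# per-pixel percent-area count
naive_percent_area <- function(gray, region, lo, hi) {
  n_region <- 0L
  n_in <- 0L
  for (i in seq_len(nrow(gray))) {
    for (j in seq_len(ncol(gray))) {
      if (region[i, j]) {
        n_region <- n_region + 1L
        if (gray[i, j] >= lo && gray[i, j] <= hi) n_in <- n_in + 1L
      }
    }
  }
  100 * n_in / n_region
}

# per-pixel histogram tally
naive_masked_histogram <- function(gray, mask) {
  counts <- integer(256)
  for (i in seq_len(nrow(gray))) {
    for (j in seq_len(ncol(gray))) {
      if (mask[i, j]) {
        v <- gray[i, j]
        counts[v + 1L] <- counts[v + 1L] + 1L
      }
    }
  }
  counts
}

# exhaustive between-class-variance maximization over all thresholds
brute_force_otsu <- function(gray) {
  v <- as.vector(gray)
  best_t <- NA_integer_
  best_var <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) / length(v)^2 * (mean(hi) - mean(lo))^2
    if (bc > best_var) {
      best_var <- bc
      best_t <- t
    }
  }
  best_t
}

# literal evaluation of the zone-score eligibility + top-5 rule
brute_zone_selection <- function(m, genes, percentile, top_k = 5) {
  score <- vapply(colnames(m), function(cl) sum(m[genes, cl]), numeric(1))
  mx <- max(score)
  if (mx <= 0) return(character())
  eligible <- names(score)[score >= percentile / 100 * mx]
  # order eligible clusters by score descending, cluster position ascending
  pos <- match(eligible, colnames(m))
  ord <- eligible[order(-score[eligible], pos)]
  ord[seq_len(min(top_k, length(ord)))]
}

# small fully specified scene used by several tests
tiny_nucleus_scene <- function(hema_od = 1, dab_od = 0, knockout = FALSE) {
  scene_spec(
    9, 9, pixel_size_um = 1, seed = 1,
    nuclei = tibble::tibble(x = 5, y = 5, radius_um = 1.4,
                            hematoxylin_od = hema_od, cell_radius_um = 4),
    cytoplasm = cyto_constant(dab_od),
    background_od = c(0, 0), knockout = knockout
  )
}
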