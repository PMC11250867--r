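#' Percent of cells expressing a gene, per ontology group
#'
#' For each (ontology, tissue) group, the percentage of cells whose
#' expression value for `gene` is strictly greater than zero.
#'
#' @param table A tibble with one row per cell: columns `ontology`,
#'   optional `tissue`, and one numeric column per gene.
#' @param gene Gene (column) name; unknown genes are an error.
#' @return Tibble with `ontology` (and `tissue` when present),
#'   `n_cells`, `n_expressing`, `percent`.
#' @export
percent_expressing <- function(table, gene) {
  table <- tibble::as_tibble(table)
  if (!gene %in% names(table)) {
    stop(sprintf("gene '%s' not found in the expression table", gene),
         call. = FALSE)
  }
  if (!"ontology" %in% names(table)) {
    stop("expression table needs an `ontology` column", call. = FALSE)
  }
  keys <- intersect(c("ontology", "tissue"), names(table))
  dplyr::summarise(
    dplyr::group_by(table, dplyr::across(dplyr::all_of(keys))),
    n_cells = dplyr::n(),
    n_expressing = sum(.data[[gene]] > 0),
    percent = 100 * sum(.data[[gene]] > 0) / dplyr::n(),
    .groups = "drop"
  )
}

#' Pearson correlation between two percent-expressing vectors
#'
#' Joins two [percent_expressing()] tables on their group keys and
#' computes the Pearson correlation over matched ontology points —
#' e.g. a necroptosis gene against a proliferation marker.
#'
#' @param x_percents,y_percents Tibbles from [percent_expressing()].
#' @return One-row tibble: `r`, `n`, `flag` (`"zero-variance"` with
#'   `r = NA` when either vector is constant).
#' @export
correlate_ontologies <- function(x_percents, y_percents) {
  keys <- intersect(intersect(c("ontology", "tissue"), names(x_percents)),
                    names(y_percents))
  joined <- dplyr::inner_join(
    dplyr::select(x_percents, dplyr::all_of(keys), x = "percent"),
    dplyr::select(y_percents, dplyr::all_of(keys), y = "percent"),
    by = keys
  )
  if (nrow(joined) < 3) stop("need at least 3 matched groups", call. = FALSE)
  if (stats::sd(joined$x) == 0 || stats::sd(joined$y) == 0) {
    return(tibble::tibble(r = NA_real_, n = nrow(joined), flag = "zero-variance"))
  }
  tibble::tibble(r = stats::cor(joined$x, joined$y), n = nrow(joined),
                 flag = NA_character_)
}

#' Zone scores from a gene-by-cluster log-fold-change matrix
#'
#' Implements the zone-score aggregation rule for spatial cluster
#' selection: subset the matrix to the zone's marker genes, sum each
#' cluster's log-fold-changes into a single score vector, keep the
#' clusters whose score is at least `percentile` percent of the maximum
#' score, and select the top `top_k` of those by score (ties broken by
#' ascending cluster id). When the maximum score is not positive the
#' selection is empty and flagged.
#'
#' @param logfc Numeric matrix (genes x clusters) with dimnames, or a
#'   tibble with a `gene` column and one column per cluster.
#' @param zone_genes Character vector of the zone's marker genes
#'   (must be nonempty and present in the matrix).
#' @param percentile Percent-of-maximum eligibility cut (50 or 75 in
#'   typical use).
#' @param top_k Maximum number of selected clusters (default 5).
#' @return List with `scores` (tibble `cluster`, `score`, `eligible`,
#'   `selected`), `selected` (character vector of cluster ids in score
#'   order) and `flag`.
#' @export
zone_scores <- function(logfc, zone_genes, percentile = 50, top_k = 5) {
  m <- as_logfc_matrix(logfc)
  if (!length(zone_genes)) stop("zone gene set is empty", call. = FALSE)
  missing <- setdiff(zone_genes, rownames(m))
  if (length(missing)) {
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  score <- colSums(m[zone_genes, , drop = FALSE])
  mx <- max(score)
  if (mx <= 0) {
    return(list(
      scores = tibble::tibble(cluster = colnames(m), score = unname(score),
                              eligible = FALSE, selected = FALSE),
      selected = character(), flag = "no-positive-score"
    ))
  }
  eligible <- score >= (percentile / 100) * mx
  ord <- order(-score, seq_along(score))       # score desc, cluster id asc
  elig_ord <- ord[eligible[ord]]
  sel_idx <- elig_ord[seq_len(min(top_k, length(elig_ord)))]
  list(
    scores = tibble::tibble(cluster = colnames(m), score = unname(score),
                            eligible = unname(eligible),
                            selected = seq_along(score) %in% sel_idx),
    selected = colnames(m)[sel_idx], flag = NA_character_
  )
}

as_logfc_matrix <- function(logfc) {
  if (is.matrix(logfc)) {
    stopifnot(!is.null(rownames(logfc)), !is.null(colnames(logfc)))
    return(logfc)
  }
  logfc <- tibble::as_tibble(logfc)
  stopifnot("gene" %in% names(logfc))
  m <- as.matrix(dplyr::select(logfc, -"gene"))
  rownames(m) <- logfc$gene
  m
}

#' Gene-by-zone aggregated score table
#'
#' Re-aggregates a log-fold-change matrix over each zone's selected
#' clusters: for every gene of interest, the zone score is the sum of
#' its log-fold-changes across that zone's clusters. Genes absent from
#' the matrix are recorded as missing, not errors. The result is a
#' heatmap-ready tibble.
#'
#' @param logfc As in [zone_scores()].
#' @param zone_clusters Named list mapping zone name to a character
#'   vector of cluster ids (e.g. the `selected` component of
#'   [zone_scores()]).
#' @param genes Genes of interest.
#' @return Tibble with `gene`, one column per zone; absent genes get
#'   `NA`.
#' @export
gene_zone_matrix <- function(logfc, zone_clusters, genes) {
  m <- as_logfc_matrix(logfc)
  out <- tibble::tibble(gene = genes)
  for (zone in names(zone_clusters)) {
    cl <- zone_clusters[[zone]]
    stopifnot(all(cl %in% colnames(m)))
    out[[zone]] <- unname(vapply(genes, function(g) {
      if (!g %in% rownames(m)) return(NA_real_)
      sum(m[g, cl, drop = TRUE])
    }, numeric(1)))
  }
  out
}

#' Simulate an expression table with planted per-group rates
#'
#' Generates a cells-by-genes table in which each (ontology, tissue)
#' group expresses each gene with a planted Bernoulli rate; expressing
#' cells get a positive lognormal magnitude. Used to validate
#' [percent_expressing()] recovery.
#'
#' @param rates Tibble with `ontology`, optional `tissue`, `gene`,
#'   `rate` (in `[0, 1]`).
#' @param n_per_group Cells per group.
#' @param seed Integer seed.
#' @return Tibble with `cell`, `ontology` (and `tissue`), one numeric
#'   column per gene; planted rates attached as attribute `rates`.
#' @export
simulate_expression_table <- function(rates, n_per_group = 500, seed = 1L) {
  rates <- tibble::as_tibble(rates)
  keys <- intersect(c("ontology", "tissue"), names(rates))
  groups <- dplyr::distinct(rates, dplyr::across(dplyr::all_of(keys)))
  genes <- unique(rates$gene)
  local_seeded(seed, {
    cells <- dplyr::mutate(
      tidyr::uncount(groups, n_per_group),
      cell = paste0("c", dplyr::row_number()), .before = 1
    )
    for (g in genes) {
      r <- dplyr::left_join(cells[keys],
                            dplyr::filter(rates, .data$gene == g)[c(keys, "rate")],
                            by = keys)$rate
      r[is.na(r)] <- 0
      expressed <- stats::rbinom(nrow(cells), 1, r)
      cells[[g]] <- expressed * stats::rlnorm(nrow(cells), 0, 0.5)
    }
    attr(cells, "rates") <- rates
    cells
  })
}

#' Simulate a log-fold-change matrix with planted zone structure
#'
#' Builds a genes-by-clusters log-fold-change matrix in which each
#' zone's marker genes are elevated in that zone's clusters, on a
#' background of Gaussian noise — the planted structure the zone-score
#' rule should recover.
#'
#' @param zones Named list mapping zone name to its marker genes.
#' @param zone_assignment Named list mapping zone name to cluster ids
#'   (character); remaining clusters are background.
#' @param n_clusters Total number of clusters.
#' @param effect Planted log-fold-change in matching clusters.
#' @param noise_sd Background noise SD.
#' @param extra_genes Additional unstructured genes.
#' @param seed Integer seed.
#' @return Matrix with gene rownames and cluster colnames
#'   (`"0", "1", ...`).
#' @export
simulate_logfc_matrix <- function(zones, zone_assignment, n_clusters = 8,
                                  effect = 2, noise_sd = 0.2,
                                  extra_genes = character(), seed = 1L) {
  genes <- unique(c(unlist(zones), extra_genes))
  clusters <- as.character(seq_len(n_clusters) - 1L)
  local_seeded(seed, {
    m <- matrix(stats::rnorm(length(genes) * n_clusters, 0, noise_sd),
                nrow = length(genes), dimnames = list(genes, clusters))
    for (zone in names(zones)) {
      cl <- intersect(zone_assignment[[zone]], clusters)
      m[zones[[zone]], cl] <- m[zones[[zone]], cl] + effect
    }
    m
  })
}
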