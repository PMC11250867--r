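toy_table <- function() {
  tibble::tibble(
    cell = paste0("c", 1:8),
    ontology = rep(c("hepatocyte", "enterocyte"), each = 4),
    Mlkl = c(1.2, 0, 0, 0, 2, 3, 0, 1),
    Ripk3 = rep(0, 8)
  )
}

test_that("percent expressing counts strictly positive cells per group", {
  pe <- percent_expressing(toy_table(), "Mlkl")
  expect_equal(pe$percent[pe$ontology == "hepatocyte"], 25)
  expect_equal(pe$percent[pe$ontology == "enterocyte"], 75)
  zero <- percent_expressing(toy_table(), "Ripk3")
  expect_true(all(zero$percent == 0))
  expect_error(percent_expressing(toy_table(), "Casp8"), "not found")
  # group sums recover the total number of expressing cells
  expect_equal(sum(pe$n_cells * pe$percent / 100), sum(toy_table()$Mlkl > 0))
})

test_that("planted Bernoulli rates are recovered within binomial 99% CIs", {
  rates <- tidyr::expand_grid(
    ontology = c("hepatocyte", "kupffer", "enterocyte", "fibroblast"),
    tissue = c("liver", "gut"),
    gene = "Mlkl"
  )
  rates$rate <- c(0.85, 0.6, 0.35, 0.1, 0.5, 0.25, 0.7, 0.05)
  tbl <- simulate_expression_table(rates, n_per_group = 500, seed = 5)
  pe <- percent_expressing(tbl, "Mlkl")
  joined <- dplyr::inner_join(pe, rates, by = c("ontology", "tissue"))
  for (i in seq_len(nrow(joined))) {
    ci <- binom.test(joined$n_expressing[i], joined$n_cells[i],
                     conf.level = 0.99)$conf.int
    expect_true(joined$rate[i] >= ci[1] && joined$rate[i] <= ci[2])
  }
})

test_that("Pearson correlation across ontologies matches the closed form", {
  mk <- function(p) tibble::tibble(ontology = c("a", "b", "c"), percent = p)
  expect_equal(correlate_ontologies(mk(c(1, 2, 3)), mk(c(1, 2, 3)))$r, 1)
  expect_equal(correlate_ontologies(mk(c(1, 2, 3)), mk(c(9, 8, 7)))$r, -1)
  # hand-computed on (1,2),(2,3),(3,5): r = cov/(sd sd)
  x <- c(1, 2, 3)
  y <- c(2, 3, 5)
  r_hand <- sum((x - 2) * (y - 10 / 3)) /
    sqrt(sum((x - 2)^2) * sum((y - 10 / 3)^2))
  expect_equal(correlate_ontologies(mk(x), mk(y))$r, r_hand)
  flat <- correlate_ontologies(mk(c(4, 4, 4)), mk(c(1, 2, 3)))
  expect_true(is.na(flat$r) && flat$flag == "zero-variance")
  expect_error(correlate_ontologies(mk(x)[1:2, ], mk(y)[1:2, ]), "at least 3")
})

test_that("zone scores follow the percent-of-maximum + top-5 rule", {
  m <- matrix(0, nrow = 3, ncol = 4,
              dimnames = list(c("g1", "g2", "g3"), as.character(0:3)))
  m["g1", ] <- c(10, 9, 4, 1)
  zs <- zone_scores(m, "g1", percentile = 50)
  expect_setequal(zs$selected, c("0", "1"))

  single <- zone_scores(m[, 1, drop = FALSE], "g1")
  expect_equal(single$selected, "0")

  # all-equal scores: every cluster eligible, lowest ids win the top-5 cut
  m6 <- matrix(1, nrow = 1, ncol = 6,
               dimnames = list("g", as.character(0:5)))
  tie <- zone_scores(m6, "g", percentile = 50, top_k = 5)
  expect_equal(tie$selected, as.character(0:4))

  neg <- zone_scores(m6 - 2, "g")
  expect_equal(neg$selected, character())
  expect_equal(neg$flag, "no-positive-score")

  expect_error(zone_scores(m, character()), "empty")
  expect_error(zone_scores(m, "nope"), "absent")
})

test_that("zone-score selection matches brute force and is scale invariant", {
  set.seed(31)
  for (k in 1:40) {
    n_cl <- sample(2:6, 1)
    m <- matrix(rnorm(3 * n_cl), nrow = 3,
                dimnames = list(paste0("g", 1:3), as.character(seq_len(n_cl) - 1)))
    genes <- paste0("g", 1:3)
    pctl <- sample(c(50, 75), 1)
    zs <- zone_scores(m, genes, percentile = pctl)
    expect_equal(zs$selected, brute_zone_selection(m, genes, pctl))
    lam <- runif(1, 0.1, 9)
    expect_equal(zone_scores(m * lam, genes, percentile = pctl)$selected,
                 zs$selected)
  }
})

test_that("gene-by-zone tables aggregate selected clusters by summation", {
  m <- matrix(c(0.5, 1, 0.3, 2), nrow = 2,
              dimnames = list(c("Mlkl", "Casp8"), c("0", "1")))
  one <- gene_zone_matrix(m, list(WP = "1"), c("Mlkl", "Casp8"))
  expect_equal(one$WP, m[, "1"], ignore_attr = TRUE)
  both <- gene_zone_matrix(m, list(WP = c("0", "1")), "Mlkl")
  expect_equal(both$WP, 0.8)
  missing <- gene_zone_matrix(m, list(WP = "0"), c("Mlkl", "Ripk1"))
  expect_true(is.na(missing$WP[missing$gene == "Ripk1"]))
})

test_that("planted zone structure is recovered end to end", {
  zones <- list(WP = c("Cd19", "Ms4a1"), RP = c("Hba-a1", "Alas2"))
  assign <- list(WP = c("1", "4"), RP = c("0", "6"))
  m <- simulate_logfc_matrix(zones, assign, n_clusters = 8,
                             extra_genes = c("Mlkl", "Ripk3"), seed = 7)
  wp <- zone_scores(m, zones$WP, percentile = 75)
  expect_setequal(wp$selected, assign$WP)
  rp <- zone_scores(m, zones$RP, percentile = 75)
  expect_setequal(rp$selected, assign$RP)
  # a planted high-Mlkl zone carries the top Mlkl score
  m["Mlkl", assign$RP] <- m["Mlkl", assign$RP] + 3
  gz <- gene_zone_matrix(m, list(WP = wp$selected, RP = rp$selected), "Mlkl")
  expect_gt(gz$RP, gz$WP)
})
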