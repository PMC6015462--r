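mk_de_tbl <- function(genes, logfc) {
  data.frame(gene = genes, logFC = logfc, t = logfc, p = 0.5, p_adj = 0.5,
             stringsAsFactors = FALSE)
}

test_that("phenotype ranking sorts by logFC with lexicographic tie-breaks", {
  r <- rank_phenotype(mk_de_tbl(c("A", "B", "C"), c(2, -1, 0)))
  expect_identical(r$gene, c("A", "C", "B"))
  r2 <- rank_phenotype(mk_de_tbl(c("B", "A"), c(1, 1)))
  expect_identical(r2$gene, c("A", "B"))
  # distinct metrics: negating them reverses the order exactly
  set.seed(71)
  de <- mk_de_tbl(sprintf("G%02d", 1:9), sample(seq(-4, 4)))
  fwd <- rank_phenotype(de)
  rev_de <- de; rev_de$logFC <- -rev_de$logFC
  expect_identical(rank_phenotype(rev_de)$gene, rev(fwd$gene))
  expect_error(rank_phenotype(mk_de_tbl(c("A", "A"), c(1, 2))), "duplicate")
})

test_that("enrichment score hits the documented extremes", {
  ranked <- rank_phenotype(mk_de_tbl(c("A", "B", "C", "D"), c(3, 2, 1, -1)))
  expect_equal(enrichment_score(ranked, "A", exponent = 0), 1)
  expect_equal(enrichment_score(ranked, "D", exponent = 0), -1)
  expect_equal(enrichment_score(ranked, c("A", "B", "C", "D")), 1)
  expect_error(enrichment_score(ranked, "ZZ"), "disjoint")
})

test_that("enrichment score equals the brute-force running sum (N <= 10)", {
  set.seed(72)
  for (i in 1:20) {
    N <- sample(4:10, 1)
    genes <- sprintf("G%02d", seq_len(N))
    metric <- round(sort(rnorm(N), decreasing = TRUE), 3)
    ranked <- rank_phenotype(mk_de_tbl(genes, metric))
    gene_set <- sample(ranked$gene, sample(1:(N - 1), 1))
    for (expo in c(0, 1)) {
      expect_equal(enrichment_score(ranked, gene_set, expo),
                   oracle_es(ranked$gene, ranked$metric, gene_set, expo),
                   tolerance = 1e-12)
    }
  }
})

test_that("two-tail scores separate modes and are antisymmetric under swap", {
  genes <- sprintf("G%02d", 1:12)
  ranked <- rank_phenotype(mk_de_tbl(genes, seq(6, -5)))
  reg <- signed_regulon("TFx",
                        pos = stats::setNames(rep(1, 3), c("G01", "G02", "G03")),
                        neg = stats::setNames(rep(1, 3), c("G10", "G11", "G12")))
  es <- two_tail_es(reg, ranked)
  expect_gt(es[["EsA"]], 0)
  expect_lt(es[["EsB"]], 0)
  expect_equal(es[["dES"]], es[["EsA"]] - es[["EsB"]], tolerance = 1e-15)
  swapped <- signed_regulon("TFx", pos = reg$neg, neg = reg$pos)
  es2 <- two_tail_es(swapped, ranked)
  expect_equal(es2[["dES"]], -es[["dES"]], tolerance = 1e-12)
  # empty subset convention: Es = 0
  one_sided <- signed_regulon("TFy", pos = reg$pos)
  expect_message(es3 <- two_tail_es(one_sided, ranked), "empty negative")
  expect_identical(es3[["EsB"]], 0)
})

test_that("permutation p hits the extreme-case floor and is seeded", {
  genes <- sprintf("G%02d", 1:20)
  ranked <- rank_phenotype(mk_de_tbl(genes, seq(10, -9)))
  reg <- signed_regulon("TFx",
                        pos = stats::setNames(rep(1, 3), c("G01", "G02", "G03")),
                        neg = stats::setNames(rep(1, 3), c("G18", "G19", "G20")))
  res <- permutation_test_dES(reg, ranked, n_perm = 200, seed = 5)
  expect_equal(res$p, 1 / 201, tolerance = 1e-12)
  res2 <- permutation_test_dES(reg, ranked, n_perm = 200, seed = 5)
  expect_identical(res$p, res2$p)
})

test_that("permutation p agrees with exhaustive subset enumeration (N = 8)", {
  genes <- sprintf("G%02d", 1:8)
  metric <- c(4, 3, 2, 1, -1, -2, -3, -4)
  ranked <- rank_phenotype(mk_de_tbl(genes, metric))
  reg <- signed_regulon("TFx",
                        pos = stats::setNames(rep(1, 2), c("G01", "G03")),
                        neg = stats::setNames(rep(1, 2), c("G06", "G08")))
  obs <- two_tail_es(reg, ranked)[["dES"]]
  # enumerate every ordered pair of disjoint 2-subsets
  combos <- combn(8, 2)
  null <- c()
  for (i in seq_len(ncol(combos))) {
    rest <- setdiff(1:8, combos[, i])
    inner <- combn(rest, 2)
    for (j in seq_len(ncol(inner))) {
      fake <- signed_regulon("f",
                             pos = stats::setNames(rep(1, 2), genes[combos[, i]]),
                             neg = stats::setNames(rep(1, 2), genes[inner[, j]]))
      null <- c(null, two_tail_es(fake, ranked)[["dES"]])
    }
  }
  p_exact <- mean(abs(null) >= abs(obs))
  res <- permutation_test_dES(reg, ranked, n_perm = 10000, seed = 6)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p - p_exact), 2 * mc_se + 2 / 10000)
})

test_that("state classification applies both thresholds and directions", {
  recs <- data.frame(tf = c("A", "B", "C", "D"),
                     dES = c(1.2, -1.2, 1.2, 0),
                     p_adj = c(0.01, 0.01, 0.2, 0.01))
  out <- suppressWarnings(classify_state(recs, alpha = 0.05))
  expect_identical(out$state, c("activated", "repressed", "ns", "ns"))
  expect_warning(classify_state(recs, alpha = 0.05), "dES == 0")
})

test_that("consensus state takes the majority direction", {
  recs <- data.frame(tf = rep(c("A", "B"), each = 3),
                     state = c("activated", "activated", "ns",
                               "activated", "repressed", "ns"))
  out <- consensus_state(recs)
  expect_identical(out$state[out$tf == "A"], "activated")
  expect_identical(out$state[out$tf == "B"], "ns")
})
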