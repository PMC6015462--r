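#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with the p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' original order. Delegates to `stats::p.adjust(method = "BH")` after
#' validating the input range.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Solve trigamma(y) = x by Newton iteration (x > 0).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Two-group moderated t-test
#'
#' Empirical-Bayes differential expression for a case-vs-control design.
#' Per gene, `logFC = mean(case) - mean(control)` and the pooled residual
#' variance `s_g^2` has `d = n - 2` degrees of freedom. The prior degrees of
#' freedom `d0` and prior variance `s0^2` are fitted by method of moments on
#' `log s_g^2` (trigamma inversion of the excess variance of the log
#' variances); the posterior variance `(d0*s0^2 + d*s_g^2) / (d0 + d)`
#' shrinks each gene toward the prior, and the moderated t is referred to a
#' t distribution with `d0 + d` degrees of freedom. P-values are BH-adjusted
#' across genes.
#'
#' @param expr genes x samples expression matrix (log scale assumed).
#' @param pheno phenotype table (`sample_id`, `group` in case/control).
#' @param study_id label stored in the result.
#' @return data.frame with columns `gene`, `logFC`, `t`, `p`, `p_adj`;
#'   attributes `d0`, `s0sq`, `study_id`. Genes with zero variance in both
#'   groups get `p = 1` (with a message) and are excluded from the
#'   hyperparameter fit.
#' @export
moderated_t_test <- function(expr, pheno, study_id = "study") {
  expr <- validate_expression_matrix(expr)
  pheno <- validate_phenotype(pheno, expr)
  case <- pheno$sample_id[pheno$group == "case"]
  ctrl <- pheno$sample_id[pheno$group == "control"]
  if (length(case) < 2L || length(ctrl) < 2L) {
    stopf("both groups need at least 2 samples")
  }
  n1 <- length(case); n2 <- length(ctrl); d <- n1 + n2 - 2L
  m_case <- rowMeans(expr[, case, drop = FALSE])
  m_ctrl <- rowMeans(expr[, ctrl, drop = FALSE])
  logFC <- m_case - m_ctrl
  ss <- rowSums((expr[, case, drop = FALSE] - m_case)^2) +
    rowSums((expr[, ctrl, drop = FALSE] - m_ctrl)^2)
  s2 <- ss / d
  ok <- s2 > 0
  if (any(!ok)) {
    message(sprintf("%d gene(s) with zero variance in both groups: p set to 1",
                    sum(!ok)))
  }
  z <- log(s2[ok])
  excess <- var(z) - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    # no evidence of variance heterogeneity: fully pooled (d0 = Inf) prior
    d0 <- Inf
    s0sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0sq <- exp(mean(z) - digamma(d / 2) + digamma(d0 / 2) - log(d0 / d))
  }
  post_s2 <- if (is.infinite(d0)) rep(s0sq, length(s2)) else
    (d0 * s0sq + d * s2) / (d0 + d)
  se <- sqrt(post_s2 * (1 / n1 + 1 / n2))
  t_mod <- logFC / se
  df_total <- d0 + d
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  p[!ok] <- 1
  t_mod[!ok] <- 0
  out <- data.frame(gene = rownames(expr), logFC = logFC, t = t_mod, p = p,
                    p_adj = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0sq") <- s0sq
  attr(out, "study_id") <- study_id
  out
}

#' Differentially expressed gene set
#'
#' @param de result of [moderated_t_test()].
#' @param alpha FDR threshold (default 0.05); genes with `p_adj < alpha`.
#' @return character vector of gene ids.
#' @export
de_gene_set <- function(de, alpha = 0.05) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must lie in (0, 1]")
  de$gene[de$p_adj < alpha]
}
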