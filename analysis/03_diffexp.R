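#!/usr/bin/env Rscript
# Stage 3 — per-study differential expression (moderated t, BH FDR).
# Full DE tables go to scratch/de/ for the downstream stages; results/ keeps
# the per-study summary.

suppressPackageStartupMessages(library(masterreg))

dir.create("scratch/de", showWarnings = FALSE, recursive = TRUE)
studies <- sprintf("study%d", 1:4)
summary_rows <- list()
for (sid in studies) {
  expr <- read_expression_matrix(sprintf("scratch/sim/%s_expression.tsv", sid))
  pheno <- read_phenotype(sprintf("scratch/sim/%s_phenotype.tsv", sid), expr)
  de <- moderated_t_test(expr, pheno, study_id = sid)
  write_tsv(de, sprintf("scratch/de/de_%s.tsv", sid))
  n_sig <- length(de_gene_set(de, 0.05))
  summary_rows[[sid]] <- data.frame(
    study_id = sid, n_genes = nrow(de), n_de_fdr05 = n_sig,
    prior_df = attr(de, "d0"), prior_var = attr(de, "s0sq"))
  cat(sprintf("%s: %d/%d genes DE at FDR < 0.05 (prior df %.1f)\n",
              sid, n_sig, nrow(de), attr(de, "d0")))
}
write_tsv(do.call(rbind, summary_rows), "results/03_de_summary.tsv")
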