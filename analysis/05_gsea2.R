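#!/usr/bin/env Rscript
# Stage 5 — two-tail GSEA activation states for the MR candidates: the
# positive- and negative-mode target subsets are scored independently in
# each study's logFC ranking; dES = EsA - EsB with a 1000-permutation
# gene-label null, BH across TFs, FDR <= 0.05 state calls.

suppressPackageStartupMessages(library(masterreg))

regulons <- read_regulon_gmt("results/network.gmt")
candidates <- read.delim("results/mr_candidates.tsv", stringsAsFactors = FALSE)
cand_tfs <- candidates$tf[candidates$is_candidate]
stopifnot(length(cand_tfs) > 0)
de_list <- lapply(sprintf("study%d", 1:4), function(sid) {
  read.delim(sprintf("scratch/de/de_%s.tsv", sid), stringsAsFactors = FALSE)
})
names(de_list) <- sprintf("study%d", 1:4)

cand_regs <- structure(regulons[cand_tfs], class = "regulon_set")
records <- run_two_tail_gsea(cand_regs, de_list, n_perm = 1000L,
                             alpha = 0.05,
                             seed = (1L + 10007L * 50L) %% 2147483647L)
states <- consensus_state(records)
write_tsv(records, "results/gsea2.tsv")
write_tsv(states, "results/states.tsv")

for (i in seq_len(nrow(states))) {
  cat(sprintf("%s: %s (activated in %d, repressed in %d of %d studies)\n",
              states$tf[i], states$state[i], states$n_activated[i],
              states$n_repressed[i], length(de_list)))
}
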