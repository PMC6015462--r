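#!/usr/bin/env Rscript
# Stage 4 — master regulator analysis: hypergeometric enrichment of each
# regulon with every study's DE genes, BH across TFs per study, and the
# >= 3-study consensus call.

suppressPackageStartupMessages(library(masterreg))

regulons <- read_regulon_gmt("results/network.gmt")
de_list <- lapply(sprintf("study%d", 1:4), function(sid) {
  de <- read.delim(sprintf("scratch/de/de_%s.tsv", sid),
                   stringsAsFactors = FALSE)
  attr(de, "study_id") <- sid
  de
})
names(de_list) <- sprintf("study%d", 1:4)

records <- run_mra(regulons, de_list, alpha = 0.05, de_alpha = 0.05)
candidates <- consensus_mr(records, min_studies = 3L)
write_tsv(records, "results/mra.tsv")
write_tsv(candidates, "results/mr_candidates.tsv")

cat(sprintf("%d TFs tested in %d studies\n",
            length(unique(records$tf)), length(de_list)))
cat(sprintf("MR candidates (significant in >= 3 studies): %s\n",
            paste(candidates$tf[candidates$is_candidate], collapse = ", ")))
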