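#!/usr/bin/env Rscript
# Stage 6 — connectivity-map drug scoring: per study, the DE targets of the
# strong MR candidates (two-tail GSEA p <= 0.01) form an up/down query
# signature; every signature-database instance gets a KS connectivity score;
# per-compound means carry instance-resampling permutation p-values; drugs
# significant (p <= 0.05) with a consistent direction in >= 2 studies are
# consensus calls (negative = therapeutic, positive = mimetic).

suppressPackageStartupMessages(library(masterreg))
suppressPackageStartupMessages(library(jsonlite))

regulons <- read_regulon_gmt("results/network.gmt")
gsea <- read.delim("results/gsea2.tsv", stringsAsFactors = FALSE)
db <- read_signature_db("scratch/sim/signature_db.tsv")
truth <- read_json("scratch/sim/truth.json")

per_study <- list()
for (i in 1:4) {
  sid <- sprintf("study%d", i)
  de <- read.delim(sprintf("scratch/de/de_%s.tsv", sid),
                   stringsAsFactors = FALSE)
  query <- build_query_signature(gsea[gsea$study_id == sid, ], regulons, de,
                                 gsea_p_cutoff = 0.01, de_alpha = 0.05)
  scored <- score_signature_db(db, query)
  per_study[[sid]] <- compound_summary(scored, n_perm = 10000L, alpha = 0.05,
                                       study_id = sid,
                                       seed = (1L + 10007L * (70L + i)) %% 2147483647L)
  cat(sprintf("%s: query %d up / %d down tags\n", sid,
              length(query$up_tags), length(query$down_tags)))
}
records <- do.call(rbind, per_study)
rownames(records) <- NULL
consensus <- consensus_drugs(records, p_cutoff = 0.05, min_studies = 2L)
write_tsv(records, "results/drugs.tsv")
write_tsv(data.frame(
  compound = c(consensus$therapeutic, consensus$mimetic),
  call = rep(c("therapeutic", "mimetic"),
             c(length(consensus$therapeutic), length(consensus$mimetic)))),
  "results/consensus_drugs.tsv")

drug_truth <- unlist(truth$drug_truth)
cat(sprintf("therapeutic consensus: %s (planted: %s)\n",
            paste(consensus$therapeutic, collapse = ", "),
            paste(names(drug_truth)[drug_truth == "therapeutic"],
                  collapse = ", ")))
cat(sprintf("mimetic consensus: %s (planted: %s)\n",
            paste(consensus$mimetic, collapse = ", "),
            paste(names(drug_truth)[drug_truth == "mimetic"],
                  collapse = ", ")))
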