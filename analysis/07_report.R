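#!/usr/bin/env Rscript
# Stage 7 — cross-MR subnetwork and funnel report: Jaccard overlap between
# the state-significant MR regulons, node degree statistics, and the tiered
# result counts.

suppressPackageStartupMessages(library(masterreg))
suppressPackageStartupMessages(library(jsonlite))

regulons <- read_regulon_gmt("results/network.gmt")
candidates <- read.delim("results/mr_candidates.tsv", stringsAsFactors = FALSE)
states <- read.delim("results/states.tsv", stringsAsFactors = FALSE)
consensus <- read.delim("results/consensus_drugs.tsv", stringsAsFactors = FALSE)

sig_tfs <- states$tf[states$state != "ns"]
if (length(sig_tfs) >= 2) {
  subnet <- build_mr_subnetwork(
    structure(regulons[sig_tfs], class = "regulon_set"),
    states = stats::setNames(states$state, states$tf))
  write_tsv(subnet$nodes, "results/subnetwork_nodes.tsv")
  write_tsv(subnet$edges, "results/subnetwork_edges.tsv")
  cat(sprintf("subnetwork: %d nodes, %d edges, degree %.2f +/- %.2f\n",
              nrow(subnet$nodes), nrow(subnet$edges), subnet$mean_degree,
              subnet$sd_degree))
} else {
  subnet <- NULL
}

summary <- funnel_summary(
  all_regulons = regulons,
  mra_regulons = regulons,
  candidates = candidates$tf[candidates$is_candidate],
  state_significant = sig_tfs,
  drugs = list(therapeutic = consensus$compound[consensus$call == "therapeutic"],
               mimetic = consensus$compound[consensus$call == "mimetic"]))
summary$subnetwork_mean_degree <- if (is.null(subnet)) NA else subnet$mean_degree
summary$subnetwork_sd_degree <- if (is.null(subnet)) NA else subnet$sd_degree
write_json(summary, "results/summary.json", auto_unbox = TRUE, digits = NA,
           pretty = TRUE)

cat("analysis funnel:\n")
for (k in names(summary)) cat(sprintf("  %s: %s\n", k, summary[[k]]))
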