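#!/usr/bin/env Rscript
# Stage 1 — simulate the study conditions.
#
# Generates the ground-truth signed regulatory network (10 TFs x 500 genes,
# 30 targets each), a 200-sample reference cohort, four case-control studies
# (50 + 50) with two activated and two repressed planted master regulators
# (activity shift delta = 2), and a 50-compound signature database (3
# therapeutic, 3 mimetic, 44 neutral). Large cohort matrices go to
# scratch/sim/ (regenerable); a small truth summary goes to results/.

suppressPackageStartupMessages(library(masterreg))
suppressPackageStartupMessages(library(jsonlite))

cfg <- simulation_config(seed = 1L)
dir.create("scratch/sim", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

truth <- simulate_network(cfg)
ref <- simulate_reference_cohort(truth, cfg$n_ref, cfg$sigma_noise,
                                 seed = (cfg$seed + 10007L * 21L) %% 2147483647L)
write_expression_matrix(ref, "scratch/sim/reference_expression.tsv")

for (i in seq_len(cfg$n_studies)) {
  study <- simulate_case_control(truth, cfg$perturbed_mrs, cfg$delta,
                                 cfg$n_case, cfg$n_control, cfg$sigma_noise,
                                 seed = (cfg$seed + 10007L * (30L + i)) %% 2147483647L,
                                 study_id = sprintf("study%d", i))
  write_expression_matrix(study$expression,
                          sprintf("scratch/sim/%s_expression.tsv", study$study_id))
  write_phenotype(study$phenotype,
                  sprintf("scratch/sim/%s_phenotype.tsv", study$study_id))
}

disease_score <- truth_disease_score(truth, cfg$perturbed_mrs, cfg$delta)
db <- simulate_signature_db(disease_score, drug_truth_for(cfg),
                            n_instances_per_drug = cfg$n_instances_per_drug,
                            noise = cfg$drug_noise,
                            seed = (cfg$seed + 10007L * 60L) %% 2147483647L)
write_signature_db(db, "scratch/sim/signature_db.tsv")

# ground truth, serialised for the downstream evaluation stages
write_json(list(
  config = unclass(cfg),
  regulons = lapply(truth$regulons, function(r) as.list(r)),
  disease_score = as.list(disease_score),
  drug_truth = as.list(drug_truth_for(cfg))
), "scratch/sim/truth.json", auto_unbox = TRUE, digits = NA)

sizes <- vapply(truth$regulons, nrow, integer(1))
truth_summary <- data.frame(
  tf = truth$tf_ids,
  n_targets = sizes,
  n_positive_mode = vapply(truth$regulons, function(r) sum(r$mode == 1L),
                           integer(1)),
  perturbation = ifelse(truth$tf_ids %in% names(cfg$perturbed_mrs),
                        cfg$perturbed_mrs[truth$tf_ids], "none")
)
write_tsv(truth_summary, "results/01_truth_summary.tsv")

cat(sprintf("simulated %d TFs over %d genes; %d/%d targets positive-mode\n",
            cfg$n_tf, cfg$n_genes, sum(truth_summary$n_positive_mode),
            sum(sizes)))
cat(sprintf("planted MRs: %s\n",
            paste(names(cfg$perturbed_mrs), cfg$perturbed_mrs,
                  sep = "=", collapse = ", ")))
cat(sprintf("signature DB: %d instances over %d compounds\n",
            nrow(db$instances), length(unique(db$instances$compound))))
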