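#' Run the full master-regulator discovery pipeline on synthetic data
#'
#' Orchestrates every stage in dependency order: ground-truth simulation,
#' reference-cohort network inference, per-study differential expression,
#' master regulator analysis with cross-study consensus, two-tail GSEA
#' activation-state calls, connectivity-map drug scoring with consensus
#' drug calls, and the cross-MR subnetwork report. Every stage receives a
#' seed derived deterministically from the config's master seed, so a rerun
#' with the same config reproduces byte-identical artifacts.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if missing); all tabular
#'   artifacts, a funnel `summary.json` and an md5 `manifest.json` are
#'   written there.
#' @param n_perm,n_boot,p_cutoff,consensus,dpi_tolerance network-inference
#'   parameters (defaults 1000, 100, 0.001, 0.95, 0).
#' @param mra_min_targets MRA-tier regulon-size floor. The default 15 suits
#'   the synthetic universe, whose regulons carry `targets_per_tf` targets;
#'   on a genome-scale cohort the conventional floor is 100.
#' @param mra_alpha,de_alpha,min_studies MRA parameters (0.05, 0.05, 3).
#' @param gsea_n_perm,gsea_alpha,gsea_p_cutoff two-tail GSEA parameters
#'   (1000, 0.05 FDR for states, 0.01 on the raw p for the drug query tier).
#' @param cmap_n_perm,cmap_p_cutoff,cmap_min_studies connectivity parameters
#'   (10000, 0.05, 2).
#' @param write_cohorts also write the expression/phenotype TSVs (large;
#'   default FALSE).
#' @return invisible list with all intermediate objects plus `manifest`
#'   (file, md5) and `summary` (funnel counts).
#' @export
run_pipeline <- function(config, outdir,
                         n_perm = 1000L, n_boot = 100L, p_cutoff = 0.001,
                         consensus = 0.95, dpi_tolerance = 0,
                         mra_min_targets = 15L, mra_alpha = 0.05,
                         de_alpha = 0.05, min_studies = 3L,
                         gsea_n_perm = 1000L, gsea_alpha = 0.05,
                         gsea_p_cutoff = 0.01,
                         cmap_n_perm = 10000L, cmap_p_cutoff = 0.05,
                         cmap_min_studies = 2L, write_cohorts = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  ## 1. ground truth and cohorts
  truth <- simulate_network(config)
  ref <- simulate_reference_cohort(truth, config$n_ref, config$sigma_noise,
                                   seed = derive_seed(seed, 21L))
  studies <- lapply(seq_len(config$n_studies), function(i) {
    simulate_case_control(truth, config$perturbed_mrs, config$delta,
                          config$n_case, config$n_control,
                          config$sigma_noise,
                          seed = derive_seed(seed, 30L + i),
                          study_id = sprintf("study%d", i))
  })
  names(studies) <- vapply(studies, `[[`, character(1), "study_id")

  ## 2. network inference on the reference cohort
  net <- infer_network(ref, truth$tf_ids, n_perm = n_perm, n_boot = n_boot,
                       p_cutoff = p_cutoff, consensus = consensus,
                       dpi_tolerance = dpi_tolerance,
                       min_targets = mra_min_targets,
                       seed = derive_seed(seed, 40L))
  write_regulon_gmt(net$regulons, file.path(outdir, "network.gmt"))

  ## 3. differential expression per study
  de_list <- lapply(studies, function(s) {
    moderated_t_test(s$expression, s$phenotype, study_id = s$study_id)
  })
  for (sid in names(de_list)) {
    write_tsv(de_list[[sid]], file.path(outdir, sprintf("de_%s.tsv", sid)))
  }

  ## 4. master regulator analysis and consensus
  mra_records <- run_mra(net$regulons, de_list, alpha = mra_alpha,
                         de_alpha = de_alpha)
  candidates_tab <- consensus_mr(mra_records, min_studies = min_studies)
  candidates <- candidates_tab$tf[candidates_tab$is_candidate]
  write_tsv(mra_records, file.path(outdir, "mra.tsv"))
  write_tsv(candidates_tab, file.path(outdir, "mr_candidates.tsv"))

  ## 5. two-tail GSEA on the candidates
  gsea_records <- NULL; states <- NULL
  if (length(candidates) > 0L) {
    cand_regs <- structure(net$regulons[candidates], class = "regulon_set")
    gsea_records <- run_two_tail_gsea(cand_regs, de_list,
                                      n_perm = gsea_n_perm,
                                      alpha = gsea_alpha,
                                      seed = derive_seed(seed, 50L))
    states <- consensus_state(gsea_records)
    write_tsv(gsea_records, file.path(outdir, "gsea2.tsv"))
    write_tsv(states, file.path(outdir, "states.tsv"))
  }

  ## 6. connectivity map against the planted signature database
  disease_score <- truth_disease_score(truth, config$perturbed_mrs,
                                       config$delta)
  db <- simulate_signature_db(disease_score, drug_truth_for(config),
                              n_instances_per_drug = config$n_instances_per_drug,
                              noise = config$drug_noise,
                              seed = derive_seed(seed, 60L))
  drug_records <- NULL; drugs <- list(therapeutic = character(0),
                                      mimetic = character(0),
                                      excluded = character(0))
  if (!is.null(gsea_records)) {
    per_study <- list()
    for (i in seq_along(de_list)) {
      sid <- names(de_list)[i]
      recs <- gsea_records[gsea_records$study_id == sid, ]
      query <- build_query_signature(recs, net$regulons, de_list[[sid]],
                                     gsea_p_cutoff = gsea_p_cutoff,
                                     de_alpha = de_alpha)
      scored <- score_signature_db(db, query)
      per_study[[sid]] <- compound_summary(scored, n_perm = cmap_n_perm,
                                           alpha = cmap_p_cutoff,
                                           study_id = sid,
                                           seed = derive_seed(seed, 70L + i))
    }
    drug_records <- do.call(rbind, per_study)
    rownames(drug_records) <- NULL
    drugs <- consensus_drugs(drug_records, p_cutoff = cmap_p_cutoff,
                             min_studies = cmap_min_studies)
    write_tsv(drug_records, file.path(outdir, "drugs.tsv"))
    write_tsv(data.frame(
      compound = c(drugs$therapeutic, drugs$mimetic),
      call = rep(c("therapeutic", "mimetic"),
                 c(length(drugs$therapeutic), length(drugs$mimetic))),
      stringsAsFactors = FALSE), file.path(outdir, "consensus_drugs.tsv"))
  }

  ## 7. cross-MR subnetwork and funnel summary
  state_sig <- if (is.null(states)) character(0) else
    states$tf[states$state != "ns"]
  subnet <- NULL
  if (length(state_sig) >= 2L) {
    subnet <- build_mr_subnetwork(
      structure(net$regulons[state_sig], class = "regulon_set"),
      states = stats::setNames(states$state, states$tf))
    write_tsv(subnet$nodes, file.path(outdir, "subnetwork_nodes.tsv"))
    write_tsv(subnet$edges, file.path(outdir, "subnetwork_edges.tsv"))
  }
  summary <- funnel_summary(net$all_regulons, net$regulons, candidates,
                            state_sig, drugs)
  summary$subnetwork_mean_degree <- if (is.null(subnet)) NA else subnet$mean_degree
  summary$subnetwork_sd_degree <- if (is.null(subnet)) NA else subnet$sd_degree
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (write_cohorts) {
    write_expression_matrix(ref, file.path(outdir, "reference_expression.tsv"))
    for (s in studies) {
      write_expression_matrix(
        s$expression, file.path(outdir, sprintf("%s_expression.tsv", s$study_id)))
      write_phenotype(
        s$phenotype, file.path(outdir, sprintf("%s_phenotype.tsv", s$study_id)))
    }
  }

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       pretty = TRUE)

  invisible(list(truth = truth, reference = ref, studies = studies,
                 network = net, de = de_list, mra = mra_records,
                 candidates = candidates_tab, gsea2 = gsea_records,
                 states = states, signature_db = db, drugs = drug_records,
                 consensus = drugs, subnetwork = subnet, summary = summary,
                 manifest = manifest, outdir = outdir))
}
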