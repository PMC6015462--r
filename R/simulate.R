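#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study conditions. The defaults
#' define the reference scenario used throughout the package's tests and
#' analysis scripts: 10 TFs over 500 genes with 30 targets each, a linear-
#' Gaussian reference cohort of 200 samples, four case-control studies of
#' 50 + 50 samples in which two planted master regulators are activated and
#' two repressed, and a 50-compound signature database with 3 therapeutic,
#' 3 mimetic and 44 neutral drugs.
#'
#' @param n_tf number of transcription factors.
#' @param n_genes total genes (TFs included).
#' @param targets_per_tf targets sampled per TF (without replacement, from
#'   non-TF genes).
#' @param mode_pos_prob probability a TF-target edge has positive mode.
#' @param beta regulatory effect size (expression units per activity unit).
#' @param sigma_noise residual standard deviation.
#' @param n_ref reference-cohort sample count.
#' @param n_case,n_control per-study case/control sample counts.
#' @param n_studies number of case-control studies.
#' @param perturbed_mrs named character vector, TF id -> `"activated"` or
#'   `"repressed"`.
#' @param delta activity shift magnitude in the perturbed TFs (must be > 0).
#' @param n_therapeutic,n_mimetic,n_neutral planted drug counts.
#' @param n_instances_per_drug treatment instances per compound.
#' @param drug_noise rank-noise s.d. added to drug instance orderings.
#' @param seed integer master seed.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_tf = 10L, n_genes = 500L, targets_per_tf = 30L,
                              mode_pos_prob = 0.7, beta = 1, sigma_noise = 0.25,
                              n_ref = 200L, n_case = 50L, n_control = 50L,
                              n_studies = 4L,
                              perturbed_mrs = c(TF01 = "activated",
                                                TF02 = "activated",
                                                TF03 = "repressed",
                                                TF04 = "repressed"),
                              delta = 2, n_therapeutic = 3L, n_mimetic = 3L,
                              n_neutral = 44L, n_instances_per_drug = 5L,
                              drug_noise = 0.5, seed = 1L) {
  cfg <- list(n_tf = as.integer(n_tf), n_genes = as.integer(n_genes),
              targets_per_tf = as.integer(targets_per_tf),
              mode_pos_prob = mode_pos_prob, beta = beta,
              sigma_noise = sigma_noise, n_ref = as.integer(n_ref),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_studies = as.integer(n_studies), perturbed_mrs = perturbed_mrs,
              delta = delta, n_therapeutic = as.integer(n_therapeutic),
              n_mimetic = as.integer(n_mimetic), n_neutral = as.integer(n_neutral),
              n_instances_per_drug = as.integer(n_instances_per_drug),
              drug_noise = drug_noise, seed = as.integer(seed))
  counts <- c(cfg$n_tf, cfg$n_genes, cfg$targets_per_tf, cfg$n_ref, cfg$n_case,
              cfg$n_control, cfg$n_studies, cfg$n_instances_per_drug)
  if (any(counts <= 0L)) stopf("all counts must be positive")
  if (cfg$delta <= 0) stopf("delta must be > 0")
  if (cfg$mode_pos_prob < 0 || cfg$mode_pos_prob > 1) {
    stopf("mode_pos_prob must lie in [0, 1]")
  }
  tf_ids <- tf_ids_for(cfg)
  if (!all(names(cfg$perturbed_mrs) %in% tf_ids)) {
    stopf("perturbed TF '%s' is not among the simulated TFs",
          setdiff(names(cfg$perturbed_mrs), tf_ids)[1L])
  }
  if (!all(cfg$perturbed_mrs %in% c("activated", "repressed"))) {
    stopf("perturbation directions must be 'activated' or 'repressed'")
  }
  structure(cfg, class = "sim_config")
}

tf_ids_for <- function(config) sprintf("TF%02d", seq_len(config$n_tf))

gene_ids_for <- function(config) {
  c(tf_ids_for(config),
    sprintf("G%04d", seq_len(config$n_genes - config$n_tf)))
}

#' Simulate a signed ground-truth regulatory network
#'
#' Each TF receives `targets_per_tf` targets drawn without replacement from
#' the non-TF genes; every edge gets mode +1 with probability
#' `mode_pos_prob` (else -1) and effect size `beta`. TFs may share targets,
#' but a target's mode for a given TF is unique by construction.
#'
#' @param config a `sim_config`.
#' @return `ground_truth` object: list with `tf_ids`, `gene_ids`, and
#'   `regulons` (per TF, data.frame `target`, `mode`, `beta`).
#' @export
simulate_network <- function(config) {
  tf_ids <- tf_ids_for(config)
  gene_ids <- gene_ids_for(config)
  pool <- setdiff(gene_ids, tf_ids)
  if (config$targets_per_tf > length(pool)) {
    stopf("targets_per_tf (%d) exceeds available non-TF genes (%d)",
          config$targets_per_tf, length(pool))
  }
  with_local_seed(derive_seed(config$seed, 11L), {
    regulons <- lapply(tf_ids, function(tf) {
      targets <- sample(pool, config$targets_per_tf)
      mode <- ifelse(runif(length(targets)) < config$mode_pos_prob, 1L, -1L)
      data.frame(target = targets, mode = mode, beta = config$beta,
                 stringsAsFactors = FALSE)
    })
    names(regulons) <- tf_ids
    structure(list(tf_ids = tf_ids, gene_ids = gene_ids, regulons = regulons),
              class = "ground_truth")
  })
}

# Draw one cohort from the linear-Gaussian generative model.
# activity_shift: named vector of additive shifts on TF activities.
draw_cohort <- function(truth, n_samples, sigma_noise, sample_prefix,
                        activity_shift = NULL) {
  tf_ids <- truth$tf_ids
  genes <- truth$gene_ids
  act <- matrix(rnorm(length(tf_ids) * n_samples), nrow = length(tf_ids),
                dimnames = list(tf_ids, NULL))
  if (!is.null(activity_shift)) {
    act[names(activity_shift), ] <- act[names(activity_shift), ] +
      activity_shift
  }
  expr <- matrix(sigma_noise * rnorm(length(genes) * n_samples),
                 nrow = length(genes),
                 dimnames = list(genes,
                                 sprintf("%s%03d", sample_prefix,
                                         seq_len(n_samples))))
  expr[tf_ids, ] <- expr[tf_ids, ] + act
  for (tf in tf_ids) {
    reg <- truth$regulons[[tf]]
    if (nrow(reg) == 0L) next
    expr[reg$target, ] <- expr[reg$target, , drop = FALSE] +
      (reg$beta * reg$mode) %o% act[tf, ]
  }
  expr
}

#' Simulate a reference (normal) cohort
#'
#' Linear-Gaussian generative model: per sample, each TF has latent activity
#' `a ~ N(0,1)`; TF expression is `a + sigma_noise * eps`; a target's
#' expression is the sum of `beta * mode * a` over its regulators plus
#' `sigma_noise * eps`; unregulated genes are pure noise.
#'
#' @param truth a `ground_truth` network.
#' @param n_ref number of samples (>= 10).
#' @param sigma_noise residual s.d.
#' @param seed integer seed.
#' @return genes x samples expression matrix.
#' @export
simulate_reference_cohort <- function(truth, n_ref, sigma_noise, seed) {
  if (n_ref < 10L) stopf("n_ref must be >= 10")
  with_local_seed(seed, draw_cohort(truth, n_ref, sigma_noise, "R"))
}

#' Simulate a case-control study with perturbed master regulators
#'
#' Controls follow the reference model; cases are identical except that the
#' latent activity of each perturbed TF is shifted by `+delta` (activated)
#' or `-delta` (repressed). Consequently, for a repressed TF, its
#' positive-mode targets have negative expected logFC and its negative-mode
#' targets positive expected logFC.
#'
#' @param truth a `ground_truth` network.
#' @param perturbed_mrs named character vector, TF -> direction.
#' @param delta activity shift (> 0).
#' @param n_case,n_control sample counts.
#' @param sigma_noise residual s.d.
#' @param seed integer seed.
#' @param study_id label attached to the study.
#' @return `synthetic_study`: list with `expression`, `phenotype`,
#'   `study_id`, and the perturbation spec.
#' @export
simulate_case_control <- function(truth, perturbed_mrs, delta, n_case,
                                  n_control, sigma_noise, seed,
                                  study_id = "study") {
  if (length(perturbed_mrs) == 0L) stopf("perturbed_mrs must be non-empty")
  absent <- setdiff(names(perturbed_mrs), truth$tf_ids)
  if (length(absent) > 0L) {
    stopf("perturbed TF '%s' absent from the ground truth", absent[1L])
  }
  shift <- ifelse(perturbed_mrs == "activated", delta, -delta)
  names(shift) <- names(perturbed_mrs)
  with_local_seed(seed, {
    ctrl <- draw_cohort(truth, n_control, sigma_noise, "C")
    case <- draw_cohort(truth, n_case, sigma_noise, "A", activity_shift = shift)
    expr <- cbind(case, ctrl)
    pheno <- data.frame(
      sample_id = colnames(expr),
      group = c(rep("case", n_case), rep("control", n_control)),
      stringsAsFactors = FALSE
    )
    structure(list(expression = expr, phenotype = pheno, study_id = study_id,
                   perturbed_mrs = perturbed_mrs, delta = delta),
              class = "synthetic_study")
  })
}

#' Expected disease logFC under the generative truth
#'
#' Closed form of the planted disease signature: for each gene, the sum over
#' perturbed regulators of `direction * delta * beta * mode`; a perturbed
#' TF's own expression shifts by `direction * delta`.
#'
#' @inheritParams simulate_case_control
#' @return named numeric vector over the whole gene universe.
#' @export
truth_disease_score <- function(truth, perturbed_mrs, delta) {
  score <- stats::setNames(numeric(length(truth$gene_ids)), truth$gene_ids)
  for (tf in names(perturbed_mrs)) {
    dir <- if (perturbed_mrs[[tf]] == "activated") 1 else -1
    score[tf] <- score[tf] + dir * delta
    reg <- truth$regulons[[tf]]
    score[reg$target] <- score[reg$target] + dir * delta * reg$beta * reg$mode
  }
  score
}

#' Simulate a compound signature database
#'
#' Builds rank-ordered gene lists per treatment instance. Therapeutic drugs
#' reverse the disease signature (disease-up genes near the bottom of the
#' instance list, disease-down genes near the top); mimetic drugs mimic it;
#' neutral drugs are uniformly random permutations. Instance orderings are
#' perturbed by Gaussian rank noise of s.d. `noise` (on the scale of the
#' standardised disease score).
#'
#' @param disease_score named numeric vector over the gene universe
#'   (positive = up in disease), e.g. [truth_disease_score()].
#' @param drug_truth named character vector, compound -> `"therapeutic"`,
#'   `"mimetic"` or `"neutral"`.
#' @param n_instances_per_drug instances per compound.
#' @param noise rank-noise s.d. (0 = deterministic extreme placement).
#' @param seed integer seed.
#' @return a `signature_db`.
#' @export
simulate_signature_db <- function(disease_score, drug_truth,
                                  n_instances_per_drug = 5L, noise = 0.5,
                                  seed = 1L) {
  if (length(disease_score) == 0L) stopf("disease signature must be non-empty")
  universe <- names(disease_score)
  scl <- max(abs(disease_score))
  if (scl == 0) scl <- 1
  base <- disease_score / scl  # standardise to [-1, 1]
  cells <- c("MCF7", "PC3", "HL60")
  with_local_seed(seed, {
    meta <- list(); ranks <- list(); k <- 0L
    for (drug in names(drug_truth)) {
      kind <- drug_truth[[drug]]
      for (i in seq_len(n_instances_per_drug)) {
        k <- k + 1L
        eps <- rnorm(length(universe), sd = noise)
        profile <- switch(kind,
          therapeutic = -base + eps,
          mimetic     =  base + eps,
          neutral     = rnorm(length(universe)),
          stopf("unknown drug class '%s'", kind))
        # rank 1 = most up-regulated by the treatment; ties broken by gene id
        ord <- order(-profile, universe)
        meta[[k]] <- data.frame(
          instance_id = sprintf("%s_i%02d", drug, i), compound = drug,
          cell_line = cells[(k - 1L) %% length(cells) + 1L],
          stringsAsFactors = FALSE)
        ranks[[k]] <- universe[ord]
      }
    }
    meta <- do.call(rbind, meta)
    ranks <- do.call(rbind, ranks)
    rownames(ranks) <- meta$instance_id
    signature_db(universe = universe, instances = meta, ranks = ranks)
  })
}

#' Planted drug truth for the reference scenario
#'
#' @param config a `sim_config`.
#' @return named character vector, compound -> class.
#' @export
drug_truth_for <- function(config) {
  drugs <- c(sprintf("thera%02d", seq_len(config$n_therapeutic)),
             sprintf("mimet%02d", seq_len(config$n_mimetic)),
             sprintf("neutr%02d", seq_len(config$n_neutral)))
  stats::setNames(rep(c("therapeutic", "mimetic", "neutral"),
                      c(config$n_therapeutic, config$n_mimetic,
                        config$n_neutral)), drugs)
}
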