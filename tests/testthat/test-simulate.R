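small_config <- function(...) {
  args <- list(n_tf = 5L, n_genes = 100L, targets_per_tf = 10L,
               n_ref = 50L, n_case = 20L, n_control = 20L, n_studies = 2L,
               perturbed_mrs = c(TF01 = "activated", TF02 = "repressed"),
               n_neutral = 4L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

test_that("simulated networks honour size contracts and determinism", {
  cfg <- small_config(seed = 1L)
  net <- simulate_network(cfg)
  expect_length(net$regulons, 5L)
  expect_true(all(vapply(net$regulons, nrow, integer(1)) == 10L))
  expect_false(any(unlist(lapply(net$regulons, `[[`, "target")) %in% net$tf_ids))
  # per-TF target sets contain no duplicates (unique mode per TF-target pair)
  expect_true(all(vapply(net$regulons,
                         function(r) !anyDuplicated(r$target), logical(1))))
  expect_identical(simulate_network(cfg), net)
  expect_false(identical(simulate_network(small_config(seed = 2L)), net))
})

test_that("mode probability boundaries are exact", {
  all_pos <- simulate_network(small_config(seed = 3L, mode_pos_prob = 1))
  expect_true(all(unlist(lapply(all_pos$regulons, `[[`, "mode")) == 1L))
  all_neg <- simulate_network(small_config(seed = 3L, mode_pos_prob = 0))
  expect_true(all(unlist(lapply(all_neg$regulons, `[[`, "mode")) == -1L))
})

test_that("oversized regulon request fails", {
  cfg <- small_config(seed = 1L)
  cfg$targets_per_tf <- 96L  # only 95 non-TF genes available
  expect_error(simulate_network(cfg), "exceeds")
})

test_that("noise-free targets are exact multiples of their TF's activity", {
  cfg <- simulation_config(n_tf = 1L, n_genes = 20L, targets_per_tf = 5L,
                           sigma_noise = 0, n_ref = 30L,
                           perturbed_mrs = c(TF01 = "activated"), seed = 4L)
  truth <- simulate_network(cfg)
  expr <- simulate_reference_cohort(truth, 30L, sigma_noise = 0, seed = 5L)
  reg <- truth$regulons$TF01
  for (i in seq_len(nrow(reg))) {
    r <- cor(expr["TF01", ], expr[reg$target[i], ])
    expect_equal(r, reg$mode[i], tolerance = 1e-12)
  }
})

test_that("a zero-effect network produces null correlations", {
  cfg <- small_config(seed = 6L, beta = 0, n_genes = 60L)
  truth <- simulate_network(cfg)
  expr <- simulate_reference_cohort(truth, 200L, cfg$sigma_noise, seed = 7L)
  cc <- cor(t(expr))
  offdiag <- abs(cc[upper.tri(cc)])
  expect_lt(mean(offdiag > 0.5), 0.01)
})

test_that("sample moments match the closed-form generative moments", {
  cfg <- small_config(seed = 8L)
  truth <- simulate_network(cfg)
  expr <- simulate_reference_cohort(truth, 500L, cfg$sigma_noise, seed = 9L)
  # gene means are 0 within 4 sd / sqrt(n)
  sds <- apply(expr, 1L, sd)
  expect_true(all(abs(rowMeans(expr)) <= 4 * sds / sqrt(500)))
  # target variance = sum(beta^2) + sigma^2 within 4 standard errors
  nreg <- table(unlist(lapply(truth$regulons, `[[`, "target")))
  for (g in names(nreg)) {
    v_theory <- as.integer(nreg[[g]]) * cfg$beta^2 + cfg$sigma_noise^2
    v_hat <- var(expr[g, ])
    se <- v_theory * sqrt(2 / 499)
    expect_lt(abs(v_hat - v_theory), 4 * se)
  }
})

test_that("perturbation shifts target logFC with the expected signs", {
  cfg <- small_config(seed = 10L)
  truth <- simulate_network(cfg)
  study <- simulate_case_control(truth, c(TF02 = "repressed"), delta = 2,
                                 n_case = 50L, n_control = 50L,
                                 sigma_noise = 0.25, seed = 11L)
  expr <- study$expression
  case <- study$phenotype$sample_id[study$phenotype$group == "case"]
  ctrl <- study$phenotype$sample_id[study$phenotype$group == "control"]
  reg <- truth$regulons$TF02
  logfc <- rowMeans(expr[reg$target, case]) - rowMeans(expr[reg$target, ctrl])
  expect_gte(mean(sign(logfc) == -reg$mode), 0.95)
})

test_that("activated perturbation gives logFC near beta * delta for +1 modes", {
  cfg <- simulation_config(n_tf = 1L, n_genes = 40L, targets_per_tf = 8L,
                           mode_pos_prob = 1, sigma_noise = 0.1,
                           perturbed_mrs = c(TF01 = "activated"), seed = 12L)
  truth <- simulate_network(cfg)
  study <- simulate_case_control(truth, c(TF01 = "activated"), delta = 2,
                                 n_case = 200L, n_control = 200L,
                                 sigma_noise = 0.1, seed = 13L)
  expr <- study$expression
  case <- study$phenotype$sample_id[study$phenotype$group == "case"]
  ctrl <- study$phenotype$sample_id[study$phenotype$group == "control"]
  targets <- truth$regulons$TF01$target
  logfc <- rowMeans(expr[targets, case]) - rowMeans(expr[targets, ctrl])
  # expectation beta * delta = 2; sd of the difference ~ sqrt(2*(1+sigma^2)/200)
  expect_true(all(abs(logfc - 2) < 4 * sqrt(2 * 1.01 / 200)))
  # closed-form truth signature agrees
  score <- truth_disease_score(truth, c(TF01 = "activated"), delta = 2)
  expect_true(all(score[targets] == 2))
  expect_equal(unname(score["TF01"]), 2)
  expect_true(all(score[setdiff(names(score), c(targets, "TF01"))] == 0))
})

test_that("a delta = 0 study is null: almost no FDR discoveries", {
  cfg <- small_config(seed = 14L)
  truth <- simulate_network(cfg)
  study <- simulate_case_control(truth, c(TF01 = "activated"), delta = 1e-9,
                                 n_case = 30L, n_control = 30L,
                                 sigma_noise = 0.25, seed = 15L)
  de <- suppressMessages(moderated_t_test(study$expression, study$phenotype))
  expect_lte(length(de_gene_set(de, 0.05)), ceiling(0.02 * nrow(de)))
})

test_that("perturbing an unknown TF fails", {
  truth <- simulate_network(small_config(seed = 16L))
  expect_error(simulate_case_control(truth, c(TF99 = "activated"), 2,
                                     20L, 20L, 0.25, seed = 1L), "TF99")
})

test_that("noise-free planted drugs score in the expected directions", {
  score <- c(A = 2, B = 1, C = -1, D = -2, E = 0, F = 0, G = 0.5, H = -0.5)
  db <- simulate_signature_db(score,
                              c(cureall = "therapeutic", badone = "mimetic",
                                inert = "neutral"),
                              n_instances_per_drug = 2L, noise = 0,
                              seed = 17L)
  up <- c("A", "B"); down <- c("C", "D")
  thera <- db$ranks[db$instances$compound == "cureall", , drop = FALSE]
  mimet <- db$ranks[db$instances$compound == "badone", , drop = FALSE]
  for (i in 1:2) {
    expect_lt(ks_tag_score(up, thera[i, ]), 0)
    expect_gt(ks_tag_score(down, thera[i, ]), 0)
    expect_gt(ks_tag_score(up, mimet[i, ]), 0)
    expect_lt(ks_tag_score(down, mimet[i, ]), 0)
  }
  # mimetic instances mimic the query: positive raw score, scaled anchor +1
  query <- tag_signature(up_tags = up, down_tags = down)
  scored <- score_signature_db(db, query)
  expect_true(all(scored$raw[scored$compound == "badone"] > 0))
  expect_equal(max(scored$score), 1)
  expect_true(1 %in% scored$score[scored$compound == "badone"])
})

test_that("simulation is deterministic under the seed at every stage", {
  cfg <- small_config(seed = 18L)
  truth <- simulate_network(cfg)
  a <- simulate_reference_cohort(truth, 50L, 0.25, seed = 19L)
  b <- simulate_reference_cohort(truth, 50L, 0.25, seed = 19L)
  expect_identical(a, b)
  expect_false(identical(a, simulate_reference_cohort(truth, 50L, 0.25,
                                                      seed = 20L)))
  s1 <- simulate_case_control(truth, c(TF01 = "activated"), 2, 20L, 20L,
                              0.25, seed = 21L)
  s2 <- simulate_case_control(truth, c(TF01 = "activated"), 2, 20L, 20L,
                              0.25, seed = 21L)
  expect_identical(s1$expression, s2$expression)
})
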