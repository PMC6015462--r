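test_that("permutation threshold boundary cases", {
  set.seed(31)
  expr <- random_expr(20, 40)
  # p_cutoff = 1 gives the null minimum: every candidate edge passes
  thr <- permutation_threshold(expr, rownames(expr)[1:3], n_perm = 200,
                               p_cutoff = 1, seed = 1)
  edges <- infer_raw_network(expr, rownames(expr)[1:3], thr)
  expect_equal(nrow(edges), 3 * 19)
  # degenerate null (all constant rows) collapses to a single value
  const <- matrix(1, nrow = 4, ncol = 20,
                  dimnames = list(paste0("G", 1:4), paste0("S", 1:20)))
  suppressWarnings(
    thr0 <- permutation_threshold(const, "G1", n_perm = 120, seed = 1))
  expect_identical(thr0, 0)
  expect_warning(permutation_threshold(expr, rownames(expr)[1:3], n_perm = 50,
                                       seed = 1), "unstable")
})

test_that("raw network matches a brute-force all-pairs scan", {
  set.seed(32)
  expr <- random_expr(20, 40)
  tfs <- rownames(expr)[1:4]
  thr <- 0.12
  edges <- infer_raw_network(expr, tfs, thr)
  brute <- 0L
  for (tf in tfs) for (g in rownames(expr)) {
    if (tf != g && estimate_mi(expr[tf, ], expr[g, ]) >= thr) brute <- brute + 1L
  }
  expect_identical(nrow(edges), brute)
  expect_identical(nrow(infer_raw_network(expr, tfs, Inf)), 0L)
  expect_error(infer_raw_network(expr, character(0), thr), "empty TF list")
})

test_that("noise-free single-TF truth is recovered exactly", {
  cfg <- simulation_config(n_tf = 1L, n_genes = 30L, targets_per_tf = 6L,
                           sigma_noise = 0, n_ref = 60L,
                           perturbed_mrs = c(TF01 = "activated"), seed = 33L)
  truth <- simulate_network(cfg)
  expr <- simulate_reference_cohort(truth, 60L, 0, seed = 34L)
  edges <- infer_raw_network(expr, "TF01", threshold = 0.5)
  expect_setequal(edges$target, truth$regulons$TF01$target)
})

test_that("bootstrap consensus boundaries behave as defined", {
  set.seed(35)
  expr <- random_expr(15, 30)
  tfs <- rownames(expr)[1:3]
  thr <- 0.15
  # n_boot = 1, consensus = 1 equals the raw network of the single resample
  b1 <- bootstrap_consensus(expr, tfs, thr, n_boot = 1, consensus = 1,
                            seed = 7)
  idx <- masterreg:::with_local_seed(7, sample.int(30, 30, replace = TRUE))
  eb <- expr[, idx]
  colnames(eb) <- sprintf("B%02d", seq_along(idx))
  manual <- infer_raw_network(eb, tfs, thr)
  expect_setequal(paste(b1$tf, b1$target), paste(manual$tf, manual$target))
  expect_true(all(b1$bootstrap_support == 1))
  # consensus = 0 is the union of the bootstrap networks
  b0 <- bootstrap_consensus(expr, tfs, thr, n_boot = 5, consensus = 0,
                            seed = 7)
  b95 <- bootstrap_consensus(expr, tfs, thr, n_boot = 5, consensus = 0.95,
                             seed = 7)
  expect_true(all(paste(b95$tf, b95$target) %in% paste(b0$tf, b0$target)))
  expect_true(all(b0$bootstrap_support > 0))
})

test_that("DPI removes the weakest edge of a closed triplet, keeps ties", {
  edges <- data.frame(tf = c("TF1", "TF2", "TF1"),
                      target = c("TF2", "T", "T"),
                      mi = c(0.8, 0.7, 0.3), stringsAsFactors = FALSE)
  out <- apply_dpi(edges, tf_list = c("TF1", "TF2"))
  expect_setequal(paste(out$tf, out$target), c("TF1 TF2", "TF2 T"))
  # equality with null tolerance keeps the edge (strict inequality rule)
  edges$mi <- c(0.8, 0.7, 0.7)
  out <- apply_dpi(edges, tf_list = c("TF1", "TF2"))
  expect_identical(nrow(out), 3L)
  # positive tolerance relaxes the bound further
  edges$mi <- c(0.8, 0.7, 0.4)
  expect_identical(nrow(apply_dpi(edges, c("TF1", "TF2"), tolerance = 0.5)),
                   3L)
})

test_that("DPI equals exhaustive triplet enumeration on random instances", {
  set.seed(36)
  for (i in 1:12) {
    tfs <- paste0("TF", 1:3)
    targets <- paste0("T", 1:12)
    nodes <- c(tfs, targets)
    all_pairs <- expand.grid(tf = tfs, target = nodes,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$tf != all_pairs$target, ]
    # drop duplicate TF-TF pairs in both orientations
    tt <- all_pairs$target %in% tfs
    cand <- all_pairs[!tt | (all_pairs$tf < all_pairs$target), ]
    sub <- cand[runif(nrow(cand)) < 0.5, ]
    sub$mi <- runif(nrow(sub), 0.05, 1)
    tol <- sample(c(0, 0, 0.2), 1)
    got <- apply_dpi(sub, tfs, tolerance = tol)
    want <- oracle_dpi(sub, tfs, tolerance = tol)
    expect_setequal(paste(got$tf, got$target), paste(want$tf, want$target))
  }
})

test_that("mode assignment follows the Pearson sign and partitions regulons", {
  cfg <- simulation_config(n_tf = 2L, n_genes = 40L, targets_per_tf = 8L,
                           sigma_noise = 0, n_ref = 50L,
                           perturbed_mrs = c(TF01 = "activated"), seed = 37L)
  truth <- simulate_network(cfg)
  expr <- simulate_reference_cohort(truth, 50L, 0, seed = 38L)
  edges <- do.call(rbind, lapply(names(truth$regulons), function(tf) {
    data.frame(tf = tf, target = truth$regulons[[tf]]$target, mi = 1,
               stringsAsFactors = FALSE)
  }))
  regs <- assign_modes(expr, edges, truth$tf_ids)
  for (tf in names(regs)) {
    tr <- truth$regulons[[tf]]
    expect_setequal(regulon_targets(regs[[tf]]), tr$target)
    expect_identical(length(regs[[tf]]$pos) + length(regs[[tf]]$neg),
                     length(tr$target))
    expect_setequal(names(regs[[tf]]$neg), tr$target[tr$mode == -1L])
  }
  # TF-TF edges are dropped from regulons
  edges2 <- rbind(edges, data.frame(tf = "TF01", target = "TF02", mi = 1))
  regs2 <- assign_modes(expr, edges2, truth$tf_ids)
  expect_false("TF02" %in% regulon_targets(regs2$TF01))
  # zero-variance gene is a hard error
  expr0 <- expr; expr0["G0001", ] <- 0
  edges3 <- data.frame(tf = "TF01", target = "G0001", mi = 1)
  expect_error(assign_modes(expr0, edges3, truth$tf_ids), "G0001")
})

test_that("regulon size filters implement both tier rules", {
  mk <- function(tf, n) {
    signed_regulon(tf, pos = stats::setNames(rep(1, n), sprintf("%s_t%03d", tf, 1:n)))
  }
  regs <- structure(list(A = mk("A", 100), B = mk("B", 25), C = mk("C", 26),
                         D = mk("D", 99)), class = "regulon_set")
  expect_identical(names(filter_regulons(regs, 100, "geq")), "A")
  expect_identical(names(filter_regulons(regs, 25, "gt")),
                   c("A", "C", "D"))
  expect_identical(names(filter_regulons(regs, 0, "geq")), names(regs))
})

test_that("inference stages are monotone and deterministic on a seeded run", {
  cfg <- simulation_config(n_tf = 4L, n_genes = 80L, targets_per_tf = 10L,
                           n_ref = 100L,
                           perturbed_mrs = c(TF01 = "activated"), seed = 39L)
  truth <- simulate_network(cfg)
  expr <- simulate_reference_cohort(truth, 100L, cfg$sigma_noise, seed = 40L)
  thr <- permutation_threshold(expr, truth$tf_ids, n_perm = 500, seed = 41)
  raw <- infer_raw_network(expr, truth$tf_ids, thr)
  boot <- bootstrap_consensus(expr, truth$tf_ids, thr, n_boot = 30,
                              p_cutoff = 0.001, seed = 42)
  pruned <- apply_dpi(boot, truth$tf_ids)
  key <- function(e) paste(e$tf, e$target)
  expect_true(all(key(boot) %in% key(raw)))
  expect_true(all(key(pruned) %in% key(boot)))
  boot2 <- bootstrap_consensus(expr, truth$tf_ids, thr, n_boot = 30,
                               p_cutoff = 0.001, seed = 42)
  expect_identical(boot, boot2)
})
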