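test_that("homogeneity test accepts tight clades and is seed-reproducible", {
  # observed variance far below the null mean: p near 1, accept
  v <- rep(0.3, 20) + seq(-1e-4, 1e-4, length.out = 20)
  e <- rep(100, 20)
  ht <- clade_homogeneity_test(v, e, seed = 1)
  expect_gt(ht$p_value, 0.99)
  ht2 <- clade_homogeneity_test(v, e, seed = 1)
  expect_identical(ht$p_value, ht2$p_value)
  expect_error(clade_homogeneity_test(0.3, 100), "at least 2")
})

test_that("pooling two separated beta clusters is detected as heterogeneous", {
  set.seed(51)
  v <- c(rbeta(100, 0.45 * 300, 0.55 * 300), rbeta(100, 0.25 * 300, 0.75 * 300))
  e <- rep(300, 200)
  ht <- clade_homogeneity_test(v, e, seed = 2)
  expect_lt(ht$p_value, 0.01)
  expect_gt(ht$observed_var, ht$null_mean)
})

test_that("a clade of genuine beta draws is accepted at alpha 0.01", {
  set.seed(52)
  accepts <- sapply(1:10, function(i) {
    v <- rbeta(150, 0.35 * 200, 0.65 * 200)
    clade_homogeneity_test(v, rep(200, 150), seed = i)$p_value >= 0.01
  })
  expect_gte(sum(accepts), 8)
})

test_that("partitioning emits disjoint exhaustive clusters and respects min size", {
  sim <- sim_single_tumor(c(0.45, 0.25), depth = 300, m = 60,
                          pool = shared_pool(), seed = 6)
  tree <- build_tree(sim$data$vaf, sim$data$depth,
                     leaves = collapse_leaves(sim$data$vaf))
  part <- partition_tree(tree, seed = 3)
  all_members <- sort(unlist(part$clusters))
  expect_equal(all_members, seq_len(nvariants(sim$data)))
  expect_equal(anyDuplicated(unlist(part$clusters)), 0L)
  expect_true(all(c("p_value", "observed_var", "null_mean") %in%
                  colnames(part$tests)))
})

test_that("two well-separated subclones at 300x resolve into two clusters", {
  ks <- sapply(1:10, function(i) {
    sim <- sim_single_tumor(c(0.45, 0.25), depth = 300, m = 100,
                            pool = shared_pool(), seed = 100 + i)
    nrow(vafclust(sim$data, seed = i)$clusters)
  })
  expect_gte(sum(ks == 2), 8)
})

test_that("a single simulated beta cluster is left intact for most seeds", {
  ks <- sapply(1:10, function(i) {
    sim <- sim_single_tumor(0.45, depth = 300, m = 200,
                            pool = shared_pool(), seed = 200 + i)
    nrow(vafclust(sim$data, seed = i)$clusters)
  })
  expect_gte(sum(ks == 1), 8)
})

test_that("stricter alpha never yields more clusters on the same tree and seed", {
  sim <- sim_single_tumor(c(0.45, 0.35), depth = 100, m = 80,
                          pool = shared_pool(), seed = 77)
  k_strict <- nrow(vafclust(sim$data, alpha = 1e-6, seed = 5)$clusters)
  k_loose <- nrow(vafclust(sim$data, alpha = 0.2, seed = 5)$clusters)
  expect_lte(k_strict, k_loose)
})

test_that("confidence scores follow the tail-probability rule", {
  sim <- sim_single_tumor(c(0.45, 0.25), depth = 300, m = 100,
                          pool = shared_pool(), seed = 8)
  fit <- vafclust(sim$data, seed = 8)
  conf <- fit$assignments$confidence
  expect_true(all(conf >= 0 & conf <= 1))
  # score decays with distance from the assigned cluster's mean
  for (c_i in seq_len(nrow(fit$clusters))) {
    sel <- fit$assignments$cluster == c_i
    dev <- abs(fit$assignments$vaf_tumor[sel] - fit$cluster_means[c_i, 1])
    expect_lt(cor(dev, conf[sel], method = "spearman"), -0.95)
  }
  # a variant sitting exactly at a symmetric cluster's mean scores 0.5
  p <- fit_beta(200, 0.5)
  expect_equal(tail_probability(p, 0.5), 0.5)
})

test_that("multi-sample summary confidence is the minimum across samples", {
  sim <- sim_multi_tumor(n_subclones = 2, n_variants = 80, n_samples = 2,
                         depth = 300, seed = 15)
  fit <- vafclust(sim$data, seed = 15)
  cs <- fit$assignments[, paste0("conf_", sim$data$samples)]
  expect_equal(fit$assignments$confidence, do.call(pmin, cs))
})

test_that("misassigned variants in overlapping clusters score below 0.5", {
  # substantial overlap at low depth: boundary variants land in the wrong
  # cluster but carry low confidence
  hits <- 0; total <- 0
  for (i in 1:5) {
    sim <- sim_single_tumor(c(0.45, 0.25), depth = 30, m = 100,
                            pool = shared_pool(), seed = 300 + i)
    fit <- vafclust(sim$data, seed = i)
    truth <- sim$truth$subclone[match(fit$assignments$id, sim$truth$id)]
    sc <- j_score(truth, fit$assignments$cluster)
    if (sc$n_clusters_inferred != 2) next
    # map inferred clusters to majority truth label
    map <- sapply(1:2, function(c_i)
      as.integer(names(which.max(table(truth[fit$assignments$cluster == c_i])))))
    if (length(unique(map)) < 2) next
    mis <- which(map[fit$assignments$cluster] != truth)
    total <- total + length(mis)
    hits <- hits + sum(fit$assignments$confidence[mis] < 0.5)
  }
  expect_gt(total, 0)
  expect_gte(hits / total, 0.9)
})
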