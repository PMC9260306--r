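test_that("leaf collapsing groups epsilon-cliques and only those", {
  lv <- collapse_leaves(matrix(c(0.300, 0.305, 0.400), ncol = 1))
  expect_equal(lapply(lv, sort), list(c(1L, 2L), 3L))
  # a chain is not a clique: 0.30-0.316 exceeds epsilon
  lv2 <- collapse_leaves(matrix(c(0.30, 0.308, 0.316), ncol = 1))
  expect_equal(lapply(lv2, sort), list(c(1L, 2L), 3L))
  # multi-sample Euclidean distance: (0.3, 0.3) vs (0.3, 0.32) is 0.02
  lv3 <- collapse_leaves(rbind(c(0.3, 0.3), c(0.3, 0.32)))
  expect_length(lv3, 2)
  # epsilon = 0 returns one leaf per variant
  v <- matrix(runif(20), ncol = 1)
  expect_length(collapse_leaves(v, epsilon = 0), 20)
  # partition property on random data
  set.seed(3)
  v2 <- matrix(runif(100), ncol = 1)
  lv4 <- collapse_leaves(v2)
  expect_equal(sort(unlist(lv4)), 1:100)
  for (leaf in lv4) {
    if (length(leaf) > 1) {
      dmat <- as.matrix(dist(v2[leaf, , drop = FALSE]))
      expect_true(all(dmat[upper.tri(dmat)] < 0.01))
    }
  }
})

test_that("pair distance matches direct evaluation of the weighted NLL", {
  set.seed(21)
  for (i in 1:10) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    S <- sample(1:2, 1)
    v1 <- matrix(runif(n1 * S, 0.1, 0.5), ncol = S)
    v2 <- matrix(runif(n2 * S, 0.1, 0.5), ncol = S)
    e1 <- matrix(rpois(n1 * S, 200), ncol = S)
    e2 <- matrix(rpois(n2 * S, 200), ncol = S)
    d <- pair_distance(v1, e1, v2, e2)
    expect_equal(d$d, brute_pair_distance(v1, e1, v2, e2), tolerance = 1e-10)
    dsym <- pair_distance(v2, e2, v1, e1)
    expect_equal(d$d, dsym$d, tolerance = 1e-12)
  }
})

test_that("tight same-mean clades are closer than clades with distant means", {
  set.seed(22)
  a1 <- matrix(0.3 + rnorm(10, sd = 0.01), ncol = 1)
  a2 <- matrix(0.3 + rnorm(10, sd = 0.01), ncol = 1)
  b <- matrix(0.1 + rnorm(10, sd = 0.01), ncol = 1)
  e <- matrix(300, 10, 1)
  d_same <- pair_distance(a1, e, a2, e)$d
  d_diff <- pair_distance(a1, e, b, e)$d
  expect_lt(d_same, d_diff)
})

test_that("very tight merged sets yield negative distances (density > 1)", {
  set.seed(23)
  v1 <- matrix(0.30 + rnorm(20, sd = 0.002), ncol = 1)
  v2 <- matrix(0.30 + rnorm(20, sd = 0.002), ncol = 1)
  e <- matrix(500, 20, 1)
  expect_lt(pair_distance(v1, e, v2, e)$d, 0)
})

test_that("degenerate variance or range is floored with a warning", {
  v <- matrix(rep(0.3, 4), ncol = 1)
  e <- matrix(100, 4, 1)
  expect_warning(d <- pair_distance(v[1:2, , drop = FALSE], e[1:2, , drop = FALSE],
                                    v[3:4, , drop = FALSE], e[3:4, , drop = FALSE]),
                 "floored")
  expect_true(is.finite(d$d))
})

test_that("greedy merging matches the exhaustive-recompute oracle", {
  set.seed(24)
  for (rep in 1:5) {
    L <- sample(4:6, 1)
    n <- L * 3
    V <- matrix(runif(n, 0.05, 0.5), ncol = 1)
    E <- matrix(rpois(n, 150), ncol = 1)
    leaves <- split(seq_len(n), rep(seq_len(L), each = 3))
    names(leaves) <- NULL
    tree <- build_tree(V, E, leaves = leaves)
    oracle <- brute_merge_sequence(tree$vaf, E, leaves)
    expect_equal(nrow(tree$merges), L - 1)
    expect_equal(unname(as.matrix(tree$merges[, c("left", "right", "new")])),
                 unname(oracle))
  }
})

test_that("first merge joins the closest pair and L leaves give L-1 merges", {
  set.seed(25)
  vafs <- c(0.10, 0.12, 0.45)
  V <- matrix(unlist(lapply(vafs, function(v) v + rnorm(10, sd = 0.005))),
              ncol = 1)
  E <- matrix(100, 30, 1)
  leaves <- split(1:30, rep(1:3, each = 10))
  names(leaves) <- NULL
  tree <- build_tree(V, E, leaves = leaves)
  expect_equal(sort(unname(unlist(tree$merges[1, c("left", "right")]))), c(1, 2))
  expect_equal(nrow(tree$merges), 2)
  # single leaf: tree of one node, no merges
  t1 <- build_tree(V[1:3, , drop = FALSE], E[1:3, , drop = FALSE],
                   leaves = list(1:3))
  expect_equal(nrow(t1$merges), 0)
  expect_equal(t1$root, 1L)
})

test_that("node statistics agree with direct recomputation from members", {
  set.seed(26)
  V <- matrix(runif(30, 0.1, 0.5), ncol = 1)
  E <- matrix(rpois(30, 200), ncol = 1)
  tree <- suppressWarnings(build_tree(V, E))
  for (id in seq_along(tree$members)) {
    mem <- tree$members[[id]]
    if (is.null(mem)) next
    expect_identical(mem, sort(mem))  # members stored sorted, no duplicates
    expect_identical(anyDuplicated(mem), 0L)
  }
  # parent members are the union of children's
  for (k in seq_len(nrow(tree$merges))) {
    with(tree$merges[k, ], expect_equal(
      tree$members[[new]],
      sort(c(tree$members[[left]], tree$members[[right]]))))
  }
})

test_that("final clusters are invariant to variant input order", {
  sim <- sim_single_tumor(c(0.45, 0.2), depth = 300, m = 40,
                          pool = shared_pool(), seed = 41)
  fit1 <- vafclust(sim$data, seed = 9)
  perm <- sample(nvariants(sim$data))
  dat2 <- vaf_data(chrom = sim$data$variants$chrom[perm],
                   pos = sim$data$variants$pos[perm],
                   ref_counts = sim$data$ref[perm, , drop = FALSE],
                   alt_counts = sim$data$alt[perm, , drop = FALSE],
                   id = sim$data$variants$id[perm], samples = "tumor")
  fit2 <- vafclust(dat2, seed = 9)
  m1 <- fit1$assignments$cluster[match(sim$data$variants$id,
                                       fit1$assignments$id)]
  m2 <- fit2$assignments$cluster[match(sim$data$variants$id,
                                       fit2$assignments$id)]
  expect_equal(j_score(m1, m2)$J, 1)
})

test_that("collapsing leaves equals no collapsing when all variants are separated", {
  set.seed(27)
  v <- seq(0.05, 0.5, length.out = 12) + runif(12, 0, 0.002)
  V <- matrix(v, ncol = 1)
  E <- matrix(rpois(12, 300), ncol = 1)
  dat <- vaf_data(chrom = rep("chr1", 12), pos = 1:12 * 10L,
                  ref_counts = round(E * (1 - V)), alt_counts = round(E * V))
  f_collapse <- vafclust(dat, collapse_eps = 0.01, seed = 4)
  f_plain <- vafclust(dat, collapse_eps = 0, seed = 4)
  expect_equal(j_score(f_collapse$assignments$cluster,
                       f_plain$assignments$cluster)$J, 1)
})
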