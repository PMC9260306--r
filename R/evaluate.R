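# Scoring decompositions against truth and the package's simulation
# experiments (variance-dependence study and accuracy grids).

#' Pairwise clustering accuracy (J-score)
#'
#' Compares an inferred partition with the true subclone labels through
#' variant pairs: precision is the fraction of co-clustered pairs in the
#' inference that are truly co-clustered, recall the fraction of truly
#' co-clustered pairs recovered, and the score their harmonic mean, in
#' [0, 1] with 1 iff the partitions are identical up to relabelling. An
#' alternative cluster-matching score (size-weighted best-match F1) is
#' available with `method = "matching"`.
#'
#' @param truth Vector of true cluster labels.
#' @param inferred Vector of inferred labels over the same variants (same
#'   order and length).
#' @param method `"pairwise"` (default) or `"matching"`.
#' @return A list of class `score_report`: `J`, `precision`, `recall`,
#'   `n_clusters_true`, `n_clusters_inferred`.
#' @export
j_score <- function(truth, inferred, method = c("pairwise", "matching")) {
  method <- match.arg(method)
  if (length(truth) != length(inferred))
    stop("truth and inferred labels must cover the same variants")
  tab <- table(truth, inferred)
  if (method == "matching") {
    nt <- rowSums(tab)
    f1 <- matrix(0, nrow(tab), ncol(tab))
    for (i in seq_len(nrow(tab)))
      f1[i, ] <- 2 * tab[i, ] / (nt[i] + colSums(tab))
    J <- sum(nt / sum(nt) * apply(f1, 1, max))
    out <- list(J = J, precision = NA_real_, recall = NA_real_,
                n_clusters_true = nrow(tab), n_clusters_inferred = ncol(tab))
    class(out) <- "score_report"
    return(out)
  }
  ch2 <- function(x) x * (x - 1) / 2
  tp <- sum(ch2(tab))
  pairs_true <- sum(ch2(rowSums(tab)))
  pairs_inf <- sum(ch2(colSums(tab)))
  if (pairs_true == 0 && pairs_inf == 0) {
    P <- R <- J <- 1
  } else {
    P <- if (pairs_inf == 0) 1 else tp / pairs_inf
    R <- if (pairs_true == 0) 1 else tp / pairs_true
    J <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  }
  out <- list(J = J, precision = P, recall = R,
              n_clusters_true = nrow(tab), n_clusters_inferred = ncol(tab))
  class(out) <- "score_report"
  out
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("J = %.4f (precision %.4f, recall %.4f; %d true / %d inferred clusters)\n",
              x$J, x$precision, x$recall, x$n_clusters_true,
              x$n_clusters_inferred))
  invisible(x)
}

#' Depth-variance and mean-variance dependence of simulated clusters
#'
#' Simulates homogeneous clusters from the founding-clone pool across a grid
#' of target depths and target mean VAFs and measures how the within-cluster
#' VAF variance depends on each axis: at fixed mean VAF the correlation of
#' log10 variance with log10 depth (strongly negative), and at fixed depth
#' the correlation of variance with mean VAF (strongly positive). Raw-scale
#' correlations are reported alongside.
#'
#' @param depths Target depth levels (default the 8 levels 30-500x).
#' @param vafs Target mean VAF levels (default 0.05-0.45 in steps of 0.05).
#' @param clusters_per_cell Simulated clusters per (depth, VAF) cell
#'   (default 10).
#' @param m Variants per cluster (default 100).
#' @param pool Optional pool from [sim_pool()].
#' @param seed Optional integer seed.
#' @return A list with `cells` (one row per simulated cluster: depth, vaf,
#'   rep, observed mean depth/VAF/variance), `cor_depth` (per VAF level:
#'   Pearson correlation of log10 var vs log10 depth, raw-scale correlation,
#'   p-value) and `cor_vaf` (per depth level: correlation of var vs mean
#'   VAF, log-scale correlation, p-value).
#' @export
depth_variance_experiment <- function(depths = c(30, 50, 75, 100, 150, 200,
                                                 300, 500),
                                      vafs = seq(0.05, 0.45, by = 0.05),
                                      clusters_per_cell = 10, m = 100,
                                      pool = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(pool)) pool <- sim_pool()
    rows <- list()
    for (e in depths) for (v in vafs) for (r in seq_len(clusters_per_cell)) {
      idx <- sample.int(nrow(pool), m, replace = m > nrow(pool))
      ds <- sim_downsample(pool[idx, , drop = FALSE], e = e, v = v)
      tot <- ds$ref + ds$alt
      ok <- tot > 0
      vv <- ds$alt[ok] / tot[ok]
      rows[[length(rows) + 1]] <- data.frame(
        depth = e, vaf = v, rep = r, mean_depth = mean(tot[ok]),
        mean_vaf = mean(vv), var_vaf = stats::var(vv))
    }
    cells <- do.call(rbind, rows)
    cor_depth <- if (length(depths) < 2) NULL else
      do.call(rbind, lapply(vafs, function(v) {
      sub <- cells[cells$vaf == v, ]
      ct <- stats::cor.test(log10(sub$var_vaf), log10(sub$depth))
      data.frame(vaf = v, pcc_log = unname(ct$estimate),
                 pcc_raw = stats::cor(sub$var_vaf, sub$depth),
                 p_value = ct$p.value)
    }))
    cor_vaf <- if (length(vafs) < 2) NULL else
      do.call(rbind, lapply(depths, function(e) {
      sub <- cells[cells$depth == e, ]
      ct <- stats::cor.test(sub$var_vaf, sub$vaf)
      data.frame(depth = e, pcc_raw = unname(ct$estimate),
                 pcc_log = stats::cor(log10(sub$var_vaf), sub$vaf),
                 p_value = ct$p.value)
    }))
    list(cells = cells, cor_depth = cor_depth, cor_vaf = cor_vaf)
  })
}

#' Accuracy grid over simulated tumors
#'
#' Runs the full simulate-fit-score loop over a grid of conditions and
#' reports, per cell, the mean J-score and the mean number of inferred
#' clusters over replicates. `mode = "single"` simulates two-subclone
#' single-sample tumors ([sim_single_tumor()]) over depths x VAF pairs;
#' `mode = "multi"` simulates multi-sample tumors ([sim_multi_tumor()])
#' over depths x sample counts.
#'
#' @param mode `"single"` or `"multi"`.
#' @param depths Depth levels.
#' @param vaf_pairs For `mode = "single"`: a two-column matrix (or list of
#'   length-2 vectors) of founding/descendant target VAFs.
#' @param n_samples For `mode = "multi"`: vector of sample counts.
#' @param n_subclones,n_variants For `mode = "multi"`.
#' @param reps Replicates per cell (default 10).
#' @param m Variants per subclone in single mode (default 100).
#' @param pool Optional pool for single mode.
#' @param seed Integer seed; each replicate derives its own sub-seed.
#' @param ... Passed to [vafclust()] (e.g. `reps`, `alpha`).
#' @return A data frame with one row per cell: the grid coordinates,
#'   `mean_J`, `mean_clusters` and `reps`.
#' @export
benchmark_grid <- function(mode = c("single", "multi"),
                           depths = c(30, 300),
                           vaf_pairs = rbind(c(0.45, 0.25)),
                           n_samples = 2, n_subclones = 3, n_variants = 200,
                           reps = 10, m = 100, pool = NULL, seed = 1L, ...) {
  mode <- match.arg(mode)
  if (is.list(vaf_pairs)) vaf_pairs <- do.call(rbind, vaf_pairs)
  rows <- list()
  counter <- 0L
  if (mode == "single") {
    if (is.null(pool)) pool <- sim_pool(seed = derive_seed(seed, 999L))
    for (e in depths) for (p in seq_len(nrow(vaf_pairs))) {
      Js <- ks <- numeric(reps)
      for (r in seq_len(reps)) {
        counter <- counter + 1L
        sim <- sim_single_tumor(vafs = vaf_pairs[p, ], depth = e, m = m,
                                pool = pool,
                                seed = derive_seed(seed, counter))
        fit <- vafclust(sim$data, seed = derive_seed(seed, counter, 1L), ...)
        sc <- j_score(sim$truth$subclone,
                      fit$assignments$cluster[match(sim$truth$id,
                                                    fit$assignments$id)])
        Js[r] <- sc$J
        ks[r] <- sc$n_clusters_inferred
      }
      rows[[length(rows) + 1]] <- data.frame(
        depth = e, vaf_founding = vaf_pairs[p, 1],
        vaf_descendant = vaf_pairs[p, 2], mean_J = mean(Js),
        mean_clusters = mean(ks), reps = reps)
    }
  } else {
    for (e in depths) for (ns in n_samples) {
      Js <- ks <- numeric(reps)
      for (r in seq_len(reps)) {
        counter <- counter + 1L
        sim <- sim_multi_tumor(n_subclones = n_subclones,
                               n_variants = n_variants, n_samples = ns,
                               depth = e, seed = derive_seed(seed, counter))
        fit <- vafclust(sim$data, seed = derive_seed(seed, counter, 1L), ...)
        sc <- j_score(sim$truth$subclone,
                      fit$assignments$cluster[match(sim$truth$id,
                                                    fit$assignments$id)])
        Js[r] <- sc$J
        ks[r] <- sc$n_clusters_inferred
      }
      rows[[length(rows) + 1]] <- data.frame(
        depth = e, n_samples = ns, n_subclones = n_subclones,
        mean_J = mean(Js), mean_clusters = mean(ks), reps = reps)
    }
  }
  do.call(rbind, rows)
}
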