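#' Decompose a tumor into subclones by clustering VAFs
#'
#' Fits the beta error model to per-variant read counts from one or more
#' samples of a tumor. Diploid variants (those outside copy-number altered
#' segments) are collapsed into leaves, merged agglomeratively under a
#' weighted negative log-likelihood distance, and the merge tree is
#' partitioned adaptively with a parametric-bootstrap variance test; each
#' accepted clade is one subclone. CNV-affected variants are then assigned
#' to the existing clusters together with their mutant-copy multiplicity.
#' Cellular prevalence, per-sample tumor purity (from the cluster with mean
#' VAF closest to 0.5) and per-variant confidence scores are reported.
#'
#' @param x A `vaf_data` object (see [vaf_data()], [read_snv_table()]).
#' @param segments Optional copy-number segment data frame
#'   ([read_cnv_table()]); segments with total copy number 2 are neutral.
#' @param alpha Per-sample significance level of the clade variance test
#'   (default 0.01); smaller values yield fewer, coarser clusters.
#' @param reps Parametric-bootstrap repetitions per clade test (default
#'   1000).
#' @param collapse_eps Euclidean VAF radius for leaf collapsing (default
#'   0.01); 0 disables collapsing.
#' @param max_copies Upper limit of the CNV multiplicity search (default
#'   10).
#' @param constrain_k Restrict multiplicity to at most `max(N, 2)` copies.
#' @param min_test_size Smallest clade that is variance-tested (default 3).
#' @param clip VAFs are clipped to `[clip, 1 - clip]` before beta densities
#'   are evaluated (default 1e-4).
#' @param seed Integer seed driving the bootstrap draws (default 1); per
#'   clade sub-seeds are derived from clade membership so results do not
#'   depend on traversal order.
#' @return An object of class `vafclust` with components `clusters` (per
#'   cluster: size and per-sample mean VAF), `assignments` (per variant:
#'   cluster, per-sample VAF and confidence, multiplicity and segment for
#'   CNV-affected variants), `purity`, `prevalence`, `segments_assigned`,
#'   `diploid_fraction`, `confidence`, `tree`, `tests`, `warnings` and the
#'   input `data`.
#' @examples
#' sim <- sim_single_tumor(c(0.45, 0.25), depth = 300, m = 50, seed = 7)
#' fit <- vafclust(sim$data)
#' fit
#' coef(fit)
#' @export
vafclust <- function(x, segments = NULL, alpha = 0.01, reps = 1000,
                     collapse_eps = 0.01, max_copies = 10,
                     constrain_k = FALSE, min_test_size = 3L,
                     clip = 1e-4, seed = 1L) {
  stopifnot(inherits(x, "vaf_data"))
  cl <- match.call()
  warn <- character(0)
  n <- nvariants(x)
  if (n < 1) stop("no variants to cluster")
  S <- length(x$samples)

  cn <- partition_by_cn_status(x, segments)
  dip <- cn$diploid
  if (!length(dip)) stop("no diploid variants: clusters cannot be formed")

  Vd <- x$vaf[dip, , drop = FALSE]
  Ed <- x$depth[dip, , drop = FALSE]

  leaves <- collapse_leaves(Vd, epsilon = collapse_eps)
  tree <- withCallingHandlers(
    build_tree(Vd, Ed, leaves = leaves, clip = clip),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  part <- partition_tree(tree, alpha = alpha, reps = reps, seed = seed,
                         min_test_size = min_test_size)

  # order clusters by decreasing mean VAF in the first sample
  means_raw <- t(vapply(part$clusters,
                        function(mem) colMeans(Vd[mem, , drop = FALSE]),
                        numeric(S)))
  means_raw <- matrix(means_raw, ncol = S)
  ord <- order(-means_raw[, 1])
  clusters_idx <- part$clusters[ord]
  C <- length(clusters_idx)
  means <- means_raw[ord, , drop = FALSE]
  colnames(means) <- x$samples
  rownames(means) <- paste0("C", seq_len(C))
  sizes <- lengths(clusters_idx)

  conf <- assign_confidence(Vd, Ed, clusters_idx, clip = clip)
  cluster_of_dip <- integer(length(dip))
  for (c_i in seq_len(C)) cluster_of_dip[clusters_idx[[c_i]]] <- c_i

  pur <- estimate_purity(means, sizes, samples = x$samples)
  if (any(pur$clamped))
    warn <- c(warn, sprintf(
      "founding-clone mean VAF exceeds 0.5 in sample(s) %s; purity clamped at 1",
      paste(pur$sample[pur$clamped], collapse = ", ")))
  prevalence <- 2 * means

  # per-variant output table
  assignments <- data.frame(
    id = x$variants$id, chrom = x$variants$chrom, pos = x$variants$pos,
    cluster = NA_integer_, cn_status = "diploid", segment_id = NA_character_,
    stringsAsFactors = FALSE)
  assignments$cluster[dip] <- cluster_of_dip
  for (s in seq_len(S)) {
    assignments[[paste0("vaf_", x$samples[s])]] <- x$vaf[, s]
    cc <- rep(NA_real_, n)
    cc[dip] <- conf$per_sample[, s]
    assignments[[paste0("conf_", x$samples[s])]] <- cc
  }
  summ <- rep(NA_real_, n)
  summ[dip] <- conf$summary
  assignments$confidence <- summ
  assignments$multiplicity <- NA_integer_

  # CNV-affected variants: per-segment assignment to existing clusters
  segs_assigned <- NULL
  if (nrow(cn$affected)) {
    assignments$cn_status[cn$affected$index] <- "cnv"
    assignments$segment_id[cn$affected$index] <- cn$affected$segment_id
    seg_rows <- list()
    for (sid in unique(cn$affected$segment_id)) {
      rows <- cn$affected[cn$affected$segment_id == sid, ]
      res <- tryCatch(
        assign_segment(rows$total_cn[1],
                       x$vaf[rows$index, , drop = FALSE], means,
                       max_copies = max_copies, constrain_k = constrain_k),
        error = function(e) e)
      if (inherits(res, "error")) {
        warn <- c(warn, sprintf("segment %s left unassigned: %s", sid,
                                conditionMessage(res)))
        next
      }
      assignments$cluster[rows$index] <- res$snv$g
      assignments$multiplicity[rows$index] <- res$snv$k
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        segment_id = sid, total_cn = rows$total_cn[1],
        omega_cluster = res$omega, total_residual = res$total_residual,
        stringsAsFactors = FALSE)
    }
    if (length(seg_rows)) segs_assigned <- do.call(rbind, seg_rows)
    if (!is.null(segments)) {
      unhit <- setdiff(segments$segment_id[segments$total_cn != 2],
                       cn$affected$segment_id)
      if (length(unhit))
        warn <- c(warn, sprintf(
          "segment(s) %s overlap no variants and were not assigned",
          paste(unhit, collapse = ", ")))
    }
  }

  dfc <- diploid_fraction_check(assignments$cn_status == "diploid",
                                assignments$cluster)
  warn <- c(warn, dfc$warnings)

  clusters_df <- data.frame(cluster = seq_len(C), n = as.integer(sizes))
  for (s in seq_len(S))
    clusters_df[[paste0("mean_vaf_", x$samples[s])]] <- means[, s]

  structure(list(
    call = cl, data = x, clusters = clusters_df, cluster_members =
      lapply(clusters_idx, function(mem) dip[mem]),
    cluster_means = means, cluster_params = conf$params,
    assignments = assignments, confidence = conf$per_sample,
    purity = pur, prevalence = prevalence,
    segments_assigned = segs_assigned,
    diploid_fraction = list(overall = dfc$overall,
                            per_cluster = as.list(dfc$per_cluster)),
    tree = tree, tests = part$tests, warnings = warn,
    params = list(alpha = alpha, reps = reps, collapse_eps = collapse_eps,
                  max_copies = max_copies, min_test_size = min_test_size,
                  clip = clip, seed = seed)
  ), class = "vafclust")
}

#' @export
print.vafclust <- function(x, ...) {
  cat(sprintf("Subclone decomposition: %d cluster(s), %d variants, %d sample(s)\n",
              nrow(x$clusters), nrow(x$assignments), length(x$data$samples)))
  print(x$clusters, row.names = FALSE)
  cat("Purity:",
      paste(sprintf("%s = %.3f", x$purity$sample, x$purity$purity),
            collapse = ", "), "\n")
  if (length(x$warnings))
    cat("Warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.vafclust <- function(object, ...) {
  structure(list(fit = object), class = "summary.vafclust")
}

#' @export
print.summary.vafclust <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCellular prevalence (2 x mean VAF):\n")
  print(round(f$prevalence, 4))
  if (!is.null(f$segments_assigned)) {
    cat("\nCNV segments:\n")
    print(f$segments_assigned, row.names = FALSE)
  }
  cat(sprintf("\nDiploid fraction: %.2f\n", f$diploid_fraction$overall))
  cat(sprintf("Clade tests run: %d (alpha = %g, %d bootstrap reps)\n",
              nrow(f$tests), f$params$alpha, f$params$reps))
  invisible(x)
}

#' @describeIn vafclust Cluster mean VAFs (clusters x samples matrix).
#' @param object,... S3 method arguments.
#' @export
coef.vafclust <- function(object, ...) object$cluster_means

#' @describeIn vafclust Per-variant residuals: observed VAF minus the mean
#'   VAF of the assigned cluster (matrix, variants x samples).
#' @export
residuals.vafclust <- function(object, ...) {
  cl <- object$assignments$cluster
  res <- object$data$vaf
  ok <- !is.na(cl)
  res[ok, ] <- res[ok, , drop = FALSE] -
    object$cluster_means[cl[ok], , drop = FALSE]
  res[!ok, ] <- NA_real_
  res
}

#' @describeIn vafclust Fitted values: the assigned cluster's mean VAF per
#'   variant and sample.
#' @export
fitted.vafclust <- function(object, ...) {
  cl <- object$assignments$cluster
  out <- matrix(NA_real_, nrow(object$assignments),
                ncol(object$cluster_means),
                dimnames = list(object$assignments$id,
                                colnames(object$cluster_means)))
  ok <- !is.na(cl)
  out[ok, ] <- object$cluster_means[cl[ok], , drop = FALSE]
  out
}

#' @describeIn vafclust Assign new VAF observations to the fitted clusters.
#'   `newdata` is a numeric vector (single sample) or matrix (variants x
#'   samples) of VAFs; each observation goes to the cluster under which its
#'   minimum-across-samples tail probability is largest.
#' @param newdata New VAF observations for `predict`.
#' @export
predict.vafclust <- function(object, newdata, ...) {
  V <- as.matrix(newdata)
  if (ncol(V) != ncol(object$cluster_means))
    stop("newdata must have one column per fitted sample")
  V <- clip_vaf(V, object$params$clip)
  C <- nrow(object$cluster_means)
  score <- matrix(NA_real_, nrow(V), C)
  for (c_i in seq_len(C)) {
    per_s <- vapply(seq_len(ncol(V)), function(s)
      tail_probability(object$cluster_params[[c_i]][[s]], V[, s]),
      numeric(nrow(V)))
    per_s <- matrix(per_s, nrow = nrow(V))
    score[, c_i] <- apply(per_s, 1, min)
  }
  cluster <- max.col(score, ties.method = "first")
  data.frame(cluster = cluster,
             confidence = score[cbind(seq_len(nrow(V)), cluster)])
}

#' @describeIn vafclust Simulate read-count data sets from the fitted
#'   clusters: per cluster and sample, depth is Poisson at the cluster mean
#'   depth and the VAF beta-distributed with the fitted shape parameters.
#' @param nsim,seed Number of simulated data sets and seed for `simulate`.
#' @export
simulate.vafclust <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      ref <- alt <- NULL
      lab <- integer(0)
      S <- ncol(object$cluster_means)
      for (c_i in seq_len(nrow(object$clusters))) {
        mem <- object$cluster_members[[c_i]]
        nmem <- length(mem)
        rr <- aa <- matrix(0L, nmem, S)
        for (s in seq_len(S)) {
          pr <- object$cluster_params[[c_i]][[s]]
          dep <- stats::rpois(nmem, mean(object$data$depth[mem, s]))
          v <- stats::rbeta(nmem, pr$alpha, pr$beta)
          aa[, s] <- stats::rbinom(nmem, dep, v)
          rr[, s] <- dep - aa[, s]
        }
        ref <- rbind(ref, rr)
        alt <- rbind(alt, aa)
        lab <- c(lab, rep(c_i, nmem))
      }
      n <- nrow(ref)
      id <- sprintf("v%05d", seq_len(n))
      dat <- suppressMessages(
        vaf_data(chrom = rep("chr1", n), pos = seq_len(n) * 1000L,
                 ref_counts = ref, alt_counts = alt, id = id,
                 samples = object$data$samples))
      list(data = dat, cluster = lab[id %in% dat$variants$id])
    })
  })
}

#' @describeIn vafclust Plot the decomposition. Single sample: VAF histogram
#'   with fitted beta densities and cluster means; two or more samples:
#'   scatter of the first two samples coloured by cluster.
#' @param x,y Plot method arguments.
#' @export
plot.vafclust <- function(x, y, ...) {
  S <- ncol(x$cluster_means)
  cl <- x$assignments$cluster
  cols <- grDevices::hcl.colors(max(cl, na.rm = TRUE), "Dark 3")
  if (S == 1) {
    v <- x$data$vaf[, 1]
    graphics::hist(v, breaks = 40, freq = FALSE, col = "grey90",
                   border = "grey70", xlab = "VAF",
                   main = "Subclone decomposition", ...)
    xs <- seq(0.001, 0.999, length.out = 400)
    for (c_i in seq_len(nrow(x$clusters))) {
      pr <- x$cluster_params[[c_i]][[1]]
      graphics::lines(xs, stats::dbeta(xs, pr$alpha, pr$beta),
                      col = cols[c_i], lwd = 2)
      graphics::abline(v = x$cluster_means[c_i, 1], col = cols[c_i],
                       lty = 2)
    }
    graphics::rug(v, col = cols[ifelse(is.na(cl), 1, cl)])
  } else {
    graphics::plot(x$data$vaf[, 1], x$data$vaf[, 2],
                   col = cols[ifelse(is.na(cl), 1, cl)], pch = 16,
                   xlab = paste("VAF", x$data$samples[1]),
                   ylab = paste("VAF", x$data$samples[2]),
                   main = "Subclone decomposition", ...)
    graphics::points(x$cluster_means[, 1], x$cluster_means[, 2], pch = 3,
                     cex = 2, lwd = 2)
  }
  invisible(x)
}
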