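# Biology-facing quantities: cellular prevalence, purity, founding clone,
# diploid-fraction warnings.

#' Cellular prevalence of a cluster
#'
#' For diploid heterozygous variants the fraction of cells carrying the
#' cluster's mutations is twice the cluster's mean VAF.
#'
#' @param mean_vaf Mean VAF of the cluster in a sample.
#' @return Cellular prevalence `2 * mean_vaf`.
#' @export
cellular_prevalence <- function(mean_vaf) 2 * mean_vaf

#' Estimate per-sample tumor purity from cluster means
#'
#' The founding clone is the cluster whose mean VAF lies closest to 0.5 in
#' the sample (ties broken towards the larger cluster, which carries the
#' most passengers); purity is its cellular prevalence, clamped at 1 with a
#' warning when the mean VAF exceeds 0.5.
#'
#' @param cluster_means Numeric matrix (clusters x samples) of mean VAFs.
#' @param cluster_sizes Integer vector of cluster sizes.
#' @param samples Optional sample names.
#' @return A data frame with one row per sample: `sample`,
#'   `founding_cluster` (row index into `cluster_means`), `purity`, and
#'   `clamped` (logical).
#' @export
estimate_purity <- function(cluster_means, cluster_sizes,
                            samples = NULL) {
  cluster_means <- as.matrix(cluster_means)
  S <- ncol(cluster_means)
  if (is.null(samples)) samples <- colnames(cluster_means)
  if (is.null(samples)) samples <- paste0("S", seq_len(S))
  out <- data.frame(sample = samples, founding_cluster = NA_integer_,
                    purity = NA_real_, clamped = FALSE,
                    stringsAsFactors = FALSE)
  for (s in seq_len(S)) {
    dist <- abs(cluster_means[, s] - 0.5)
    cand <- which(dist == min(dist))
    if (length(cand) > 1) cand <- cand[which.max(cluster_sizes[cand])]
    r <- cellular_prevalence(cluster_means[cand, s])
    out$founding_cluster[s] <- cand
    out$clamped[s] <- r > 1
    out$purity[s] <- min(1, r)
  }
  out
}

#' Diploid-fraction warnings
#'
#' Subclones are detected from diploid passenger variants; when most
#' variants sit inside copy-number altered regions the decomposition may
#' miss subclones. This check computes the fraction of diploid variants
#' overall and within each cluster and emits a warning string for each
#' fraction below 0.5.
#'
#' @param is_diploid Logical vector over all variants.
#' @param cluster Cluster label per variant (NA allowed for unassigned).
#' @return A list with `overall` (fraction), `per_cluster` (named vector)
#'   and `warnings` (character vector, possibly empty).
#' @export
diploid_fraction_check <- function(is_diploid, cluster) {
  overall <- mean(is_diploid)
  warnings <- character(0)
  if (overall < 0.5)
    warnings <- c(warnings, sprintf(
      "only %.1f%% of variants are diploid; subclones dominated by CNVs may be missed",
      100 * overall))
  per_cluster <- tapply(is_diploid, cluster, mean)
  low <- names(per_cluster)[which(per_cluster < 0.5)]
  for (cl in low)
    warnings <- c(warnings, sprintf(
      "cluster %s: only %.1f%% of members are diploid", cl,
      100 * per_cluster[[cl]]))
  list(overall = overall, per_cluster = per_cluster, warnings = warnings)
}
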