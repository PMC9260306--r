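# Assignment of CNV-affected variants to existing clusters with mutant-copy
# multiplicity inference.

#' Average ploidy of a CNV segment
#'
#' In a mixture of diploid cells and cells carrying a segment of total copy
#' number `N`, with the CNV belonging to a cluster of cellular prevalence
#' `2 * vbar_omega`, the population-averaged copy number at the locus is
#' `phi = 2 * (1 + vbar_omega * (N - 2))`. Copy-neutral segments (`N = 2`)
#' give `phi = 2` regardless of the cluster.
#'
#' @param N Total copy number of the segment (integer >= 0).
#' @param vbar_omega Mean VAF of the cluster the CNV belongs to, in
#'   (0, 0.5].
#' @return Average ploidy (> 0); an error is raised if the combination
#'   implies non-positive ploidy (e.g. a full deletion at high prevalence).
#' @export
average_ploidy <- function(N, vbar_omega) {
  phi <- 2 * (1 + vbar_omega * (N - 2))
  if (any(phi <= 0))
    stop("non-positive average ploidy: total copy number ", N,
         " at cluster mean VAF ", vbar_omega,
         " leaves no copies in the mixture")
  phi
}

#' Expected VAF of a CNV-affected variant
#'
#' A variant on `k` mutant copies within a segment of average ploidy `phi`,
#' belonging to an SNV cluster of mean VAF `vbar_g`, has expected VAF
#' `k * 2 * vbar_g / phi`. With `phi = 2` and `k = 1` this reduces to the
#' diploid expectation `vbar_g`.
#'
#' @param k Mutant-copy multiplicity (integer >= 1).
#' @param vbar_g Mean VAF of the variant's SNV cluster.
#' @param phi Average ploidy from [average_ploidy()].
#' @return Expected VAF.
#' @export
expected_vaf <- function(k, vbar_g, phi) k * 2 * vbar_g / phi

#' Assign a CNV segment and its variants to existing clusters
#'
#' CNVs are assumed not to introduce new clusters; the task is to place the
#' segment (cluster `omega`) and each affected variant (cluster `g`,
#' multiplicity `k`) among the clusters already found from diploid
#' variants. For each candidate `omega` the segment's average ploidy is
#' computed per sample; each variant then takes the `(g, k)` pair minimising
#' the summed per-sample absolute residual between observed and expected
#' VAF, with `k` searched over `1..max_copies` (combinations whose expected
#' VAF reaches 1 in any sample are rejected). The segment's `omega` is the
#' candidate minimising the total residual over its variants. Ties are
#' broken towards the smaller residual, then the smaller `k`, then the
#' cluster with the larger mean VAF.
#'
#' @param N Total copy number of the segment.
#' @param vaf Matrix (affected variants x samples) of observed VAFs.
#' @param cluster_means Matrix (clusters x samples) of diploid-cluster mean
#'   VAFs.
#' @param max_copies Upper limit of the multiplicity search (default 10).
#' @param constrain_k If `TRUE`, additionally require `k <= max(N, 2)`.
#' @return A list with `omega` (cluster index of the CNV), `phi` (per-sample
#'   average ploidy under `omega`), `total_residual`, and `snv`, a data
#'   frame per variant: `g`, `k`, `residual`.
#' @export
assign_segment <- function(N, vaf, cluster_means, max_copies = 10,
                           constrain_k = FALSE) {
  vaf <- as.matrix(vaf)
  cluster_means <- as.matrix(cluster_means)
  C <- nrow(cluster_means)
  if (C < 1) stop("no existing clusters: CNVs cannot introduce new clusters")
  if (nrow(vaf) < 1) stop("segment has no affected variants")
  S <- ncol(vaf)
  kmax <- if (constrain_k) min(max_copies, max(N, 2)) else max_copies
  ks <- seq_len(kmax)
  best <- NULL
  for (omega in seq_len(C)) {
    phi <- tryCatch(average_ploidy(N, cluster_means[omega, ]),
                    error = function(e) NULL)
    if (is.null(phi)) next
    # expected VAF for every (g, k): array [g, k, s]
    snv_g <- snv_k <- integer(nrow(vaf))
    snv_res <- numeric(nrow(vaf))
    combos <- expand.grid(g = seq_len(C), k = ks)
    vhat <- array(NA_real_, c(nrow(combos), S))
    for (s in seq_len(S))
      vhat[, s] <- expected_vaf(combos$k, cluster_means[combos$g, s], phi[s])
    ok <- rowSums(vhat >= 1) == 0
    if (!any(ok)) next
    for (i in seq_len(nrow(vaf))) {
      res <- rowSums(abs(matrix(vaf[i, ], nrow(combos), S, byrow = TRUE) -
                         vhat))
      res[!ok] <- Inf
      # round so equal expected VAFs (up to float noise) tie toward small k
      ord <- order(round(res, 9), combos$k, -cluster_means[combos$g, 1])
      pick <- ord[1]
      snv_g[i] <- combos$g[pick]
      snv_k[i] <- combos$k[pick]
      snv_res[i] <- res[pick]
    }
    total <- sum(snv_res)
    if (is.null(best) || total < best$total_residual - 1e-12 ||
        (abs(total - best$total_residual) <= 1e-12 &&
         cluster_means[omega, 1] > cluster_means[best$omega, 1])) {
      best <- list(omega = omega, phi = phi, total_residual = total,
                   snv = data.frame(g = snv_g, k = snv_k,
                                    residual = snv_res))
    }
  }
  if (is.null(best))
    stop("no feasible cluster assignment for segment with total copy number ",
         N)
  best
}
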