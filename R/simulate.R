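# Read-count simulators: synthetic founding-clone pool, Poisson
# down-sampling to a target depth and VAF, single-sample two-subclone
# admixtures, and a multi-sample generator with ordered subclonal
# expansions.

#' Simulate a founding-clone read pool
#'
#' Generates a pool of deeply sequenced heterozygous variants emulating the
#' founding clone of a ~90%-pure tumor: per variant the total read count is
#' Poisson around `depth` and the alternate count binomial at `vaf`.
#' Variants drawn at the boundary (zero or all alternate reads) are
#' redrawn so every pool VAF is interior. Defaults mirror a founding clone
#' of 911 variants at 1394x mean depth and mean VAF 0.45.
#'
#' @param n Number of pool variants.
#' @param depth Mean pool sequencing depth.
#' @param vaf Mean pool VAF.
#' @param seed Optional integer seed.
#' @return A data frame with columns `ref`, `alt`, `u` (pool VAF).
#' @export
sim_pool <- function(n = 911, depth = 1394, vaf = 0.45, seed = NULL) {
  with_seed(seed, {
    tot <- stats::rpois(n, depth)
    alt <- stats::rbinom(n, tot, vaf)
    bad <- which(tot == 0 | alt == 0 | alt == tot)
    while (length(bad)) {
      tot[bad] <- stats::rpois(length(bad), depth)
      alt[bad] <- stats::rbinom(length(bad), tot[bad], vaf)
      bad <- bad[tot[bad] == 0 | alt[bad] == 0 | alt[bad] == tot[bad]]
    }
    data.frame(ref = tot - alt, alt = alt, u = alt / tot)
  })
}

#' Poisson down-sampling of pool reads to a target depth and VAF
#'
#' Given pool counts `(ref0, alt0)` with pool VAF `u`, draws simulated
#' counts `ref ~ Pois(ref0 * eta * (1 - v) / (1 - u))` and
#' `alt ~ Pois(alt0 * eta * v / u)` with `eta = e / (ref0 + alt0)`, so that
#' the expected total depth is exactly `e` and the expected VAF is `v`.
#'
#' @param pool Data frame from [sim_pool()] (columns `ref`, `alt`, `u`), or
#'   any subset of its rows.
#' @param e Target mean sequencing depth.
#' @param v Target mean VAF in (0, 1).
#' @param seed Optional integer seed.
#' @return A data frame with columns `ref`, `alt`.
#' @export
sim_downsample <- function(pool, e, v, seed = NULL) {
  stopifnot(v > 0, v < 1, e > 0)
  with_seed(seed, {
    eta <- e / (pool$ref + pool$alt)
    data.frame(
      ref = stats::rpois(nrow(pool), pool$ref * eta * (1 - v) / (1 - pool$u)),
      alt = stats::rpois(nrow(pool), pool$alt * eta * v / pool$u))
  })
}

#' Simulate a single-sample tumor with one or more subclones
#'
#' For each target subclone VAF, `m` variants are drawn from the pool
#' (without replacement when the pool is large enough) and down-sampled via
#' [sim_downsample()] to the target depth and VAF; the union of subclones
#' forms the admixture. Variants ending with zero alternate reads are
#' dropped by the data container (as they would be by a variant caller);
#' the returned truth covers the retained variants.
#'
#' @param vafs Numeric vector of target subclone mean VAFs (founding clone
#'   first, e.g. `c(0.45, 0.25)`).
#' @param depth Target mean sequencing depth.
#' @param m Variants per subclone (default 100).
#' @param pool Optional pool from [sim_pool()]; generated (with a seed
#'   derived from `seed`) when `NULL`.
#' @param seed Optional integer seed.
#' @return A list with `data` (a `vaf_data` object), `truth` (data frame of
#'   `id`, `subclone`, `target_vaf` for retained variants) and `params`.
#' @export
sim_single_tumor <- function(vafs = c(0.45, 0.25), depth = 300, m = 100,
                             pool = NULL, seed = NULL) {
  with_seed(seed, {
    if (is.null(pool)) pool <- sim_pool()
    K <- length(vafs)
    ref <- alt <- integer(0)
    lab <- integer(0)
    for (k in seq_len(K)) {
      idx <- sample.int(nrow(pool), m, replace = m > nrow(pool))
      ds <- sim_downsample(pool[idx, , drop = FALSE], e = depth, v = vafs[k])
      ref <- c(ref, ds$ref)
      alt <- c(alt, ds$alt)
      lab <- c(lab, rep(k, m))
    }
    n <- length(ref)
    id <- sprintf("v%04d", seq_len(n))
    dat <- suppressMessages(
      vaf_data(chrom = rep("chr1", n), pos = seq_len(n) * 1000L,
               ref_counts = matrix(ref, ncol = 1),
               alt_counts = matrix(alt, ncol = 1),
               samples = "tumor", id = id))
    keep <- id %in% dat$variants$id
    list(data = dat,
         truth = data.frame(id = id[keep], subclone = lab[keep],
                            target_vaf = vafs[lab[keep]],
                            stringsAsFactors = FALSE),
         params = list(vafs = vafs, depth = depth, m = m, seed = seed))
  })
}

# Random rooted tree over K subclones: node 1 is the founding clone, each
# later node attaches to a uniformly chosen earlier node.
random_clone_tree <- function(K) {
  parent <- integer(K)
  if (K > 1)
    for (k in 2:K) parent[k] <- if (k == 2) 1L else sample.int(k - 1L, 1L)
  parent
}

# Tree-consistent prevalences for one sample by uniform stick-breaking:
# each child receives a uniform fraction of its parent's remaining
# (unallocated) prevalence, so parent prevalence >= sum of children.
stick_break_prevalence <- function(parent, purity) {
  K <- length(parent)
  prev <- numeric(K)
  prev[1] <- purity
  remaining <- prev
  for (k in seq_len(K)[-1]) {
    p <- parent[k]
    prev[k] <- remaining[p] * stats::runif(1)
    remaining[p] <- remaining[p] - prev[k]
    remaining[k] <- prev[k]
  }
  prev
}

#' Simulate multi-sample read counts with ordered subclonal expansions
#'
#' Builds a random rooted tree over the subclones (the founding clone at the
#' root) and, independently for each sample, draws tree-consistent cellular
#' prevalences by uniform stick-breaking, so that every node's prevalence is
#' at least the sum of its children's (the order of subclonal expansions is
#' respected). Draws are rejected and repeated while any two subclones'
#' VAFs differ by less than `min_sep` in every sample. Per variant and
#' sample, depth is Poisson around `depth` and the alternate count binomial
#' at VAF = prevalence / 2. Variants are split evenly among subclones.
#'
#' @param n_subclones Number of subclones (default 3).
#' @param n_variants Total variants (default 200).
#' @param n_samples Number of tumor samples (default 2).
#' @param depth Target mean sequencing depth per sample.
#' @param purity Founding-clone prevalence in every sample (default 0.9).
#' @param min_sep Minimum VAF separation (in at least one sample) between
#'   any two subclones (default 0.01).
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling cap for the prevalence draws.
#' @return A list with `data` (a `vaf_data` object), `truth` (data frame of
#'   `id`, `subclone`, plus the per-sample true VAF columns `vaf_<sample>`),
#'   `tree` (parent vector), `prevalence` (subclones x samples matrix) and
#'   `params`.
#' @export
sim_multi_tumor <- function(n_subclones = 3, n_variants = 200,
                            n_samples = 2, depth = 300, purity = 0.9,
                            min_sep = 0.01, seed = NULL, max_tries = 1000) {
  stopifnot(n_variants >= n_subclones)
  with_seed(seed, {
    parent <- random_clone_tree(n_subclones)
    for (try in seq_len(max_tries)) {
      prev <- vapply(seq_len(n_samples),
                     function(s) stick_break_prevalence(parent, purity),
                     numeric(n_subclones))
      prev <- matrix(prev, nrow = n_subclones)
      vafm <- prev / 2
      ok <- TRUE
      if (n_subclones > 1) {
        for (a in 1:(n_subclones - 1)) for (b in (a + 1):n_subclones)
          if (all(abs(vafm[a, ] - vafm[b, ]) < min_sep)) ok <- FALSE
      }
      if (ok) break
    }
    if (!ok) stop("could not draw separated subclone prevalences")
    sizes <- rep(n_variants %/% n_subclones, n_subclones)
    extra <- n_variants - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    lab <- rep(seq_len(n_subclones), sizes)
    n <- length(lab)
    ref <- alt <- matrix(0L, n, n_samples)
    for (s in seq_len(n_samples)) {
      tot <- stats::rpois(n, depth)
      a <- stats::rbinom(n, tot, vafm[lab, s])
      ref[, s] <- tot - a
      alt[, s] <- a
    }
    id <- sprintf("v%04d", seq_len(n))
    samples <- paste0("S", seq_len(n_samples))
    dat <- suppressMessages(
      vaf_data(chrom = rep("chr1", n), pos = seq_len(n) * 1000L,
               ref_counts = ref, alt_counts = alt, samples = samples,
               id = id))
    keep <- id %in% dat$variants$id
    truth <- data.frame(id = id[keep], subclone = lab[keep],
                        stringsAsFactors = FALSE)
    for (s in seq_len(n_samples))
      truth[[paste0("vaf_", samples[s])]] <- vafm[lab[keep], s]
    list(data = dat, truth = truth, tree = parent, prevalence = prev,
         params = list(n_subclones = n_subclones, n_variants = n_variants,
                       n_samples = n_samples, depth = depth,
                       purity = purity, seed = seed))
  })
}
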