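# Phase 1: leaf collapsing and agglomerative merging under the weighted
# negative log-likelihood distance.

#' Collapse near-identical variants into leaf nodes
#'
#' Variants whose VAF vectors (across all samples) lie within Euclidean
#' distance `epsilon` of each other are collapsed into a single leaf before
#' tree building, which shrinks the number of leaves and hence the cost of
#' the merge phase. Leaves are grown greedily over variants sorted by their
#' VAF vector: a variant joins the current leaf only if it is within
#' `epsilon` of every current member (a clique under the epsilon-incidence
#' relation), otherwise it starts a new leaf. `epsilon = 0` returns one leaf
#' per variant.
#'
#' @param vaf Numeric matrix (variants x samples) of VAFs.
#' @param epsilon Collapsing radius (default 0.01).
#' @return A list of integer vectors, each the variant indices of one leaf.
#' @export
collapse_leaves <- function(vaf, epsilon = 0.01) {
  vaf <- as.matrix(vaf)
  n <- nrow(vaf)
  if (n == 0) return(list())
  ord <- do.call(order, c(lapply(seq_len(ncol(vaf)), function(s) vaf[, s]),
                          list(seq_len(n))))
  if (epsilon <= 0) return(as.list(ord))
  leaves <- list()
  cur <- ord[1]
  for (i in ord[-1]) {
    d2 <- rowSums((vaf[cur, , drop = FALSE] -
                   matrix(vaf[i, ], nrow = length(cur), ncol = ncol(vaf),
                          byrow = TRUE))^2)
    if (all(sqrt(d2) < epsilon)) {
      cur <- c(cur, i)
    } else {
      leaves[[length(leaves) + 1]] <- cur
      cur <- i
    }
  }
  leaves[[length(leaves) + 1]] <- cur
  leaves
}

# Per-node sufficient statistics (per sample): member count m, and sums of
# depth, v, v^2, log v, log(1 - v), plus min/max of v over members. These
# are enough to evaluate the merge distance of any node pair in O(S):
# the beta fit needs (ebar, vbar), the log-likelihood sum is
# (a-1)*sum(log v) + (b-1)*sum(log(1-v)) - m*lbeta(a, b), and the weight
# needs var(v) (from the sums) and range(v).
node_stats <- function(V, E, members) {
  Vm <- V[members, , drop = FALSE]
  Em <- E[members, , drop = FALSE]
  list(m = length(members),
       sE = colSums(Em), sV = colSums(Vm), sV2 = colSums(Vm^2),
       sLV = colSums(log(Vm)), sL1V = colSums(log1p(-Vm)),
       mn = apply(Vm, 2, min), mx = apply(Vm, 2, max))
}

# Vectorised pair distance over matched index vectors I, J into the stats
# arrays. Returns the combined distance (max over samples) plus per-sample
# components. `floor_tol` floors degenerate var/range.
.pair_dist_core <- function(m, sE, sV, sV2, sLV, sL1V, mn, mx, I, J,
                            floor_tol = 1e-6) {
  M <- m[I] + m[J]
  SE <- sE[I, , drop = FALSE] + sE[J, , drop = FALSE]
  SV <- sV[I, , drop = FALSE] + sV[J, , drop = FALSE]
  SV2 <- sV2[I, , drop = FALSE] + sV2[J, , drop = FALSE]
  SLV <- sLV[I, , drop = FALSE] + sLV[J, , drop = FALSE]
  SL1V <- sL1V[I, , drop = FALSE] + sL1V[J, , drop = FALSE]
  MN <- pmin(mn[I, , drop = FALSE], mn[J, , drop = FALSE])
  MX <- pmax(mx[I, , drop = FALSE], mx[J, , drop = FALSE])
  ebar <- pmax(SE / M, 1)          # depth floor guards all-absent samples
  vbar <- SV / M                   # V is clipped, so vbar is interior
  a <- vbar * ebar
  b <- (1 - vbar) * ebar
  nll <- -((a - 1) * SLV + (b - 1) * SL1V - M * lbeta(a, b))
  varv <- (SV2 - SV^2 / M) / (M - 1)
  rng <- MX - MN
  degen <- any(varv < floor_tol) || any(rng < floor_tol)
  varv <- pmax(varv, floor_tol)
  rng <- pmax(rng, floor_tol)
  ds <- nll / (M * varv * rng)
  d <- ds[, 1]
  if (ncol(ds) > 1) for (s in 2:ncol(ds)) d <- pmax(d, ds[, s])
  list(d = d, ds = ds, degenerate = degen)
}

#' Merge distance between two clades
#'
#' The distance is the weighted negative log-likelihood that all VAFs of the
#' merged set are drawn from one beta distribution fitted (per sample) to
#' the merged set's mean depth and mean VAF, with weight
#' `1 / ((m1 + m2) * var(v) * range(v))` computed over the merged set. With
#' multiple samples the per-sample distances are combined by taking the
#' maximum, so only variants concordant in every sample look close. Because
#' beta densities can exceed 1, distances can be negative; such pairs merge
#' first. Degenerate merged sets (zero variance or range after clipping)
#' have both quantities floored at `1e-6`, with a warning.
#'
#' @param vaf1,vaf2 VAF matrices (variants x samples) of the two clades.
#' @param depth1,depth2 Matching depth matrices.
#' @param clip Boundary clip applied to VAFs before density evaluation.
#' @return A list with `d` (combined distance), `ds` (per-sample distances),
#'   `w` (per-sample weights) and the per-sample fitted `alpha`, `beta`.
#' @export
pair_distance <- function(vaf1, depth1, vaf2, depth2, clip = 1e-4) {
  V <- clip_vaf(rbind(as.matrix(vaf1), as.matrix(vaf2)), clip)
  E <- rbind(as.matrix(depth1), as.matrix(depth2))
  m1 <- nrow(as.matrix(vaf1))
  M <- nrow(V)
  st1 <- node_stats(V, E, seq_len(m1))
  st2 <- node_stats(V, E, (m1 + 1):M)
  stack2 <- function(a, b) rbind(matrix(a, nrow = 1), matrix(b, nrow = 1))
  m <- c(st1$m, st2$m)
  res <- .pair_dist_core(m = m, sE = stack2(st1$sE, st2$sE),
                         sV = stack2(st1$sV, st2$sV),
                         sV2 = stack2(st1$sV2, st2$sV2),
                         sLV = stack2(st1$sLV, st2$sLV),
                         sL1V = stack2(st1$sL1V, st2$sL1V),
                         mn = stack2(st1$mn, st2$mn),
                         mx = stack2(st1$mx, st2$mx), I = 1L, J = 2L)
  if (res$degenerate)
    warning("zero VAF variance or range in merged set; floored at 1e-6")
  ebar <- pmax(colMeans(E), 1)
  vbar <- colMeans(V)
  varv <- pmax(apply(V, 2, stats::var), 1e-6)
  rng <- pmax(apply(V, 2, max) - apply(V, 2, min), 1e-6)
  list(d = res$d, ds = drop(res$ds), w = 1 / (M * varv * rng),
       alpha = vbar * ebar, beta = (1 - vbar) * ebar)
}

#' Build the agglomerative merge tree
#'
#' Starting from the given leaves, iteratively merges the pair of active
#' nodes with the smallest distance (ties broken by the lexicographically
#' smallest node-id pair) until a single root remains. Distances involving a
#' newly created node are computed fresh from exact sufficient statistics;
#' stale candidate entries are discarded lazily, so the result is identical
#' to full recomputation at every step.
#'
#' @param vaf Numeric matrix (variants x samples) of VAFs (unclipped).
#' @param depth Matching depth matrix.
#' @param leaves List of integer vectors from [collapse_leaves()]; defaults
#'   to one leaf per variant.
#' @param clip Boundary clip for VAFs.
#' @return An object of class `merge_tree`: a list with `members` (list of
#'   variant-index vectors per node), `children` (list of length-2 integer
#'   vectors, `NULL` for leaves), `merges` (data frame logging each merge:
#'   left, right, new node id, distance), `root`, `n_leaves`, and the
#'   clipped `vaf`/`depth` matrices used.
#' @export
build_tree <- function(vaf, depth, leaves = NULL, clip = 1e-4) {
  V <- clip_vaf(as.matrix(vaf), clip)
  E <- as.matrix(depth)
  n <- nrow(V)
  S <- ncol(V)
  if (is.null(leaves)) leaves <- as.list(seq_len(n))
  L <- length(leaves)
  maxN <- 2L * L - 1L
  m <- numeric(maxN)
  sE <- matrix(0, maxN, S); sV <- matrix(0, maxN, S)
  sV2 <- matrix(0, maxN, S); sLV <- matrix(0, maxN, S)
  sL1V <- matrix(0, maxN, S)
  mn <- matrix(Inf, maxN, S); mx <- matrix(-Inf, maxN, S)
  members <- vector("list", maxN)
  children <- vector("list", maxN)
  for (l in seq_len(L)) {
    st <- node_stats(V, E, leaves[[l]])
    m[l] <- st$m; sE[l, ] <- st$sE; sV[l, ] <- st$sV; sV2[l, ] <- st$sV2
    sLV[l, ] <- st$sLV; sL1V[l, ] <- st$sL1V; mn[l, ] <- st$mn
    mx[l, ] <- st$mx
    members[[l]] <- sort(leaves[[l]])
  }
  degen <- FALSE
  pd <- function(I, J) {
    r <- .pair_dist_core(m, sE, sV, sV2, sLV, sL1V, mn, mx, I, J)
    if (r$degenerate) degen <<- TRUE
    r$d
  }
  merges <- data.frame(left = integer(0), right = integer(0),
                       new = integer(0), distance = numeric(0))
  if (L == 1) {
    tree <- list(members = members, children = children, merges = merges,
                 root = 1L, n_leaves = 1L, vaf = V, depth = E)
    class(tree) <- "merge_tree"
    return(tree)
  }
  ci <- rep(seq_len(L - 1L), times = (L - 1L):1L)
  cj <- sequence((L - 1L):1L) + ci
  cd <- pd(ci, cj)
  active <- c(rep(TRUE, L), rep(FALSE, maxN - L))
  nxt <- L
  ml <- mr <- mw <- integer(L - 1L); md <- numeric(L - 1L)
  for (step in seq_len(L - 1L)) {
    valid <- active[ci] & active[cj]
    dd <- cd
    dd[!valid] <- Inf
    best <- min(dd)
    idx <- which(dd == best)
    if (length(idx) > 1L) idx <- idx[order(ci[idx], cj[idx])][1L]
    i <- ci[idx]; j <- cj[idx]
    nxt <- nxt + 1L
    m[nxt] <- m[i] + m[j]
    sE[nxt, ] <- sE[i, ] + sE[j, ]; sV[nxt, ] <- sV[i, ] + sV[j, ]
    sV2[nxt, ] <- sV2[i, ] + sV2[j, ]; sLV[nxt, ] <- sLV[i, ] + sLV[j, ]
    sL1V[nxt, ] <- sL1V[i, ] + sL1V[j, ]
    mn[nxt, ] <- pmin(mn[i, ], mn[j, ]); mx[nxt, ] <- pmax(mx[i, ], mx[j, ])
    members[[nxt]] <- sort(c(members[[i]], members[[j]]))
    children[[nxt]] <- c(i, j)
    active[i] <- active[j] <- FALSE
    active[nxt] <- TRUE
    ml[step] <- i; mr[step] <- j; mw[step] <- nxt; md[step] <- best
    others <- which(active[seq_len(nxt - 1L)])
    # drop stale candidates occasionally to bound memory
    if (length(cd) > 8L * maxN * maxN) {
      keep <- active[ci] & active[cj]
      ci <- ci[keep]; cj <- cj[keep]; cd <- cd[keep]
    }
    if (length(others)) {
      nd <- pd(others, rep(nxt, length(others)))
      ci <- c(ci, others); cj <- c(cj, rep(nxt, length(others)))
      cd <- c(cd, nd)
    }
  }
  if (degen)
    warning("zero VAF variance or range in some merged set; floored at 1e-6")
  merges <- data.frame(left = ml, right = mr, new = mw, distance = md)
  tree <- list(members = members, children = children, merges = merges,
               root = nxt, n_leaves = L, vaf = V, depth = E)
  class(tree) <- "merge_tree"
  tree
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("Merge tree: %d leaves, %d merges, %d variants\n",
              x$n_leaves, nrow(x$merges), length(x$members[[x$root]])))
  invisible(x)
}
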