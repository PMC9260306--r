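# Shared fixtures: small variant/segment tables written to temp files, and a
# reusable founding-clone pool so per-test simulation stays cheap.

write_snv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_snv_table <- function() {
  data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
             pos = c(100L, 200L, 300L, 400L),
             ref = c("A", "C", "G", "T"),
             alt = c("T", "G", "A", "C"),
             tumor_ref_count = c(55L, 70L, 80L, 40L),
             tumor_alt_count = c(45L, 30L, 0L, 60L))
}

shared_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) pool <<- sim_pool(seed = 424242)
    pool
  }
})

# Independent brute-force merge distance: direct evaluation of the weighted
# negative log-likelihood on raw VAF vectors (no sufficient statistics).
brute_pair_distance <- function(v1, e1, v2, e2, clip = 1e-4) {
  V <- pmin(pmax(rbind(as.matrix(v1), as.matrix(v2)), clip), 1 - clip)
  E <- rbind(as.matrix(e1), as.matrix(e2))
  M <- nrow(V)
  ds <- sapply(seq_len(ncol(V)), function(s) {
    ebar <- max(mean(E[, s]), 1)
    vbar <- mean(V[, s])
    a <- vbar * ebar
    b <- (1 - vbar) * ebar
    w <- 1 / (M * max(var(V[, s]), 1e-6) *
                max(max(V[, s]) - min(V[, s]), 1e-6))
    w * sum(-dbeta(V[, s], a, b, log = TRUE))
  })
  max(ds)
}

# Exhaustive greedy merging: recompute every pairwise distance from raw
# members at each step (the oracle build_tree must match).
brute_merge_sequence <- function(V, E, leaves) {
  V <- as.matrix(V); E <- as.matrix(E)
  nodes <- lapply(leaves, identity)
  ids <- seq_along(nodes)
  next_id <- length(nodes)
  seq_out <- list()
  while (length(nodes) > 1) {
    best <- NULL
    for (i in seq_along(nodes)[-length(nodes)])
      for (j in (i + 1):length(nodes)) {
        d <- brute_pair_distance(V[nodes[[i]], , drop = FALSE],
                                 E[nodes[[i]], , drop = FALSE],
                                 V[nodes[[j]], , drop = FALSE],
                                 E[nodes[[j]], , drop = FALSE])
        key <- c(d, ids[i], ids[j])
        if (is.null(best) || d < best$key[1] - 1e-12 ||
            (abs(d - best$key[1]) <= 1e-12 &&
             (ids[i] < best$key[2] ||
              (ids[i] == best$key[2] && ids[j] < best$key[3]))))
          best <- list(i = i, j = j, key = key)
      }
    next_id <- next_id + 1
    seq_out[[length(seq_out) + 1]] <-
      c(left = ids[best$i], right = ids[best$j], new = next_id)
    merged <- sort(c(nodes[[best$i]], nodes[[best$j]]))
    nodes <- c(nodes[-c(best$i, best$j)], list(merged))
    ids <- c(ids[-c(best$i, best$j)], next_id)
  }
  do.call(rbind, seq_out)
}
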