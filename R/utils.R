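# Internal helpers: RNG scoping and deterministic per-clade seed derivation.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# state; seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministic child seed from a root seed and a set of integer ids.
# Ids are sorted first so the seed depends on clade membership only, not on
# tree-traversal order. Arithmetic stays exact in doubles (< 2^53).
derive_seed <- function(root, ids, offset = 0L) {
  p <- 2147483629
  h <- as.double(root) %% p
  for (i in as.double(sort(ids))) h <- (h * 31 + i) %% p
  as.integer((h + as.double(offset)) %% p)
}

# VAFs are clipped away from {0, 1} before any beta log-density is evaluated.
clip_vaf <- function(v, eps = 1e-4) pmin(pmax(v, eps), 1 - eps)

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < tol
}
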