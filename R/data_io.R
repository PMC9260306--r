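# Input containers and readers/writers for variant and copy-number tables.

#' Construct a VAF data set from read-count matrices
#'
#' Bundles per-variant, per-sample reference/alternate read counts into the
#' container consumed by [vafclust()]. VAFs are computed as
#' `alt / (ref + alt)`; germline-heterozygous variants with VAF > 0.5 have
#' their alleles swapped (folded) per sample; variants with zero alternate
#' reads in every sample are dropped (with a message), while variants absent
#' from only some samples are kept with VAF 0 at the observed depth.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param ref_counts,alt_counts Numeric matrices (variants x samples) of
#'   non-negative integer read counts; vectors are taken as single-sample.
#' @param samples Sample names; defaults to the count-matrix column names or
#'   `"S1"`, `"S2"`, ...
#' @param id Optional variant identifiers; defaults to `chrom:pos`.
#' @param germline_het Logical vector (recycled) flagging variants with a
#'   heterozygous germline genotype, which are folded.
#' @param min_depth,max_depth Optional depth filter: a variant is kept only
#'   if its depth lies within `[min_depth, max_depth]` in every sample.
#'   Disabled by default.
#' @return An object of class `vaf_data`: a list with `variants` (data frame
#'   of id, chrom, pos, germline_het), `samples`, and variants x samples
#'   matrices `ref`, `alt`, `depth`, `vaf`, `absent`. Attribute `dropped`
#'   records ids removed by the invariant and depth filters.
#' @export
vaf_data <- function(chrom, pos, ref_counts, alt_counts, samples = NULL,
                     id = NULL, germline_het = FALSE,
                     min_depth = NULL, max_depth = NULL) {
  ref_counts <- as.matrix(ref_counts)
  alt_counts <- as.matrix(alt_counts)
  n <- length(chrom)
  if (length(pos) != n || nrow(ref_counts) != n || nrow(alt_counts) != n)
    stop("chrom, pos and count matrices must agree in length")
  if (ncol(ref_counts) != ncol(alt_counts))
    stop("ref_counts and alt_counts must have the same number of samples")
  if (!all(is_wholenumber(ref_counts)) || !all(is_wholenumber(alt_counts)))
    stop("read counts must be non-negative integers")
  if (any(ref_counts < 0) || any(alt_counts < 0))
    stop("read counts must be non-negative integers")
  S <- ncol(ref_counts)
  if (is.null(samples)) samples <- colnames(ref_counts)
  if (is.null(samples)) samples <- paste0("S", seq_len(S))
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  id <- as.character(id)
  if (anyDuplicated(id)) id <- make.unique(id)
  germline_het <- rep_len(as.logical(germline_het), n)

  storage.mode(ref_counts) <- "double"
  storage.mode(alt_counts) <- "double"

  # fold germline-heterozygous variants: swap alleles where VAF > 0.5
  depth <- ref_counts + alt_counts
  v <- ifelse(depth > 0, alt_counts / depth, 0)
  swap <- germline_het & (v > 0.5)
  if (any(swap)) {
    tmp <- ref_counts[swap]
    ref_counts[swap] <- alt_counts[swap]
    alt_counts[swap] <- tmp
  }
  depth <- ref_counts + alt_counts
  vaf <- ifelse(depth > 0, alt_counts / depth, 0)

  dropped <- character(0)
  keep <- rowSums(alt_counts) > 0
  if (any(!keep)) {
    dropped <- c(dropped, id[!keep])
    message(sum(!keep), " variant(s) with no alternate reads in any sample ",
            "dropped: ", paste(utils::head(id[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ..." else "")
  }
  if (!is.null(min_depth) || !is.null(max_depth)) {
    lo <- if (is.null(min_depth)) 0 else min_depth
    hi <- if (is.null(max_depth)) Inf else max_depth
    ok <- rowSums(depth < lo | depth > hi) == 0
    bad <- keep & !ok
    if (any(bad)) {
      dropped <- c(dropped, id[bad])
      message(sum(bad), " variant(s) outside the configured depth range ",
              "dropped")
    }
    keep <- keep & ok
  }

  dimnames(ref_counts) <- dimnames(alt_counts) <- dimnames(vaf) <-
    dimnames(depth) <- list(id, samples)
  out <- structure(list(
    variants = data.frame(id = id, chrom = as.character(chrom),
                          pos = as.integer(pos),
                          germline_het = germline_het,
                          stringsAsFactors = FALSE)[keep, , drop = FALSE],
    samples = samples,
    ref = ref_counts[keep, , drop = FALSE],
    alt = alt_counts[keep, , drop = FALSE],
    depth = depth[keep, , drop = FALSE],
    vaf = vaf[keep, , drop = FALSE],
    absent = (alt_counts == 0)[keep, , drop = FALSE]
  ), class = "vaf_data")
  rownames(out$variants) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' @export
print.vaf_data <- function(x, ...) {
  cat(sprintf("VAF data set: %d variants, %d sample(s) [%s]\n",
              nrow(x$variants), length(x$samples),
              paste(x$samples, collapse = ", ")))
  cat(sprintf("  mean depth %.1f, mean VAF %.3f\n",
              mean(x$depth), mean(x$vaf)))
  if (length(attr(x, "dropped")))
    cat(sprintf("  %d variant(s) dropped on input\n",
                length(attr(x, "dropped"))))
  invisible(x)
}

#' Number of variants in a `vaf_data` set
#' @param x A `vaf_data` object.
#' @export
nvariants <- function(x) nrow(x$variants)

#' Fold germline-heterozygous variants
#'
#' For every variant flagged `germline_het`, swaps reference and alternate
#' read counts in each sample where the VAF exceeds 0.5, so that the folded
#' VAF is `1 - v`. Depth is invariant; the operation is idempotent;
#' unflagged (somatic) variants pass through unchanged.
#'
#' @param x A `vaf_data` object.
#' @return The folded `vaf_data` object.
#' @export
fold_germline_het <- function(x) {
  stopifnot(inherits(x, "vaf_data"))
  swap <- x$variants$germline_het & (x$vaf > 0.5)
  if (any(swap)) {
    tmp <- x$ref[swap]
    x$ref[swap] <- x$alt[swap]
    x$alt[swap] <- tmp
    x$vaf <- ifelse(x$depth > 0, x$alt / x$depth, 0)
    x$absent <- x$alt == 0
  }
  x
}

#' Read a tab-separated variant table
#'
#' The expected layout has a header with columns `chrom`, `pos`, `ref`,
#' `alt` (alleles) followed by one pair `<sample>_ref_count`,
#' `<sample>_alt_count` per sample. Optional columns `id` and
#' `germline_het` (logical or 0/1) are honoured. Rows violating the
#' container invariants (no alternate reads anywhere; depth outside a
#' configured range) are reported and dropped.
#'
#' @param path Path to the TSV file.
#' @param sample_names Optional sample names; inferred from the
#'   `*_ref_count` columns when `NULL`.
#' @inheritParams vaf_data
#' @return A `vaf_data` object.
#' @export
read_snv_table <- function(path, sample_names = NULL,
                           min_depth = NULL, max_depth = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("chrom", "pos", "ref", "alt"))
    if (!col %in% names(tab))
      stop("required column '", col, "' missing from ", path)
  if (is.null(sample_names)) {
    rc <- grep("_ref_count$", names(tab), value = TRUE)
    sample_names <- sub("_ref_count$", "", rc)
    if (!length(sample_names))
      stop("no '<sample>_ref_count' columns found in ", path)
  }
  refs <- paste0(sample_names, "_ref_count")
  alts <- paste0(sample_names, "_alt_count")
  for (col in c(refs, alts))
    if (!col %in% names(tab))
      stop("required column '", col, "' missing from ", path)
  ref_m <- as.matrix(tab[refs])
  alt_m <- as.matrix(tab[alts])
  for (m in list(ref_m, alt_m)) {
    bad <- which(!is_wholenumber(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-integer read count at row ", bad[1, 1], " of ", path)
  }
  vaf_data(chrom = tab$chrom, pos = tab$pos,
           ref_counts = ref_m, alt_counts = alt_m,
           samples = sample_names,
           id = if ("id" %in% names(tab)) tab$id else NULL,
           germline_het = if ("germline_het" %in% names(tab))
             as.logical(tab$germline_het) else FALSE,
           min_depth = min_depth, max_depth = max_depth)
}

#' Read per-sample allelic depths from a VCF file
#'
#' Extracts the `AD` FORMAT field (reference and first alternate depth) for
#' the requested samples and builds the same container as
#' [read_snv_table()]. Requires the `vcfR` package.
#'
#' @param path Path to a VCF file (uncompressed or bgzipped).
#' @param sample_names Samples to extract; defaults to all samples.
#' @inheritParams vaf_data
#' @return A `vaf_data` object.
#' @export
read_snv_vcf <- function(path, sample_names = NULL,
                         min_depth = NULL, max_depth = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_snv_vcf() requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(sample_names)) sample_names <- colnames(ad)
  ad <- ad[, sample_names, drop = FALSE]
  split2 <- function(k) {
    m <- vapply(strsplit(ad[, k], ","),
                function(p) as.numeric(p[1:2]), numeric(2))
    t(m)
  }
  ref_m <- sapply(seq_along(sample_names), function(k) split2(k)[, 1])
  alt_m <- sapply(seq_along(sample_names), function(k) split2(k)[, 2])
  ref_m <- matrix(ref_m, ncol = length(sample_names))
  alt_m <- matrix(alt_m, ncol = length(sample_names))
  ref_m[is.na(ref_m)] <- 0
  alt_m[is.na(alt_m)] <- 0
  fix <- vcfR::getFIX(vcf)
  vaf_data(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
           ref_counts = ref_m, alt_counts = alt_m, samples = sample_names,
           min_depth = min_depth, max_depth = max_depth)
}

#' Read a copy-number segment table
#'
#' Tab-separated columns `chrom`, `start`, `end`, `total_cn` and optional
#' `segment_id`. Coordinates are 1-based inclusive by default; `bed = TRUE`
#' converts 0-based half-open (BED) input. Segments with total copy number 2
#' are copy-neutral.
#'
#' @param path Path to the TSV file.
#' @param bed Logical; input uses BED coordinates.
#' @return A data frame with columns `segment_id`, `chrom`, `start`, `end`,
#'   `total_cn`.
#' @export
read_cnv_table <- function(path, bed = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("chrom", "start", "end", "total_cn"))
    if (!col %in% names(tab))
      stop("required column '", col, "' missing from ", path)
  if (bed) tab$start <- tab$start + 1L
  if (!all(is_wholenumber(tab$total_cn)) || any(tab$total_cn < 0))
    stop("total_cn must be a non-negative integer")
  if (any(tab$start > tab$end)) stop("segment start exceeds end")
  data.frame(
    segment_id = if ("segment_id" %in% names(tab)) as.character(tab$segment_id)
                 else paste0("seg", seq_len(nrow(tab))),
    chrom = as.character(tab$chrom),
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    total_cn = as.integer(tab$total_cn),
    stringsAsFactors = FALSE)
}

#' Split variants by copy-number status
#'
#' A variant is CNV-affected iff its position falls inside any segment whose
#' total copy number differs from 2 (1-based inclusive overlap); all other
#' variants are treated as diploid. Segment chromosomes absent from the
#' variant table trigger a warning.
#'
#' @param x A `vaf_data` object.
#' @param segments A segment data frame as returned by [read_cnv_table()],
#'   or `NULL` (all variants diploid).
#' @return A list with `diploid` (integer indices into `x`), and `affected`,
#'   a data frame of `index`, `segment_id`, `total_cn` for variants inside
#'   non-neutral segments.
#' @export
partition_by_cn_status <- function(x, segments = NULL) {
  stopifnot(inherits(x, "vaf_data"))
  n <- nvariants(x)
  if (is.null(segments) || nrow(segments) == 0)
    return(list(diploid = seq_len(n),
                affected = data.frame(index = integer(0),
                                      segment_id = character(0),
                                      total_cn = integer(0),
                                      stringsAsFactors = FALSE)))
  unmatched <- setdiff(unique(segments$chrom), unique(x$variants$chrom))
  if (length(unmatched))
    warning("segment chromosome(s) not present among variants: ",
            paste(unmatched, collapse = ", "))
  seg_idx <- rep(NA_integer_, n)
  nonneutral <- which(segments$total_cn != 2L)
  for (k in nonneutral) {
    hit <- which(is.na(seg_idx) &
                 x$variants$chrom == segments$chrom[k] &
                 x$variants$pos >= segments$start[k] &
                 x$variants$pos <= segments$end[k])
    seg_idx[hit] <- k
  }
  aff <- which(!is.na(seg_idx))
  list(diploid = which(is.na(seg_idx)),
       affected = data.frame(index = aff,
                             segment_id = segments$segment_id[seg_idx[aff]],
                             total_cn = segments$total_cn[seg_idx[aff]],
                             stringsAsFactors = FALSE))
}

#' Write decomposition results to disk
#'
#' Writes `<prefix>_assignments.tsv` (one row per variant: cluster, per-sample
#' VAF and confidence, multiplicity for CNV-affected variants) and
#' `<prefix>_summary.json` (per-sample purity and founding cluster,
#' per-cluster prevalence, diploid fractions, warnings).
#'
#' @param fit A fitted [vafclust()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_vafclust <- function(fit, prefix) {
  stopifnot(inherits(fit, "vafclust"))
  ap <- paste0(prefix, "_assignments.tsv")
  sp <- paste0(prefix, "_summary.json")
  utils::write.table(fit$assignments, ap, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- list(
    n_variants = nrow(fit$assignments),
    n_clusters = nrow(fit$clusters),
    samples = fit$data$samples,
    purity = as.list(stats::setNames(fit$purity$purity, fit$purity$sample)),
    founding_cluster = as.list(stats::setNames(fit$purity$founding_cluster,
                                               fit$purity$sample)),
    prevalence = fit$prevalence,
    diploid_fraction = fit$diploid_fraction,
    warnings = fit$warnings)
  jsonlite::write_json(summ, sp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(assignments = ap, summary = sp))
}

#' Read back an assignments table written by [write_vafclust()]
#' @param path Path to the `*_assignments.tsv` file.
#' @return A data frame.
#' @export
read_assignments <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
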