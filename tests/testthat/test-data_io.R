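test_that("VAFs are computed from counts and invariant-violating rows are dropped", {
  path <- write_snv_fixture(toy_snv_table())
  expect_message(dat <- read_snv_table(path), "dropped")
  expect_s3_class(dat, "vaf_data")
  expect_equal(nvariants(dat), 3)                 # chr2:300 has alt = 0
  expect_equal(attr(dat, "dropped"), "chr2:300")
  expect_equal(unname(dat$vaf[1, 1]), 45 / 100)
  expect_equal(unname(dat$depth[1, 1]), 100)
})

test_that("missing and malformed columns give hard errors naming the offender", {
  df <- toy_snv_table()
  path <- write_snv_fixture(df[, setdiff(names(df), "pos")])
  expect_error(read_snv_table(path), "'pos'")
  df2 <- toy_snv_table()
  path2 <- write_snv_fixture(df2)
  expect_error(read_snv_table(path2, sample_names = "normal"),
               "normal_ref_count")
  df3 <- toy_snv_table()
  df3$tumor_alt_count <- df3$tumor_alt_count + 0.5
  expect_error(read_snv_table(write_snv_fixture(df3)), "non-integer")
})

test_that("depth filter drops out-of-range variants only when configured", {
  df <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L), ref = "A", alt = "T",
                   t_ref_count = c(10L, 100L, 300L),
                   t_alt_count = c(5L, 60L, 150L))
  path <- write_snv_fixture(df)
  expect_equal(nvariants(read_snv_table(path)), 3)
  filtered <- suppressMessages(
    read_snv_table(path, min_depth = 20, max_depth = 500))
  expect_equal(nvariants(filtered), 2)
  expect_true(all(filtered$depth >= 20 & filtered$depth <= 500))
})

test_that("germline-heterozygous folding swaps alleles above 0.5 and is idempotent", {
  dat <- vaf_data(chrom = c("chr1", "chr1", "chr1"), pos = c(1L, 2L, 3L),
                  ref_counts = c(30L, 50L, 15L), alt_counts = c(70L, 50L, 85L),
                  germline_het = c(TRUE, TRUE, FALSE))
  expect_equal(unname(dat$vaf[, 1]), c(0.3, 0.5, 0.85))  # folded, boundary, somatic
  expect_equal(unname(dat$depth[, 1]), c(100, 100, 100)) # depth invariant
  refolded <- fold_germline_het(dat)
  expect_identical(refolded$vaf, dat$vaf)
})

test_that("copy-number partition is a disjoint, exhaustive split with 1-based inclusive overlap", {
  dat <- vaf_data(chrom = rep("chr1", 10), pos = as.integer(seq(10, 100, 10)),
                  ref_counts = rep(60L, 10), alt_counts = rep(40L, 10))
  segs <- data.frame(segment_id = c("s1", "s2"), chrom = "chr1",
                     start = c(25L, 65L), end = c(55L, 95L),
                     total_cn = c(1L, 2L))
  cn <- partition_by_cn_status(dat, segs)
  # s1 (N=1) covers pos 30,40,50; s2 is neutral and ignored
  expect_equal(cn$affected$index, c(3L, 4L, 5L))
  expect_equal(sort(c(cn$diploid, cn$affected$index)), 1:10)
  expect_length(intersect(cn$diploid, cn$affected$index), 0)
  # boundary inclusivity
  segs2 <- data.frame(segment_id = "s", chrom = "chr1", start = 50L,
                      end = 150L, total_cn = 3L)
  expect_true(5L %in% partition_by_cn_status(dat, segs2)$affected$index)
  expect_warning(partition_by_cn_status(dat,
    data.frame(segment_id = "x", chrom = "chr9", start = 1L, end = 2L,
               total_cn = 4L)), "chr9")
})

test_that("BED-coordinate segment input is converted to 1-based inclusive", {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(chrom = "chr1", start = 49L, end = 150L,
                         total_cn = 3L),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  segs <- read_cnv_table(path, bed = TRUE)
  expect_equal(segs$start, 50L)
  expect_equal(segs$end, 150L)
})

test_that("results round-trip through the assignments table", {
  sim <- sim_single_tumor(c(0.45, 0.2), depth = 300, m = 40,
                          pool = shared_pool(), seed = 5)
  fit <- vafclust(sim$data, seed = 5)
  prefix <- tempfile()
  paths <- write_vafclust(fit, prefix)
  back <- read_assignments(paths["assignments"])
  expect_equal(back$cluster, fit$assignments$cluster)
  expect_equal(back$id, fit$assignments$id)
  expect_equal(nrow(back), nrow(fit$assignments))
  summ <- jsonlite::read_json(paths["summary"])
  expect_equal(summ$n_clusters, nrow(fit$clusters))
})

test_that("VCF allelic depths load into the same container as the TSV path", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ttumor",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:55,45",
    "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT:AD\t0/1:70,30")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  dat <- read_snv_vcf(path)
  expect_equal(nvariants(dat), 2)
  expect_equal(unname(dat$vaf[, 1]), c(0.45, 0.30))
})
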