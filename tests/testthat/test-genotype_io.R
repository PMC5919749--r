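test_that("VCF genotypes decode to alt-allele dosages with NA for missing", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("chr1", "100", ".", "A", "C", "45", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", ".", "G", "T", "30", "PASS", ".", "GT",
          "./.", "1/1", "0/0", sep = "\t")), vcf)
  g <- read_genotypes(vcf, "vcf",
                      pops = c(s1 = "A", s2 = "A", s3 = "B"))
  expect_equal(unname(g$dosages[, 1L]), c(0L, 1L, 2L))
  expect_true(is.na(g$dosages["s1", 2L]))
  expect_false(identical(g$dosages["s1", 2L], 0L))
  expect_equal(g$variants$qual, c(45, 30))
})

test_that("write/read round trips preserve the genotype matrix", {
  set.seed(42)
  g <- random_genotypes(n = 8, m = 14, miss = 0.1)
  for (fmt in c("vcf", "table")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_genotypes(g, path, fmt)
    g2 <- read_genotypes(path, fmt,
                         pops = stats::setNames(g$pop_labels, g$samples))
    expect_equal(unname(g2$dosages), unname(g$dosages), info = fmt)
    expect_equal(g2$variants$chrom, g$variants$chrom, info = fmt)
    expect_equal(g2$variants$pos, g$variants$pos, info = fmt)
    expect_equal(g2$pop_labels, g$pop_labels, info = fmt)
  }
  # PLINK drops qual but must round-trip dosages and labels via .fam
  prefix <- tempfile()
  write_genotypes(g, prefix, "plink")
  g3 <- read_genotypes(prefix, "plink")
  expect_equal(unname(g3$dosages), unname(g$dosages))
  expect_equal(g3$pop_labels, g$pop_labels)
  # empty-variant matrix still writes a readable header-only VCF
  g0 <- genotype_matrix(g$variants[0, ], g$samples, g$pop_labels,
                        g$dosages[, 0, drop = FALSE])
  p0 <- tempfile(fileext = ".vcf")
  write_genotypes(g0, p0, "vcf")
  expect_equal(nrow(read_genotypes(p0, "vcf",
    pops = stats::setNames(g$pop_labels, g$samples))$variants), 0L)
})

test_that("phased VCF yields haplotype panels consistent with dosages", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "100", ".", "A", "C", ".", "PASS", ".", "GT",
          "0|1", "1|1", sep = "\t")), vcf)
  panels <- read_haplotypes(vcf, "vcf")
  expect_length(panels, 1L)
  expect_equal(as.vector(panels$chr1$haplotypes), c(0L, 1L, 1L, 1L))
  # cross-reader consistency: summed haplotype pairs equal read dosages
  g <- read_genotypes(vcf, "vcf", pops = c(s1 = "A", s2 = "B"))
  expect_equal(unname(panel_dosages(panels$chr1)), unname(g$dosages))
})

test_that("unphased or missing calls are rejected by the haplotype reader", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("chr1", "100", ".", "A", "C", ".", "PASS", ".", "GT", "0/1",
          sep = "\t")), vcf)
  expect_error(read_haplotypes(vcf, "vcf"), "unphased")
  vcf2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("chr1", "100", ".", "A", "C", ".", "PASS", ".", "GT", ".|.",
          sep = "\t")), vcf2)
  expect_error(read_haplotypes(vcf2, "vcf"), "[Mm]issing")
})

test_that("invalid genotype containers are rejected", {
  v <- data.frame(chrom = "chr1", pos = c(10L, 5L), ref = "A", alt = "C",
                  qual = NA_real_)
  expect_error(genotype_matrix(v, c("a", "b"), c("A", "B"),
                               matrix(0L, 2, 2)), "unsorted")
  v2 <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "C")
  expect_error(genotype_matrix(v2, c("a", "b"), c("A", NA),
                               matrix(0L, 2, 1)), "population label")
})

test_that("variant filters apply the qual/chrom/call-rate/MAF rules in order", {
  # 10 samples; each variant engineered to fail exactly one rule first
  n <- 10L
  mk <- function(dos) dos
  dos <- cbind(
    rep(1L, n),                                   # passes everything
    c(rep(NA_integer_, 2L), rep(1L, 8L)),         # call rate 0.8 -> fail
    c(1L, rep(0L, n - 1L)),                       # MAF 0.05 boundary -> keep
    c(rep(0L, n - 1L), 1L),                       # qual below 20 -> fail qual
    rep(c(0L, 2L), n / 2),                        # on scaffold -> fail chrom
    c(rep(0L, n))                                 # all ref: MAF 0 -> fail maf
  )
  variants <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1",
                                   "scaffold_7", "chr2"),
                         pos = c(10L, 20L, 30L, 40L, 10L, 10L),
                         ref = "A", alt = "C",
                         qual = c(50, 50, 50, 10, 50, 50))
  g <- genotype_matrix(variants, sprintf("s%d", 1:n),
                       rep(c("A", "B"), each = 5L), dos)
  res <- apply_variant_filters(g, variant_filter_spec(
    allowed_chroms = c("chr1", "chr2")))
  rep <- res$report
  expect_equal(rep$n_input, 6L)
  expect_equal(rep$n_failed_qual, 1L)
  expect_equal(rep$n_failed_chrom, 1L)
  expect_equal(rep$n_failed_call_rate, 1L)
  expect_equal(rep$n_failed_maf, 1L)
  expect_equal(rep$n_passed, 2L)
  expect_equal(rep$n_passed + rep$n_failed_qual + rep$n_failed_chrom +
                 rep$n_failed_call_rate + rep$n_failed_maf, rep$n_input)
  # MAF exactly at the threshold is retained (inclusive >=)
  expect_true(30L %in% res$genotypes$variants$pos)
  # idempotence: filtering the filtered set changes nothing
  res2 <- apply_variant_filters(res$genotypes, variant_filter_spec(
    allowed_chroms = c("chr1", "chr2")))
  expect_equal(res2$genotypes$variants, res$genotypes$variants)
  expect_equal(res2$report$n_passed, res$report$n_passed)
})

test_that("population split partitions samples and preserves variants", {
  set.seed(7)
  g <- random_genotypes(n = 8, m = 12, miss = 0.05)
  sp <- split_by_population(g)
  expect_setequal(names(sp), c("A", "B"))
  expect_equal(sort(c(sp$A$samples, sp$B$samples)), sort(g$samples))
  expect_equal(sp$A$variants, g$variants)
  # stratified allele frequencies match masked-column computation
  af <- function(d) colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  expect_equal(af(sp$A$dosages), af(g$dosages[g$pop_labels == "A", ]))
  expect_equal(af(sp$B$dosages), af(g$dosages[g$pop_labels == "B", ]))
})
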