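#' Construct a genotype matrix object
#'
#' The central genotype container of the package: an ordered variant table,
#' sample ids with population labels, and a samples x variants alt-allele
#' dosage matrix. Dosages are coded 0/1/2 (count of alt alleles); missing
#' genotypes are `NA`, never 0.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt` (single-character alleles) and optionally `qual`
#'   (Phred-like quality, `NA` when absent).
#' @param samples character vector of sample ids.
#' @param pop_labels character vector of population labels, one per sample.
#' @param dosages integer matrix, `length(samples)` rows x `nrow(variants)`
#'   columns, values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, samples, pop_labels, dosages) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (is.null(variants$qual)) variants$qual <- NA_real_
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (length(pop_labels) != length(samples))
    stop("every sample needs a population label")
  if (anyNA(pop_labels))
    stop("sample without population label: ",
         paste(samples[is.na(pop_labels)], collapse = ", "))
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants))
    stop("dosage dimensions do not match samples x variants")
  if (any(variants$pos < 1L)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  ok <- dosages %in% c(0L, 1L, 2L) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  # per chromosome, positions strictly increasing (sortedness + no duplicates)
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("unsorted or duplicated positions on chromosome ", ch)
  }
  rownames(dosages) <- samples
  structure(list(variants = variants,
                 samples = as.character(samples),
                 pop_labels = as.character(pop_labels),
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(table(x$pop_labels)),
                    as.integer(table(x$pop_labels))), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a phased haplotype panel
#'
#' One chromosome of fully phased binary haplotypes: a 2N x M matrix with
#' 0 = ref, 1 = alt and no missing entries. Rows come in sample pairs.
#'
#' @param chrom chromosome name.
#' @param positions strictly increasing 1-based bp positions (length M).
#' @param haplotypes 2N x M integer matrix of 0/1.
#' @param sample_of_haplotype character vector of length 2N mapping each
#'   row to its sample id (each sample appears exactly twice, consecutively).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(chrom, positions, haplotypes, sample_of_haplotype) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  positions <- as.integer(positions)
  if (anyNA(haplotypes)) stop("haplotype panel must be fully phased (no NA)")
  if (!all(haplotypes %in% c(0L, 1L))) stop("haplotypes must be binary 0/1")
  if (ncol(haplotypes) != length(positions))
    stop("column count must equal number of positions")
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  if (nrow(haplotypes) != length(sample_of_haplotype) ||
      nrow(haplotypes) %% 2L != 0L)
    stop("haplotype rows must pair up per sample")
  structure(list(chrom = as.character(chrom), positions = positions,
                 haplotypes = haplotypes,
                 sample_of_haplotype = as.character(sample_of_haplotype)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$haplotypes), "haplotypes x",
      length(x$positions), "SNPs on", x$chrom, "\n")
  invisible(x)
}

# Resolve a population-label argument: either a named character vector or a
# path to a two-column (sample, label) TSV. Returns labels ordered by
# `samples`; errors on any unlabeled sample.
resolve_pop_labels <- function(pops, samples) {
  if (is.null(pops)) stop("population labels required (named vector or file)")
  if (is.character(pops) && length(pops) == 1L && file.exists(pops)) {
    tab <- utils::read.table(pops, header = FALSE, sep = "\t",
                             col.names = c("sample", "label"),
                             colClasses = "character")
    pops <- stats::setNames(tab$label, tab$sample)
  }
  lab <- pops[samples]
  if (anyNA(lab))
    stop("sample without population label: ",
         paste(samples[is.na(lab)], collapse = ", "))
  unname(lab)
}

parse_gt_dosage <- function(gt) {
  # genotype strings -> dosage; "./." and ".|." -> NA; multi-allelic rejected
  out <- rep(NA_integer_, length(gt))
  gt <- sub(":.*$", "", gt)
  known <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  miss <- gt %in% c("./.", ".|.", ".") | is.na(gt)
  out[!miss] <- known[gt[!miss]]
  bad <- !miss & is.na(out)
  if (any(bad))
    stop("unsupported genotype call(s): ",
         paste(unique(gt[bad]), collapse = ", "))
  out
}

read_vcf_body <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) > 0L && any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic sites are not supported (reject policy)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (nrow(fix) > 0L && is.null(gt))
    stop("VCF has no GT field")
  list(fix = fix, gt = gt,
       samples = if (is.null(gt)) character(0) else colnames(gt))
}

#' Read a two-population genotype matrix
#'
#' Supported formats: VCF 4.x (`"vcf"`, biallelic sites, GT field), a plain
#' tab-separated dosage table (`"table"`: columns chrom, pos, ref, alt,
#' qual, then one 0/1/2/NA column per sample), and PLINK binary
#' (`"plink"`: path is the prefix of a .bed/.bim/.fam trio).
#'
#' @param path input file (or PLINK prefix).
#' @param format one of `"vcf"`, `"table"`, `"plink"`.
#' @param pops population labels: a named character vector (names = sample
#'   ids) or the path of a two-column sample/label TSV. For PLINK input the
#'   .fam family-id column is used when `pops` is `NULL`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "table", "plink"),
                           pops = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    if (!file.exists(path)) stop("file not found: ", path)
    b <- read_vcf_body(path)
    variants <- data.frame(chrom = b$fix$CHROM, pos = as.integer(b$fix$POS),
                           ref = b$fix$REF, alt = b$fix$ALT,
                           qual = suppressWarnings(as.numeric(b$fix$QUAL)),
                           stringsAsFactors = FALSE)
    dos <- if (nrow(variants) == 0L)
      matrix(integer(0), nrow = length(b$samples), ncol = 0L)
    else t(apply(b$gt, 2L, parse_gt_dosage))
    if (nrow(variants) == 1L) dos <- matrix(as.integer(dos), ncol = 1L)
    genotype_matrix(variants, b$samples,
                    resolve_pop_labels(pops, b$samples), dos)
  } else if (format == "table") {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    meta <- c("chrom", "pos", "ref", "alt", "qual")
    if (!all(meta %in% names(tab))) stop("table is missing metadata columns")
    samples <- setdiff(names(tab), meta)
    variants <- tab[meta]
    dos <- t(as.matrix(tab[samples]))
    genotype_matrix(variants, samples,
                    resolve_pop_labels(pops, samples), dos)
  } else {
    read_plink(path, pops)
  }
}

#' Read phased haplotypes
#'
#' Accepts a phased VCF (all GT calls must use the `|` separator and carry
#' no missing alleles) or a haplotype table (`"table"`: columns chrom, pos,
#' then two 0/1 columns per sample named `<sample>_h1`, `<sample>_h2`).
#'
#' @param path input file.
#' @param format `"vcf"` or `"table"`.
#' @return A named list of [haplotype_panel()] objects, one per chromosome.
#' @export
read_haplotypes <- function(path, format = c("vcf", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    b <- read_vcf_body(path)
    gt <- sub(":.*$", "", b$gt)
    if (anyNA(gt)) stop("missing allele in a phased record")
    if (any(grepl("/", gt, fixed = TRUE)))
      stop("unphased genotype separator '/' encountered; panel must be phased")
    if (any(grepl(".", gt, fixed = TRUE)))
      stop("missing allele in a phased record")
    a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
    a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
    samples <- b$samples
    # interleave the two haplotypes of each sample: rows 2i-1, 2i
    H <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(b$fix))
    H[seq(1L, nrow(H), by = 2L), ] <- t(a1)
    H[seq(2L, nrow(H), by = 2L), ] <- t(a2)
    soh <- rep(samples, each = 2L)
    chroms <- b$fix$CHROM
    pos <- as.integer(b$fix$POS)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    hcols <- setdiff(names(tab), c("chrom", "pos"))
    if (!all(grepl("_h[12]$", hcols)))
      stop("haplotype columns must be named <sample>_h1 / <sample>_h2")
    H <- t(as.matrix(tab[hcols]))
    if (anyNA(H)) stop("missing allele in a phased record")
    soh <- sub("_h[12]$", "", hcols)
    chroms <- as.character(tab$chrom)
    pos <- as.integer(tab$pos)
  }
  out <- list()
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    out[[ch]] <- haplotype_panel(ch, pos[idx],
                                 H[, idx, drop = FALSE], soh)
  }
  out
}

#' Collapse a haplotype panel to sample dosages
#'
#' Sums each sample's haplotype pair; by construction equals the dosage
#' column block of the same chromosome.
#'
#' @param panel a [haplotype_panel()].
#' @return integer matrix, samples x SNPs.
#' @export
panel_dosages <- function(panel) {
  H <- panel$haplotypes
  odd <- seq(1L, nrow(H), by = 2L)
  d <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  rownames(d) <- panel$sample_of_haplotype[odd]
  d
}

#' Variant filter settings
#'
#' Defaults follow standard reduced-representation SNP QC: call rate >= 90%,
#' pooled minor allele frequency >= 5%, variant quality >= 20, and an
#' optional whitelist of assembled chromosomes (unplaced scaffolds dropped).
#'
#' @param min_call_rate minimum fraction of non-missing calls (inclusive).
#' @param min_maf minimum pooled minor allele frequency (inclusive).
#' @param min_qual minimum variant quality; skipped where qual is absent.
#' @param allowed_chroms character vector of retained chromosome names, or
#'   `NULL` to keep all.
#' @return An object of class `variant_filter_spec`.
#' @export
variant_filter_spec <- function(min_call_rate = 0.90, min_maf = 0.05,
                                min_qual = 20, allowed_chroms = NULL) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_qual = min_qual, allowed_chroms = allowed_chroms),
            class = "variant_filter_spec")
}

#' Apply variant filters
#'
#' Retains variants passing all rules; each dropped variant is attributed to
#' its first failing rule in the fixed order qual, chromosome, call rate,
#' MAF, so report counts are deterministic. MAF is computed over non-missing
#' dosages pooled across both populations.
#'
#' @param g a [genotype_matrix()].
#' @param spec a [variant_filter_spec()].
#' @return list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (class `filter_report`: n_input, n_failed_qual,
#'   n_failed_chrom, n_failed_call_rate, n_failed_maf, n_passed).
#' @export
apply_variant_filters <- function(g, spec = variant_filter_spec()) {
  n <- ncol(g$dosages)
  n_nonmiss <- colSums(!is.na(g$dosages))
  call_rate <- n_nonmiss / nrow(g$dosages)
  alt_count <- colSums(g$dosages, na.rm = TRUE)
  af <- ifelse(n_nonmiss > 0L, alt_count / (2 * n_nonmiss), NA_real_)
  maf <- pmin(af, 1 - af)
  fail_qual <- !is.na(g$variants$qual) & g$variants$qual < spec$min_qual
  fail_chrom <- if (is.null(spec$allowed_chroms)) rep(FALSE, n)
                else !(g$variants$chrom %in% spec$allowed_chroms)
  fail_cr <- call_rate < spec$min_call_rate
  fail_maf <- is.na(maf) | maf < spec$min_maf
  first_fail <- rep("pass", n)
  first_fail[fail_maf] <- "maf"
  first_fail[fail_cr] <- "call_rate"
  first_fail[fail_chrom] <- "chrom"
  first_fail[fail_qual] <- "qual"
  keep <- first_fail == "pass"
  report <- structure(list(
    n_input = n,
    n_failed_qual = sum(first_fail == "qual"),
    n_failed_chrom = sum(first_fail == "chrom"),
    n_failed_call_rate = sum(first_fail == "call_rate"),
    n_failed_maf = sum(first_fail == "maf"),
    n_passed = sum(keep)), class = "filter_report")
  if (report$n_passed == 0L) warning("no variants pass the filters")
  out <- genotype_matrix(g$variants[keep, , drop = FALSE], g$samples,
                         g$pop_labels, g$dosages[, keep, drop = FALSE])
  list(genotypes = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("filter_report: %d in; dropped %d qual, %d chrom, ",
                     "%d call_rate, %d maf; %d passed\n"),
              x$n_input, x$n_failed_qual, x$n_failed_chrom,
              x$n_failed_call_rate, x$n_failed_maf, x$n_passed))
  invisible(x)
}

#' Split a genotype matrix by population
#'
#' @param g a [genotype_matrix()].
#' @return named list of [genotype_matrix()] objects, one per population
#'   label, all sharing the full variant set.
#' @export
split_by_population <- function(g) {
  labs <- unique(g$pop_labels)
  out <- lapply(labs, function(l) {
    idx <- which(g$pop_labels == l)
    if (length(idx) < 2L) stop("population ", l, " has fewer than 2 samples")
    genotype_matrix(g$variants, g$samples[idx], g$pop_labels[idx],
                    g$dosages[idx, , drop = FALSE])
  })
  stats::setNames(out, labs)
}

#' Subset the haplotype panels of one population
#'
#' @param panels list of [haplotype_panel()] objects.
#' @param g the [genotype_matrix()] carrying population labels.
#' @param label the population to keep.
#' @return list of panels restricted to that population's haplotypes.
#' @export
subset_panels <- function(panels, g, label) {
  keep_samples <- g$samples[g$pop_labels == label]
  lapply(panels, function(p) {
    rows <- which(p$sample_of_haplotype %in% keep_samples)
    haplotype_panel(p$chrom, p$positions, p$haplotypes[rows, , drop = FALSE],
                    p$sample_of_haplotype[rows])
  })
}

#' Write a genotype matrix
#'
#' Emits output readable back by [read_genotypes()]. Missing dosages become
#' `./.` in VCF, `NA` in the table format, and the missing code in PLINK.
#' Heterozygous VCF genotypes are written unphased (`0/1`).
#'
#' @param g a [genotype_matrix()].
#' @param path output file (or PLINK prefix).
#' @param format one of `"vcf"`, `"table"`, `"plink"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "table", "plink")) {
  format <- match.arg(format)
  if (format == "vcf") {
    gt_of <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
    body <- apply(g$dosages, 1L, function(d)
      ifelse(is.na(d), "./.", gt_of[as.character(d)]))
    if (is.null(dim(body))) body <- matrix(body, nrow = nrow(g$variants))
    write_vcf_text(g$variants, g$samples, body, path)
  } else if (format == "table") {
    tab <- cbind(g$variants[c("chrom", "pos", "ref", "alt", "qual")],
                 as.data.frame(t(g$dosages)))
    names(tab) <- c("chrom", "pos", "ref", "alt", "qual", g$samples)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_plink(g, path)
  }
  invisible(path)
}

#' Write phased haplotype panels
#'
#' VCF output uses `|`-separated GT calls and is readable by both
#' [read_haplotypes()] and [read_genotypes()]; the table format mirrors the
#' `<sample>_h1`/`<sample>_h2` layout of [read_haplotypes()].
#'
#' @param panels list of [haplotype_panel()] objects (same samples, same
#'   order, one panel per chromosome).
#' @param path output file.
#' @param format `"vcf"` or `"table"`.
#' @param qual optional list of per-panel quality vectors (VCF only).
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(panels, path, format = c("vcf", "table"),
                             qual = NULL) {
  format <- match.arg(format)
  odd <- seq(1L, nrow(panels[[1L]]$haplotypes), by = 2L)
  samples <- panels[[1L]]$sample_of_haplotype[odd]
  if (format == "vcf") {
    vs <- list(); bodies <- list()
    for (i in seq_along(panels)) {
      p <- panels[[i]]
      q <- if (is.null(qual)) rep(NA_real_, length(p$positions)) else qual[[i]]
      vs[[i]] <- data.frame(chrom = p$chrom, pos = p$positions,
                            ref = "A", alt = "C", qual = q,
                            stringsAsFactors = FALSE)
      a1 <- t(p$haplotypes[odd, , drop = FALSE])
      a2 <- t(p$haplotypes[odd + 1L, , drop = FALSE])
      bodies[[i]] <- matrix(paste0(a1, "|", a2), nrow = nrow(a1))
    }
    write_vcf_text(do.call(rbind, vs), samples, do.call(rbind, bodies), path)
  } else {
    tabs <- lapply(panels, function(p) {
      m <- as.data.frame(t(p$haplotypes))
      names(m) <- paste0(rep(samples, each = 2L), c("_h1", "_h2"))
      cbind(data.frame(chrom = p$chrom, pos = p$positions), m)
    })
    utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Minimal VCF 4.2 writer: variants data.frame + sample GT string matrix
# (variants x samples). vcfR is used for reading; writing from a dosage or
# haplotype matrix is plain text.
write_vcf_text <- function(variants, samples, gt_body, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(variants) == 0L) return(invisible(path))
  qual <- ifelse(is.na(variants$qual), ".",
                 format(variants$qual, trim = TRUE, scientific = FALSE))
  left <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, qual, "PASS", ".", "GT", sep = "\t")
  rows <- paste(left, apply(gt_body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

# --- PLINK binary (.bed/.bim/.fam), SNP-major ---------------------------
# 2-bit codes with A1 = alt, A2 = ref: 00 hom A1 (dosage 2), 10 het (1),
# 11 hom A2 (0), 01 missing. No installed package reads this format, so the
# (tiny) codec lives here.

read_plink <- function(prefix, pops = NULL) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  if (!all(file.exists(bed, bim, fam))) stop("missing .bed/.bim/.fam at ", prefix)
  famt <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bimt <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(famt[[2L]])
  n <- length(samples); m <- nrow(bimt)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  bytes_per_snp <- ceiling(n / 4)
  bits <- matrix(rawToBits(raw[-(1:3)]), nrow = 8L)
  codes <- matrix(as.integer(bits[seq(1, 7, 2), , drop = FALSE]) +
                  2L * as.integer(bits[seq(2, 8, 2), , drop = FALSE]),
                  nrow = 4L * bytes_per_snp)
  codes <- codes[seq_len(n), seq_len(m), drop = FALSE]
  lookup <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  dos <- matrix(lookup[as.character(codes)], nrow = n)
  variants <- data.frame(chrom = as.character(bimt[[1L]]),
                         pos = as.integer(bimt[[4L]]),
                         ref = as.character(bimt[[6L]]),
                         alt = as.character(bimt[[5L]]),
                         qual = NA_real_, stringsAsFactors = FALSE)
  labels <- if (is.null(pops)) as.character(famt[[1L]])
            else resolve_pop_labels(pops, samples)
  genotype_matrix(variants, samples, labels, dos)
}

write_plink <- function(g, prefix) {
  n <- length(g$samples); m <- nrow(g$variants)
  fam <- data.frame(g$pop_labels, g$samples, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(g$variants$chrom,
                    paste0(g$variants$chrom, "_", g$variants$pos), 0L,
                    g$variants$pos, g$variants$alt, g$variants$ref)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code_of <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  bytes_per_snp <- ceiling(n / 4)
  out <- raw(3L + bytes_per_snp * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  codes <- matrix(1L, nrow = 4L * bytes_per_snp, ncol = m)  # pad = missing
  codes[seq_len(n), ] <- matrix(code_of(g$dosages), nrow = n)
  # pack 4 two-bit codes per byte, first sample in the low bits
  c1 <- codes[seq(1, nrow(codes), 4), , drop = FALSE]
  c2 <- codes[seq(2, nrow(codes), 4), , drop = FALSE]
  c3 <- codes[seq(3, nrow(codes), 4), , drop = FALSE]
  c4 <- codes[seq(4, nrow(codes), 4), , drop = FALSE]
  out[-(1:3)] <- as.raw(c1 + 4L * c2 + 16L * c3 + 64L * c4)
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

#' Read a chromosome-sizes table
#'
#' @param path two-column TSV (chrom, length in bp), no header.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = c("character", "numeric"))
  stats::setNames(as.integer(tab[[2L]]), tab[[1L]])
}
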