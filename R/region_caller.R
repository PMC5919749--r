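#' Call outlier loci from a p-valued score track
#'
#' Outliers are sites with `p < alpha` (strict inequality), routed by the
#' sign of z: positive outliers mark selection in the observed population,
#' negative in the reference population.
#'
#' @param track a `score_track` with `p` filled.
#' @param alpha p-value threshold (default 0.01).
#' @return list of class `outlier_set` with data.frames `positive` and
#'   `negative` (chrom, pos, z, p) and the `alpha` used.
#' @export
call_outliers <- function(track, alpha = 0.01) {
  ok <- track$scorable & !is.na(track$p) & track$p < alpha
  loci <- track[ok, c("chrom", "pos", "z", "p")]
  loci <- loci[order(loci$chrom, loci$pos), ]
  rownames(loci) <- NULL
  structure(list(positive = loci[loci$z > 0, , drop = FALSE],
                 negative = loci[loci$z < 0, , drop = FALSE],
                 alpha = alpha),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat("outlier_set (p <", x$alpha, "):", nrow(x$positive), "positive,",
      nrow(x$negative), "negative loci\n")
  invisible(x)
}

#' Merge nearby outlier loci into sections
#'
#' Same-sign outlier loci are chained transitively: two consecutive loci on
#' a chromosome join one section when their distance is strictly below
#' `gap_bp`. A section spans the min to max member position; a lone locus
#' is a zero-length section at its own position.
#'
#' @param loci data.frame with chrom, pos (one sign at a time; order does
#'   not matter).
#' @param gap_bp merge distance (default 10 kb, strict `<`).
#' @return data.frame: chrom, start, end, n_snps, plus a list-column
#'   `members` of member positions.
#' @export
merge_outliers <- function(loci, gap_bp = 1e4) {
  if (nrow(loci) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(loci$chrom)) {
    pos <- loci$pos[loci$chrom == ch]
    new_sec <- c(TRUE, diff(pos) >= gap_bp)
    id <- cumsum(new_sec)
    st <- tapply(pos, id, min); en <- tapply(pos, id, max)
    memb <- split(pos, id)
    df <- data.frame(chrom = ch, start = as.integer(st),
                     end = as.integer(en),
                     n_snps = as.integer(lengths(memb)))
    df$members <- unname(memb)
    out[[ch]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extend outlier sections into potentially selected regions
#'
#' Each section grows by `flank_bp` on both sides, clipped to
#' `[1, chromosome length]`. PSR length is `end - start` bp (so a
#' single-SNP section becomes a region of exactly `2 * flank_bp`). When
#' extension makes same-sign regions touch or overlap, a post-pass merges
#' them (`merge_touching = FALSE` disables it). Regions of opposite sign
#' are never merged.
#'
#' @param sections output of [merge_outliers()] for one sign.
#' @param sign_label `"positive"` or `"negative"`.
#' @param flank_bp flank size (default 10 kb).
#' @param chrom_sizes named vector of chromosome lengths (bp), covering all
#'   chromosomes present.
#' @param merge_touching merge same-sign PSRs that meet after extension.
#' @return data.frame of class `psr_set`: chrom, start, end, sign, n_snps,
#'   length_bp, length_kb, and a `members` list-column.
#' @export
extend_sections <- function(sections, sign_label, flank_bp = 1e4,
                            chrom_sizes, merge_touching = TRUE) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), sign = character(0),
                      n_snps = integer(0), length_bp = numeric(0),
                      length_kb = numeric(0))
  class(empty) <- c("psr_set", "data.frame")
  if (nrow(sections) == 0L) return(empty)
  missing_ch <- setdiff(unique(sections$chrom), names(chrom_sizes))
  if (length(missing_ch))
    stop("chromosome(s) absent from sizes table: ",
         paste(missing_ch, collapse = ", "))
  st <- pmax(1, sections$start - flank_bp)
  en <- pmin(chrom_sizes[sections$chrom], sections$end + flank_bp)
  psr <- data.frame(chrom = sections$chrom, start = as.integer(st),
                    end = as.integer(en), sign = sign_label,
                    n_snps = sections$n_snps)
  psr$members <- if (is.null(sections$members))
    lapply(seq_len(nrow(sections)), function(i)
      c(sections$start[i], sections$end[i]))
  else sections$members
  if (merge_touching) {
    out <- list()
    for (ch in unique(psr$chrom)) {
      p <- psr[psr$chrom == ch, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      grp <- cumsum(c(TRUE, p$start[-1L] > cummax_head_end(p$end)))
      agg <- lapply(split(seq_len(nrow(p)), grp), function(ix)
        data.frame(chrom = ch, start = min(p$start[ix]),
                   end = max(p$end[ix]), sign = sign_label,
                   n_snps = sum(p$n_snps[ix]),
                   members = I(list(sort(unlist(p$members[ix]))))))
      out[[ch]] <- do.call(rbind, agg)
    }
    psr <- do.call(rbind, out)
  }
  psr$length_bp <- as.numeric(psr$end - psr$start)
  psr$length_kb <- psr$length_bp / 1000
  rownames(psr) <- NULL
  class(psr) <- c("psr_set", "data.frame")
  psr
}

# running max of the preceding ends, for interval chaining
cummax_head_end <- function(end) {
  if (length(end) <= 1L) return(numeric(0))
  cummax(end)[-length(end)]
}

#' Full outlier-to-PSR pipeline for both signs
#'
#' @param outliers an `outlier_set` from [call_outliers()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param gap_bp,flank_bp,merge_touching see [merge_outliers()] and
#'   [extend_sections()].
#' @return a `psr_set` covering both signs.
#' @export
call_psrs <- function(outliers, chrom_sizes, gap_bp = 1e4, flank_bp = 1e4,
                      merge_touching = TRUE) {
  pos <- extend_sections(merge_outliers(outliers$positive, gap_bp),
                         "positive", flank_bp, chrom_sizes, merge_touching)
  neg <- extend_sections(merge_outliers(outliers$negative, gap_bp),
                         "negative", flank_bp, chrom_sizes, merge_touching)
  res <- rbind(pos, neg)
  class(res) <- c("psr_set", "data.frame")
  res
}

#' Per-chromosome PSR summary
#'
#' One row per chromosome with, for each sign, the number of member outlier
#' SNPs, the number of regions, total and mean region length in kb, plus a
#' totals row and the genome fraction covered.
#'
#' @param psrs a `psr_set`.
#' @param chrom_sizes named vector of chromosome lengths (defines row order
#'   and the genome size for coverage fractions).
#' @return list of class `psr_summary`: `table` (per-chromosome data.frame),
#'   `totals`, `genome_fraction` (per sign).
#' @export
summarize_regions <- function(psrs, chrom_sizes) {
  chroms <- names(chrom_sizes)
  one_sign <- function(sign) {
    p <- psrs[psrs$sign == sign, , drop = FALSE]
    t(vapply(chroms, function(ch) {
      q <- p[p$chrom == ch, , drop = FALSE]
      c(n_snps = sum(q$n_snps), n_regions = nrow(q),
        total_kb = sum(q$length_kb),
        mean_kb = if (nrow(q)) sum(q$length_kb) / nrow(q) else 0)
    }, numeric(4)))
  }
  pos <- one_sign("positive"); neg <- one_sign("negative")
  tab <- data.frame(chrom = chroms,
                    snp_pos = pos[, "n_snps"], regions_pos = pos[, "n_regions"],
                    total_kb_pos = round(pos[, "total_kb"], 3),
                    mean_kb_pos = round(pos[, "mean_kb"], 3),
                    snp_neg = neg[, "n_snps"], regions_neg = neg[, "n_regions"],
                    total_kb_neg = round(neg[, "total_kb"], 3),
                    mean_kb_neg = round(neg[, "mean_kb"], 3),
                    row.names = NULL)
  tab$snp_total <- tab$snp_pos + tab$snp_neg
  totals <- c(snp_pos = sum(tab$snp_pos), regions_pos = sum(tab$regions_pos),
              total_kb_pos = sum(tab$total_kb_pos),
              snp_neg = sum(tab$snp_neg), regions_neg = sum(tab$regions_neg),
              total_kb_neg = sum(tab$total_kb_neg))
  genome_bp <- sum(as.numeric(chrom_sizes))
  structure(list(table = tab, totals = totals,
                 genome_fraction = c(
                   positive = sum(tab$total_kb_pos) * 1000 / genome_bp,
                   negative = sum(tab$total_kb_neg) * 1000 / genome_bp)),
            class = "psr_summary")
}

#' @export
print.psr_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("totals: +%d SNPs in %d PSRs (%.3f kb); -%d SNPs in %d PSRs (%.3f kb)\n",
              x$totals["snp_pos"], x$totals["regions_pos"],
              x$totals["total_kb_pos"], x$totals["snp_neg"],
              x$totals["regions_neg"], x$totals["total_kb_neg"]))
  cat(sprintf("genome fraction: %.4f%% / %.4f%%\n",
              100 * x$genome_fraction["positive"],
              100 * x$genome_fraction["negative"]))
  invisible(x)
}

#' Write PSRs as a BED-like table
#'
#' @param psrs a `psr_set`.
#' @param path output TSV path (columns chrom, start, end, sign, n_snps,
#'   length_kb).
#' @return `path`, invisibly.
#' @export
write_psr_bed <- function(psrs, path) {
  utils::write.table(
    psrs[c("chrom", "start", "end", "sign", "n_snps", "length_kb")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
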