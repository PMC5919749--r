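#' Read a gene annotation table
#'
#' Accepts BED6 (0-based half-open; converted to 1-based inclusive) or GFF3
#' restricted to `gene` features (already 1-based inclusive).
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @return data.frame: gene_id, name, chrom, start, end, strand.
#' @export
read_genes <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    data.frame(gene_id = tab[[4L]], name = tab[[4L]],
               chrom = as.character(tab[[1L]]),
               start = as.integer(tab[[2L]]) + 1L,
               end = as.integer(tab[[3L]]),
               strand = if (ncol(tab) >= 6L) tab[[6L]] else "*",
               stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, function(x) x[3L] == "gene", logical(1))]
    id_of <- function(attr) {
      m <- regmatches(attr, regexec("ID=([^;]+)", attr))[[1L]]
      if (length(m) == 2L) m[2L] else attr
    }
    data.frame(
      gene_id = vapply(f, function(x) id_of(x[9L]), character(1)),
      name = vapply(f, function(x) {
        m <- regmatches(x[9L], regexec("Name=([^;]+)", x[9L]))[[1L]]
        if (length(m) == 2L) m[2L] else id_of(x[9L])
      }, character(1)),
      chrom = vapply(f, `[`, character(1), 1L),
      start = as.integer(vapply(f, `[`, character(1), 4L)),
      end = as.integer(vapply(f, `[`, character(1), 5L)),
      strand = vapply(f, `[`, character(1), 7L),
      stringsAsFactors = FALSE)
  }
}

#' Read a QTL interval table
#'
#' @param path TSV with header columns qtl_id, trait, trait_class, chrom,
#'   start, end (1-based inclusive).
#' @return data.frame of QTL records with a `length` column
#'   (`end - start` bp).
#' @export
read_qtl <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("qtl_id", "trait", "trait_class", "chrom", "start", "end")
  if (!all(need %in% names(tab))) stop("QTL table is missing columns")
  tab$chrom <- as.character(tab$chrom)
  tab$length <- tab$end - tab$start
  tab
}

as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

#' Assign genes to PSRs by any-overlap
#'
#' A gene belongs to a region when their intervals (1-based inclusive)
#' share at least one bp. Chromosome-name mismatch between the two inputs
#' is an explicit error listing the offending names.
#'
#' @param psrs a `psr_set`.
#' @param genes data.frame from [read_genes()].
#' @return list: `per_psr` (list of gene-id vectors, one per PSR row) and
#'   `genes` (the deduplicated union of assigned gene ids).
#' @export
genes_in_regions <- function(psrs, genes) {
  bad <- setdiff(unique(psrs$chrom), unique(genes$chrom))
  if (length(bad) && nrow(psrs))
    stop("chromosome name(s) absent from gene annotation: ",
         paste(bad, collapse = ", "))
  if (nrow(psrs) == 0L) return(list(per_psr = list(), genes = character(0)))
  hits <- GenomicRanges::findOverlaps(
    as_granges(psrs$chrom, psrs$start, psrs$end),
    as_granges(genes$chrom, genes$start, genes$end))
  per <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(psrs))))
  per <- lapply(per, unique)
  list(per_psr = unname(per), genes = unique(unlist(per, use.names = FALSE)))
}

#' Clean a QTL table for overlap analysis
#'
#' Two-step preparation: (1) QTL longer than `max_len_bp` (strictly) are
#' removed; (2) any pair overlapping by more than `merge_frac` of the
#' shorter interval (or of both, with `reciprocal = TRUE`) is merged into
#' its union, with trait names concatenated, iterating until no pair
#' qualifies. The operation is a fixed point: re-running it changes
#' nothing.
#'
#' @param qtls data.frame from [read_qtl()].
#' @param max_len_bp length cutoff (default 1 Mb; length = end - start).
#' @param merge_frac overlap fraction required for merging (default 0.5,
#'   strict `>`).
#' @param reciprocal require the fraction of both intervals, not just the
#'   shorter one.
#' @return the cleaned QTL data.frame.
#' @export
prepare_qtl <- function(qtls, max_len_bp = 1e6, merge_frac = 0.5,
                        reciprocal = FALSE) {
  qtls$length <- qtls$end - qtls$start
  qtls <- qtls[qtls$length <= max_len_bp, , drop = FALSE]
  join_semi <- function(a, b)
    paste(unique(c(strsplit(a, ";")[[1L]], strsplit(b, ";")[[1L]])),
          collapse = ";")
  repeat {
    qtls <- qtls[order(qtls$chrom, qtls$start, qtls$end), , drop = FALSE]
    rownames(qtls) <- NULL
    pair <- find_mergeable_pair(qtls, merge_frac, reciprocal)
    if (is.null(pair)) break
    i <- pair[1L]; j <- pair[2L]
    qtls$start[i] <- min(qtls$start[i], qtls$start[j])
    qtls$end[i] <- max(qtls$end[i], qtls$end[j])
    qtls$trait[i] <- join_semi(qtls$trait[i], qtls$trait[j])
    qtls$trait_class[i] <- join_semi(qtls$trait_class[i], qtls$trait_class[j])
    qtls <- qtls[-j, , drop = FALSE]
  }
  qtls$length <- qtls$end - qtls$start
  rownames(qtls) <- NULL
  qtls
}

# first (i, j) pair of same-chromosome QTL whose overlap exceeds merge_frac
# of the shorter (or, reciprocal, the longer) interval; NULL when none
find_mergeable_pair <- function(qtls, merge_frac, reciprocal) {
  n <- nrow(qtls)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (qtls$chrom[j] != qtls$chrom[i]) break
      if (qtls$start[j] > qtls$end[i]) break   # sorted: no later overlaps
      ov <- min(qtls$end[i], qtls$end[j]) - max(qtls$start[i], qtls$start[j])
      len_i <- qtls$end[i] - qtls$start[i]
      len_j <- qtls$end[j] - qtls$start[j]
      denom <- if (reciprocal) max(len_i, len_j) else min(len_i, len_j)
      if (denom > 0 && ov / denom > merge_frac) return(c(i, j))
    }
  }
  NULL
}

#' PSR/QTL overlap by mutual containment
#'
#' An overlap is counted only when one interval fully contains the other
#' (in either direction); partial overlaps do not count. Returns per-PSR
#' QTL matches and per-trait-class counts of PSRs with at least one match.
#'
#' @param psrs a `psr_set`.
#' @param qtls prepared QTL table ([prepare_qtl()]).
#' @return list of class `overlap_report`: `per_psr` (data.frame psr index,
#'   chrom, start, end, sign, qtl ids, trait classes), `class_counts`
#'   (named vector over trait classes), `n_psr_with_overlap`.
#' @export
qtl_overlap <- function(psrs, qtls) {
  n <- nrow(psrs)
  qtl_ids <- character(n); classes <- character(n)
  for (i in seq_len(n)) {
    same <- qtls$chrom == psrs$chrom[i]
    contain <- same &
      ((qtls$start >= psrs$start[i] & qtls$end <= psrs$end[i]) |
       (qtls$start <= psrs$start[i] & qtls$end >= psrs$end[i]))
    qtl_ids[i] <- paste(qtls$qtl_id[contain], collapse = ";")
    cls <- unlist(strsplit(qtls$trait_class[contain], ";"))
    classes[i] <- paste(unique(cls), collapse = ";")
  }
  per <- data.frame(psr = seq_len(n), chrom = psrs$chrom,
                    start = psrs$start, end = psrs$end, sign = psrs$sign,
                    qtl_ids = qtl_ids, trait_classes = classes,
                    stringsAsFactors = FALSE)
  has <- nzchar(qtl_ids)
  all_classes <- unique(unlist(strsplit(classes[has], ";")))
  cc <- vapply(all_classes, function(cl)
    sum(vapply(strsplit(classes, ";"), function(v) cl %in% v, logical(1))),
    integer(1))
  structure(list(per_psr = per,
                 class_counts = cc,
                 n_psr_with_overlap = sum(has)),
            class = "overlap_report")
}

#' Hypergeometric term-enrichment test
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least `k` term-annotated genes among the `n` selected, given `K`
#' annotated genes in a background of `N`: `p = P(X >= k)`. No multiple-
#' testing correction is applied to the significance call (nominal
#' threshold, default 0.05); a Benjamini-Hochberg column is emitted for
#' information.
#'
#' @param selected_genes character vector (subset of the background).
#' @param background_genes character vector.
#' @param term_map data.frame with columns term_id, gene_id (flat
#'   association dump), or a named list of gene-id vectors.
#' @param alpha significance threshold on the raw p (default 0.05).
#' @return data.frame sorted by p: term_id, k, K, n, N, p, p_bh,
#'   significant.
#' @export
enrichment_test <- function(selected_genes, background_genes, term_map,
                            alpha = 0.05) {
  selected_genes <- unique(selected_genes)
  background_genes <- unique(background_genes)
  if (length(selected_genes) == 0L) stop("empty selected gene set")
  if (!all(selected_genes %in% background_genes))
    stop("selected genes must be a subset of the background")
  if (is.data.frame(term_map))
    term_map <- split(term_map$gene_id, term_map$term_id)
  N <- length(background_genes); n <- length(selected_genes)
  rows <- lapply(names(term_map), function(term) {
    tg <- intersect(unique(term_map[[term]]), background_genes)
    K <- length(tg)
    k <- length(intersect(tg, selected_genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, K = K, n = n, N = N, p = p)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
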