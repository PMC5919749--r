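# Small programmatic fixtures shared across the suite.

# a hand-sized genotype matrix: 6 samples (4 popA, 2 popB), 4 SNPs on 2 chroms
toy_genotypes <- function() {
  variants <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                         pos = c(100L, 500L, 900L, 200L),
                         ref = "A", alt = "C",
                         qual = c(50, 30, 25, 40))
  dos <- rbind(c(0L, 1L, 2L, 0L),
               c(1L, 1L, 2L, 0L),
               c(2L, 0L, 1L, 1L),
               c(0L, 2L, 0L, 2L),
               c(1L, 0L, 0L, 1L),
               c(2L, 1L, 1L, 2L))
  genotype_matrix(variants, paste0("s", 1:6),
                  c("A", "A", "A", "A", "B", "B"), dos)
}

# random genotype matrix with optional missingness
random_genotypes <- function(n = 10, m = 20, miss = 0, chroms = c("chr1", "chr2")) {
  variants <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch, pos = sort(sample.int(1e6, ceiling(m / length(chroms)))),
               ref = "A", alt = "G", qual = round(stats::runif(ceiling(m / length(chroms)), 21, 99), 1))))
  mm <- nrow(variants)
  dos <- matrix(sample(0:2, n * mm, replace = TRUE), nrow = n)
  if (miss > 0) dos[stats::runif(n * mm) < miss] <- NA_integer_
  genotype_matrix(variants, sprintf("s%02d", seq_len(n)),
                  rep(c("A", "B"), length.out = n), dos)
}

# random phased panel: n_hap haplotypes x m SNPs
random_panel <- function(n_hap = 8, m = 20, chrom = "chr1", freq = NULL) {
  pos <- sort(sample.int(1e6, m))
  if (is.null(freq)) freq <- stats::runif(m, 0.1, 0.9)
  H <- matrix(stats::rbinom(n_hap * m, 1L, rep(freq, each = n_hap)),
              nrow = n_hap)
  haplotype_panel(chrom, pos, H,
                  rep(sprintf("s%02d", seq_len(n_hap / 2)), each = 2L))
}

# brute-force EHH: probability two haplotypes are identical at all markers
# from the core out to each marker on one side (window includes the core);
# element 1 (distance 0) is 1 by definition
brute_ehh <- function(H, core, side) {
  n <- nrow(H)
  m <- ncol(H)
  idxs <- if (side == "left") rev(seq_len(core - 1L)) else
    if (core < m) (core + 1L):m else integer(0)
  ehh <- 1
  for (j in idxs) {
    win <- if (side == "left") j:core else core:j
    cnt <- 0L
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
      if (all(H[a, win] == H[b, win])) cnt <- cnt + 1L
    ehh <- c(ehh, cnt / choose(n, 2))
  }
  ehh
}

# a minimal score track for region-caller tests
mk_track <- function(chrom, pos, z) {
  tr <- data.frame(chrom = chrom, pos = pos, raw = z, z = z,
                   p = 2 * stats::pnorm(-abs(z)),
                   truncated = FALSE, scorable = TRUE)
  class(tr) <- c("score_track", "data.frame")
  tr
}
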