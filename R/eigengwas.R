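#' Single-marker regression of eigenvector phenotypes on genotypes
#'
#' An EigenGWAS scan treats a PCA eigenvector as the phenotype and runs
#' ordinary least squares of the eigenvector on each SNP's dosage (with
#' intercept). The Wald statistic `(beta / se)^2` is referred to a 1-df
#' chi-square; loci carrying large between-population frequency
#' differences surface with the smallest p-values, and drift-driven
#' inflation is removed afterwards by [genomic_control()].
#'
#' Missing dosages are mean-imputed per SNP; monomorphic SNPs are reported
#' untested (`NA`). Eigenvector sign is arbitrary: flipping it negates beta
#' and leaves se, chi2 and p unchanged.
#'
#' @param g a [genotype_matrix()].
#' @param evec an `eigen_result` from [compute_pca()] computed on the same
#'   samples, or a numeric matrix of phenotype columns (e.g. a deposited
#'   eigenvector table).
#' @param which integer indices of the components/columns to scan
#'   (default 2:5 — the leading eigenvector is often dominated by noise or
#'   gross structure and is scanned separately when wanted).
#' @return list of `association_track` data.frames (chrom, pos, beta, se,
#'   chi2, p_raw, and after correction lambda_gc, p_gc), one per phenotype,
#'   named `EV<k>`.
#' @export
eigengwas_scan <- function(g, evec, which = 2:5) {
  Y <- if (inherits(evec, "eigen_result")) evec$eigenvectors else as.matrix(evec)
  if (nrow(Y) != length(g$samples))
    stop("phenotypes must be computed on the same samples")
  if (length(g$samples) < 3L) stop("fewer than 3 samples")
  if (any(which < 1L | which > ncol(Y)))
    stop("component index out of range")
  lapply(stats::setNames(as.list(which), paste0("EV", which)), function(k)
    ols_scan(g, Y[, k], phenotype_id = paste0("EV", k)))
}

# vectorized per-SNP OLS with intercept: beta, se (residual df = n - 2),
# Wald chi2 = (beta/se)^2, p from 1-df chi-square
ols_scan <- function(g, y, phenotype_id = "pheno") {
  X <- g$dosages
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na)) X[na] <- mu[na[, 2L]]
  n <- nrow(X)
  xc <- sweep(X, 2L, colMeans(X))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, yc))
  syy <- sum(yc^2)
  tested <- sxx > 0
  beta <- ifelse(tested, sxy / sxx, NA_real_)
  rss <- pmax(syy - ifelse(tested, sxy^2 / sxx, 0), 0)
  s2 <- rss / (n - 2L)
  se <- ifelse(tested & s2 > 0, sqrt(s2 / sxx), NA_real_)
  chi2 <- ifelse(tested & !is.na(se), (beta / se)^2, NA_real_)
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  out <- data.frame(chrom = g$variants$chrom, pos = g$variants$pos,
                    beta = beta, se = se, chi2 = chi2, p_raw = p,
                    tested = tested & !is.na(chi2))
  attr(out, "phenotype_id") <- phenotype_id
  class(out) <- c("association_track", "data.frame")
  out
}

#' Genomic-control correction of an association scan
#'
#' `lambda_gc = median(chi2) / 0.4549364` (the 1-df chi-square median);
#' corrected statistics are `chi2 / lambda_gc` with fresh 1-df p-values.
#' Lambda well above 1 signals inflation from population structure/drift.
#'
#' @param track an `association_track` with at least 20 tested SNPs.
#' @return the track with columns `chi2_gc`, `p_gc` and attribute/column
#'   `lambda_gc`.
#' @export
genomic_control <- function(track) {
  chi2 <- track$chi2[track$tested]
  if (length(chi2) < 20L) stop("need at least 20 tested SNPs")
  med <- stats::median(chi2)
  if (med <= 0) stop("zero median chi-square")
  lambda <- med / stats::qchisq(0.5, df = 1L)
  track$chi2_gc <- track$chi2 / lambda
  track$p_gc <- stats::pchisq(track$chi2_gc, df = 1L, lower.tail = FALSE)
  track$lambda_gc <- lambda
  track
}

#' Per-SNP Hudson F_ST between two populations
#'
#' The two-population Hudson estimator with sample-size correction:
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`, with allele frequencies p and allele counts n per
#' population. The overall value is the ratio of averages (sum of
#' numerators over sum of denominators), the recommended genome-wide
#' combination; the mean of per-SNP ratios is also returned.
#'
#' @param g a [genotype_matrix()] with exactly two population labels.
#' @return list: `per_snp` (numeric vector, NA where undefined), `overall`
#'   (ratio of averages), `mean_per_snp`.
#' @export
hudson_fst <- function(g) {
  labs <- unique(g$pop_labels)
  if (length(labs) != 2L) stop("exactly two populations required")
  stats_of <- function(lab) {
    D <- g$dosages[g$pop_labels == lab, , drop = FALSE]
    nn <- 2 * colSums(!is.na(D))
    p <- colSums(D, na.rm = TRUE) / nn
    list(p = p, n = nn)
  }
  a <- stats_of(labs[1L]); b <- stats_of(labs[2L])
  num <- (a$p - b$p)^2 - a$p * (1 - a$p) / (a$n - 1) -
    b$p * (1 - b$p) / (b$n - 1)
  den <- a$p * (1 - b$p) + b$p * (1 - a$p)
  per <- ifelse(den > 0 & a$n > 1 & b$n > 1, num / den, NA_real_)
  ok <- !is.na(per)
  list(per_snp = per,
       overall = sum(num[ok]) / sum(den[ok]),
       mean_per_snp = mean(per[ok]))
}
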