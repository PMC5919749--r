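#!/usr/bin/env Rscript
# Association-based corroboration of the scan: EigenGWAS (eigenvector
# phenotypes, single-marker OLS + genomic control; EV2-EV5 by default,
# EV1 reported too) and the expedited mixed model (kinship + one-shot
# REML + per-marker GLS) on EV1-EV5.

suppressPackageStartupMessages(library(sweepscan))

g <- read_genotypes("results/fixture/haplotypes.vcf", "vcf",
                    pops = "results/fixture/pops.tsv")
chrom_sizes <- read_chrom_sizes("results/fixture/chrom_sizes.tsv")
g <- apply_variant_filters(g, variant_filter_spec(
  allowed_chroms = names(chrom_sizes)))$genotypes

evec <- read.table("results/eigenvectors.tsv", header = TRUE, sep = "\t")
Y <- as.matrix(evec[, grep("^EV", names(evec))])

scans <- eigengwas_scan(g, Y, which = 1:5)
lams <- c()
for (nm in names(scans)) {
  tr <- genomic_control(scans[[nm]])
  lams[nm] <- tr$lambda_gc[1L]
  write.table(tr[c("chrom", "pos", "beta", "chi2", "p_raw", "p_gc")],
              sprintf("results/eigengwas_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
cat("EigenGWAS lambda_gc:",
    paste(sprintf("%s=%.2f", names(lams), lams), collapse = " "), "\n")

K <- compute_kinship(g, "ibs")
write_kinship(K, "results/kinship_ibs.tsv")
mm_lams <- c()
for (k in 1:5) {
  y <- Y[, k]
  vc <- reml_fit(y, K)
  tr <- genomic_control(emmax_scan(g, y, K, vc, phenotype_id = paste0("EV", k)))
  mm_lams[paste0("EV", k)] <- tr$lambda_gc[1L]
  write.table(tr[c("chrom", "pos", "beta", "chi2", "p_raw", "p_gc")],
              sprintf("results/emmax_EV%d.tsv", k), sep = "\t",
              quote = FALSE, row.names = FALSE)
  qq <- qq_points(tr)
  write.table(qq, sprintf("results/emmax_EV%d_qq.tsv", k), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (k == 1L)
    cat(sprintf("EV1 variance components: sigma_g2 %.3g, sigma_e2 %.3g (h2 %.2f)\n",
                vc$sigma_g2, vc$sigma_e2, vc$h2))
}
cat("EMMAX lambda_gc:",
    paste(sprintf("%s=%.2f", names(mm_lams), mm_lams), collapse = " "), "\n")
cat("mixed-model correction pulls the EV1 inflation of",
    sprintf("%.1f", lams["EV1"]), "down to",
    sprintf("%.2f", mm_lams["EV1"]), "\n")
cat("wrote results/eigengwas_EV*.tsv, results/emmax_EV*.tsv\n")
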