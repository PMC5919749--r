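#!/usr/bin/env Rscript
# Population structure of the study genotypes: PCA eigenvectors (written
# for reuse as EigenGWAS/EMMAX phenotypes) and per-population LD decay
# with the distance at which mean r^2 falls to 0.3.

suppressPackageStartupMessages(library(sweepscan))

g <- read_genotypes("results/fixture/haplotypes.vcf", "vcf",
                    pops = "results/fixture/pops.tsv")
chrom_sizes <- read_chrom_sizes("results/fixture/chrom_sizes.tsv")
g <- apply_variant_filters(g, variant_filter_spec(
  allowed_chroms = names(chrom_sizes)))$genotypes

pc <- compute_pca(g, k = 5L)
cat("variance explained (%):",
    paste0(sprintf("EV%d=%.1f", 1:5, 100 * pc$var_explained),
           collapse = " "), "\n")
evec <- data.frame(sample = g$samples, pop = g$pop_labels,
                   pc$eigenvectors)
write.table(evec, "results/eigenvectors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# EV1 separates the populations when divergence dominates
sep <- split(pc$eigenvectors[, 1L], g$pop_labels)
cat(sprintf("EV1 means: popA %.3f, popB %.3f\n",
            mean(sep$popA), mean(sep$popB)))

pops <- split_by_population(g)
curves <- list()
for (lab in names(pops)) {
  rec <- pairwise_r2(pops[[lab]], max_distance_bp = 1e6)
  cv <- ld_decay_curve(rec, bin_width_bp = 1e4, max_distance_bp = 1e6)
  ext <- ld_extent(cv, threshold = 0.3)
  cat(sprintf("%s: %d SNP pairs, first-bin mean r2 %.3f, extent(0.3) %s\n",
              lab, nrow(rec), cv$mean_r2[1L],
              if (is.na(ext)) "beyond range" else sprintf("%.1f kb", ext / 1000)))
  cv$population <- lab
  curves[[lab]] <- cv
}
write.table(do.call(rbind, curves), "results/ld_decay.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/eigenvectors.tsv, results/ld_decay.tsv\n")
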