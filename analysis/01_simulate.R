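#!/usr/bin/env Rscript
# Build the study dataset: two diverged chicken-like populations with a
# hard selective sweep planted in the observed population (popA), written
# to results/fixture/ as a phased VCF plus sidecar tables. Downstream
# steps (02-05) read these files, so the whole analysis runs from disk
# exactly as it would on real genotypes.

suppressPackageStartupMessages(library(sweepscan))
seed <- 20170
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(
  sweep = list(pop = "popA", chrom = 1L, focal_pos = 2.5e6,
               carrier_fraction = 0.9, erosion_mean_bp = 2e5),
  seed = seed)
sim <- simulate_two_populations(cfg)
files <- write_fixture(sim, "results/fixture")

print(sim$genotypes)
fst <- hudson_fst(sim$genotypes)
cat(sprintf("realized Hudson F_ST (target %.2f): %.3f\n",
            cfg$fst_target, fst$overall))
cat(sprintf("planted sweep: %s @ %.1f Mb, carrier fraction %.2f\n",
            sim$truth$sweep$chrom, sim$truth$sweep$focal_pos / 1e6,
            sim$truth$sweep$carrier_fraction))

filt <- apply_variant_filters(sim$genotypes, variant_filter_spec(
  allowed_chroms = names(sim$chrom_sizes)))
print(filt$report)
cat("fixture written to results/fixture/\n")
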