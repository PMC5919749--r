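#!/usr/bin/env Rscript
# Functional context for the called PSRs: gene content (any-overlap), QTL
# matches under the containment rule after QTL cleaning (> 1 Mb dropped,
# > 50% overlaps merged), per-trait-class counts, and hypergeometric term
# enrichment of PSR genes against the full gene background.

suppressPackageStartupMessages(library(sweepscan))

psr_tab <- read.table("results/psr.bed", header = TRUE, sep = "\t")
class(psr_tab) <- c("psr_set", "data.frame")
genes <- read_genes("results/fixture/genes.bed", "bed")
qtl_raw <- read_qtl("results/fixture/qtl.tsv")
terms <- read.table("results/fixture/terms.tsv", header = TRUE,
                    stringsAsFactors = FALSE)

hits <- genes_in_regions(psr_tab, genes)
cat(sprintf("%d genes fall inside the %d PSRs\n",
            length(hits$genes), nrow(psr_tab)))
gene_rows <- data.frame(
  psr = rep(seq_len(nrow(psr_tab)), lengths(hits$per_psr)),
  gene_id = unlist(hits$per_psr))
write.table(gene_rows, "results/psr_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

qtl <- prepare_qtl(qtl_raw, max_len_bp = 1e6, merge_frac = 0.5)
cat(sprintf("QTL cleaning: %d -> %d records (dropped > 1 Mb, merged > 50%% overlaps)\n",
            nrow(qtl_raw), nrow(qtl)))
ov <- qtl_overlap(psr_tab, qtl)
cat(sprintf("%d of %d PSRs contain or are contained by a QTL\n",
            ov$n_psr_with_overlap, nrow(psr_tab)))
if (length(ov$class_counts))
  cat("per trait class:",
      paste(sprintf("%s=%d", names(ov$class_counts), ov$class_counts),
            collapse = " "), "\n")
write.table(ov$per_psr, "results/psr_qtl_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

if (length(hits$genes)) {
  enr <- enrichment_test(hits$genes, genes$gene_id, terms, alpha = 0.05)
  write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("top term %s: k=%d/%d, p=%.3g%s\n", enr$term_id[1L],
              enr$k[1L], enr$K[1L], enr$p[1L],
              if (enr$significant[1L]) " (significant at 0.05)" else ""))
}
cat("wrote results/psr_genes.tsv, results/psr_qtl_overlap.tsv, results/enrichment.tsv\n")
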