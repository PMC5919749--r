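#' Configuration for the two-population simulator
#'
#' The generator draws ancestral allele frequencies, diverges them into two
#' populations under the Balding-Nichols model at a target F_ST, builds a
#' small founder-haplotype panel per population, and copies sample
#' haplotypes from the founders with a Markov switch process along the
#' chromosome (a Li-Stephens-flavored mosaic), which produces
#' distance-decaying LD. An optional hard sweep overwrites a fraction of
#' one population's haplotypes with a single sweep haplotype around a
#' focal site, with exponentially eroded flanks.
#'
#' @param n_samples samples per population.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length (bp).
#' @param n_snps SNPs per chromosome.
#' @param fst_target Balding-Nichols divergence parameter, in (0, 1).
#' @param n_founders founder haplotypes per population (fewer founders =>
#'   stronger LD).
#' @param copy_switch_rate per-bp probability rate of switching founder
#'   while copying.
#' @param founder_block_rate per-bp refresh rate of the latent uniform
#'   driving founder alleles; founder haplotypes keep a shared latent draw
#'   over `~1/founder_block_rate` bp, so the founder panel itself carries
#'   LD that decays with distance (without it, site-wise independent
#'   founders would cap inter-site r-squared near `1/(n_founders-1)`).
#' @param freq_corr_rate per-bp decay rate of the Gaussian-copula
#'   autocorrelation of *ancestral* allele frequencies along the
#'   chromosome. Marginal frequency distributions — and therefore the
#'   realized F_ST — are unchanged; local frequency similarity lifts the
#'   attainable inter-site r-squared, which is otherwise capped by
#'   allele-frequency mismatch. Per-site Balding-Nichols drift stays
#'   independent across sites, so breed divergence does not form long
#'   near-fixed runs that would mimic sweeps.
#' @param maf_floor ancestral frequencies drawn uniform on
#'   `(maf_floor, 1 - maf_floor)`.
#' @param pop_labels the two population labels (first = observed
#'   population by convention).
#' @param sweep `NULL` or a list with `pop` (label), `chrom` (index),
#'   `focal_pos` (bp), `carrier_fraction` in (0, 1], `erosion_mean_bp`.
#' @param seed integer seed; the run is fully deterministic given it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 50L, n_chrom = 2L,
                             chrom_length_bp = 5e6, n_snps = 2000L,
                             fst_target = 0.2, n_founders = 30L,
                             copy_switch_rate = 5e-6,
                             founder_block_rate = 5e-6,
                             freq_corr_rate = 3e-5, maf_floor = 0.05,
                             pop_labels = c("popA", "popB"),
                             sweep = NULL, seed = 1L) {
  stopifnot(n_samples >= 2L, n_chrom >= 1L, chrom_length_bp > n_snps,
            n_snps >= 2L, fst_target > 0, fst_target < 1,
            n_founders >= 2L, copy_switch_rate > 0, founder_block_rate > 0,
            freq_corr_rate > 0,
            maf_floor >= 0, maf_floor < 0.5, length(pop_labels) == 2L)
  if (!is.null(sweep)) {
    stopifnot(sweep$pop %in% pop_labels,
              sweep$chrom >= 1L, sweep$chrom <= n_chrom,
              sweep$focal_pos >= 1, sweep$focal_pos <= chrom_length_bp,
              sweep$carrier_fraction > 0, sweep$carrier_fraction <= 1)
    if (is.null(sweep$erosion_mean_bp) || sweep$erosion_mean_bp <= 0)
      stop("sweep erosion_mean_bp must be positive")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_chrom = as.integer(n_chrom),
                 chrom_length_bp = chrom_length_bp, n_snps = as.integer(n_snps),
                 fst_target = fst_target, n_founders = as.integer(n_founders),
                 copy_switch_rate = copy_switch_rate,
                 founder_block_rate = founder_block_rate,
                 freq_corr_rate = freq_corr_rate,
                 maf_floor = maf_floor,
                 pop_labels = pop_labels, sweep = sweep,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# stationary AR(1) latent over irregular positions: corr(z_j, z_{j+1}) =
# exp(-rate * gap_j); standard normal marginals
latent_ar1 <- function(gaps, rate) {
  m <- length(gaps) + 1L
  z <- numeric(m)
  z[1L] <- stats::rnorm(1L)
  rho <- exp(-rate * gaps)
  eps <- stats::rnorm(m - 1L)
  for (j in seq_len(m - 1L))
    z[j + 1L] <- rho[j] * z[j] + sqrt(1 - rho[j]^2) * eps[j]
  z
}

# founder haplotypes with Markov-correlated alleles: each founder carries a
# latent uniform that is refreshed between consecutive markers with
# probability 1 - exp(-block_rate * gap); the allele is the indicator
# u < p_site, so marginal frequencies follow p while nearby sites stay
# strongly correlated within a founder
make_founders <- function(p, gaps, n_founders, block_rate) {
  m <- length(p)
  Fm <- matrix(0L, n_founders, m)
  keep_prob <- exp(-block_rate * gaps)
  for (f in seq_len(n_founders)) {
    fresh <- c(TRUE, stats::runif(m - 1L) >= keep_prob)
    idx <- cumsum(fresh)
    u <- stats::runif(max(idx))[idx]
    Fm[f, ] <- as.integer(u < p)
  }
  Fm
}

# copy one haplotype from a founder panel: founder switches form a Markov
# process over inter-marker gaps with P(switch) = 1 - exp(-rate * gap)
copy_haplotype <- function(founders, gaps, rate) {
  m <- ncol(founders)
  sw <- stats::runif(m - 1L) < 1 - exp(-rate * gaps)
  seg <- cumsum(c(1L, as.integer(sw)))
  picks <- sample.int(nrow(founders), max(seg), replace = TRUE)
  founders[cbind(picks[seg], seq_len(m))]
}

#' Simulate two diverged populations with haplotype structure
#'
#' Runs the full generator described in [synthetic_config()]; when
#' `cfg$sweep` is set, [insert_sweep()] is applied before genotypes are
#' assembled. Byte-identical outputs for identical seeds.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_dataset`: `genotypes`
#'   (a [genotype_matrix()], observed population's samples first),
#'   `panels` (list of [haplotype_panel()] per chromosome, rows following
#'   the samples), `chrom_sizes` (named vector), `truth` (list: config
#'   echo, per-chromosome ancestral and per-population frequencies,
#'   sweep record or NULL).
#' @export
simulate_two_populations <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  labs <- cfg$pop_labels
  samples <- c(sprintf("%s_%02d", labs[1L], seq_len(n)),
               sprintf("%s_%02d", labs[2L], seq_len(n)))
  pop_of_sample <- rep(labs, each = n)
  F <- cfg$fst_target
  panels <- list(); freqs <- list()
  for (ci in seq_len(cfg$n_chrom)) {
    chrom <- paste0("chr", ci)
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$n_snps))
    gaps <- diff(pos)
    # Gaussian-copula draws: marginals stay Uniform / Balding-Nichols Beta,
    # but neighboring sites share similar quantiles
    p_anc <- cfg$maf_floor + (1 - 2 * cfg$maf_floor) *
      stats::pnorm(latent_ar1(gaps, cfg$freq_corr_rate))
    p_pop <- lapply(1:2, function(i)
      stats::rbeta(cfg$n_snps, p_anc * (1 - F) / F,
                   (1 - p_anc) * (1 - F) / F))
    H <- matrix(0L, nrow = 4L * n, ncol = cfg$n_snps)
    row <- 0L
    founders_by_pop <- list()
    for (pi in 1:2) {
      founders <- make_founders(p_pop[[pi]], gaps, cfg$n_founders,
                                cfg$founder_block_rate)
      founders_by_pop[[pi]] <- founders
      for (h in seq_len(2L * n)) {
        row <- row + 1L
        H[row, ] <- copy_haplotype(founders, gaps, cfg$copy_switch_rate)
      }
    }
    panels[[chrom]] <- haplotype_panel(chrom, pos, H,
                                       rep(samples, each = 2L))
    freqs[[chrom]] <- list(ancestral = p_anc,
                           pop1 = p_pop[[1L]], pop2 = p_pop[[2L]],
                           founders = founders_by_pop)
  }
  truth <- list(config = cfg, freqs = freqs, sweep = NULL)
  if (!is.null(cfg$sweep)) {
    sw <- insert_sweep(panels, truth, cfg$sweep, pop_of_sample)
    panels <- sw$panels; truth <- sw$truth
  }
  qual <- lapply(panels, function(p)
    round(stats::runif(length(p$positions), 25, 500), 1))
  g <- panels_to_genotypes(panels, pop_of_sample, qual)
  structure(list(genotypes = g, panels = panels,
                 chrom_sizes = stats::setNames(
                   rep(cfg$chrom_length_bp, cfg$n_chrom),
                   paste0("chr", seq_len(cfg$n_chrom))),
                 truth = truth),
            class = "synthetic_dataset")
}

#' Overwrite haplotypes with a hard sweep
#'
#' Picks the first founder haplotype of the target population as the sweep
#' haplotype; a `carrier_fraction` of the population's haplotypes (sampled
#' at random) have their alleles replaced by the sweep haplotype over
#' `[focal - L, focal + R]`, with `L, R ~ Exponential(mean =
#' erosion_mean_bp)` drawn independently per carrier — mimicking
#' recombination erosion of the swept core.
#'
#' @param panels list of [haplotype_panel()] (pooled populations).
#' @param truth truth list carrying `freqs` (for the founder panel).
#' @param sweep sweep settings (see [synthetic_config()]).
#' @param pop_of_sample population label per sample, ordered as the
#'   panels' samples.
#' @return list with modified `panels` and updated `truth` (`truth$sweep`
#'   records chrom, focal position, population, carrier rows and erosion
#'   intervals).
#' @export
insert_sweep <- function(panels, truth, sweep, pop_of_sample) {
  chrom <- names(panels)[sweep$chrom]
  p <- panels[[chrom]]
  pop_of_hap <- rep(pop_of_sample, each = 2L)
  rows <- which(pop_of_hap == sweep$pop)
  n_carrier <- round(sweep$carrier_fraction * length(rows))
  carriers <- sort(sample(rows, n_carrier))
  pi <- if (sweep$pop == pop_of_sample[1L]) 1L else 2L
  sweep_hap <- truth$freqs[[chrom]]$founders[[pi]][1L, ]
  H <- p$haplotypes
  spans <- matrix(0, nrow = n_carrier, ncol = 2L)
  for (i in seq_along(carriers)) {
    L <- stats::rexp(1L, rate = 1 / sweep$erosion_mean_bp)
    R <- stats::rexp(1L, rate = 1 / sweep$erosion_mean_bp)
    lo <- sweep$focal_pos - L; hi <- sweep$focal_pos + R
    cols <- which(p$positions >= lo & p$positions <= hi)
    H[carriers[i], cols] <- sweep_hap[cols]
    spans[i, ] <- c(lo, hi)
  }
  panels[[chrom]] <- haplotype_panel(p$chrom, p$positions, H,
                                     p$sample_of_haplotype)
  truth$sweep <- list(chrom = chrom, focal_pos = sweep$focal_pos,
                      pop = sweep$pop,
                      carrier_fraction = sweep$carrier_fraction,
                      carrier_rows = carriers, spans = spans)
  list(panels = panels, truth = truth)
}

#' Assemble a genotype matrix from haplotype panels
#'
#' @param panels list of [haplotype_panel()] (same samples, same order).
#' @param pop_of_sample population label per sample.
#' @param qual optional list of per-panel quality vectors.
#' @return a [genotype_matrix()].
#' @export
panels_to_genotypes <- function(panels, pop_of_sample, qual = NULL) {
  vs <- list(); ds <- list()
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    vs[[i]] <- data.frame(chrom = p$chrom, pos = p$positions,
                          ref = "A", alt = "C",
                          qual = if (is.null(qual)) NA_real_ else qual[[i]],
                          stringsAsFactors = FALSE)
    ds[[i]] <- panel_dosages(p)
  }
  odd <- seq(1L, nrow(panels[[1L]]$haplotypes), by = 2L)
  samples <- panels[[1L]]$sample_of_haplotype[odd]
  genotype_matrix(do.call(rbind, vs), samples, pop_of_sample,
                  do.call(cbind, ds))
}

#' Write a complete simulated fixture to disk
#'
#' Emits a phased VCF (`haplotypes.vcf`), the sample/population table
#' (`pops.tsv`), a chromosome-sizes file (`chrom_sizes.tsv`), the ground
#' truth (`truth.json`), and a coherent toy annotation over the same
#' coordinates: `genes.bed`, `qtl.tsv` (containing one deliberately
#' over-length QTL > 1 Mb), and a flat `terms.tsv` term-to-gene map. All
#' files are plain text.
#'
#' @param sim a `synthetic_dataset` from [simulate_two_populations()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  qual <- lapply(names(sim$panels), function(ch)
    sim$genotypes$variants$qual[sim$genotypes$variants$chrom == ch])
  write_haplotypes(sim$panels, pth("haplotypes.vcf"), "vcf", qual = qual)
  utils::write.table(
    data.frame(sample = sim$genotypes$samples,
               label = sim$genotypes$pop_labels),
    pth("pops.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(chrom = names(sim$chrom_sizes),
               len = sprintf("%d", as.integer(sim$chrom_sizes))),
    pth("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  truth_out <- list(
    fst_target = sim$truth$config$fst_target,
    seed = sim$truth$config$seed,
    sweep = if (is.null(sim$truth$sweep)) NULL else
      sim$truth$sweep[c("chrom", "focal_pos", "pop", "carrier_fraction")])
  jsonlite::write_json(truth_out, pth("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  ann <- make_toy_annotation(sim$chrom_sizes)
  utils::write.table(
    data.frame(ann$genes$chrom, ann$genes$start - 1L, ann$genes$end,
               ann$genes$gene_id, 0L, ann$genes$strand),
    pth("genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(ann$qtl, pth("qtl.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ann$terms, pth("terms.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = pth("haplotypes.vcf"), pops = pth("pops.tsv"),
              chrom_sizes = pth("chrom_sizes.tsv"), truth = pth("truth.json"),
              genes = pth("genes.bed"), qtl = pth("qtl.tsv"),
              terms = pth("terms.tsv")))
}

#' Toy annotation fixtures over simulated coordinates
#'
#' Deterministic (given the current RNG state) gene models tiled along each
#' chromosome, a QTL table in the four trait classes — including exactly
#' one over-length (> 1 Mb) QTL and one > 50%-overlapping pair, so the
#' cleaning rules have planted cases — and a flat term-to-gene map.
#'
#' @param chrom_sizes named vector of chromosome lengths.
#' @param genes_per_mb gene density (default 10).
#' @return list: `genes`, `qtl`, `terms` data.frames.
#' @export
make_toy_annotation <- function(chrom_sizes, genes_per_mb = 10) {
  genes <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    n <- max(2L, round(genes_per_mb * len / 1e6))
    start <- sort(sample.int(len - 20000L, n))
    end <- pmin(start + sample(2000:20000, n, replace = TRUE), len)
    data.frame(gene_id = sprintf("%s_g%03d", ch, seq_len(n)),
               name = sprintf("%s_g%03d", ch, seq_len(n)), chrom = ch,
               start = start, end = end,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  classes <- c("healthy", "production", "physiological", "other")
  qtl <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    n <- max(4L, round(len / 1e6) * 3L)
    start <- sort(sample.int(len - 600000L, n))
    width <- sample(30000:600000, n, replace = TRUE)
    data.frame(qtl_id = sprintf("%s_q%03d", ch, seq_len(n)),
               trait = sprintf("trait_%s_%d", ch, seq_len(n)),
               trait_class = sample(classes, n, replace = TRUE),
               chrom = ch, start = start,
               end = pmin(start + width, len), stringsAsFactors = FALSE)
  }))
  ch1 <- names(chrom_sizes)[1L]
  planted <- data.frame(
    qtl_id = c("planted_long", "planted_ovl_a", "planted_ovl_b"),
    trait = c("oversized", "pair_a", "pair_b"),
    trait_class = c("other", "production", "production"),
    chrom = ch1,
    start = c(1e5, 1.5e6, 1.55e6),
    end = c(1e5 + 1.2e6, 1.5e6 + 1e5, 1.55e6 + 6e4),
    stringsAsFactors = FALSE)
  qtl <- rbind(qtl, planted)
  n_terms <- 8L
  terms <- do.call(rbind, lapply(seq_len(n_terms), function(t) {
    gs <- sample(genes$gene_id, max(3L, round(nrow(genes) / n_terms)))
    data.frame(term_id = sprintf("term_%02d", t), gene_id = gs,
               stringsAsFactors = FALSE)
  }))
  rownames(qtl) <- rownames(genes) <- NULL
  list(genes = genes, qtl = qtl, terms = terms)
}
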