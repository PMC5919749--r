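test_that("simulation is seed-deterministic and shape-correct", {
  cfg <- synthetic_config(n_samples = 10L, n_chrom = 2L, n_snps = 50L,
                          chrom_length_bp = 5e5, seed = 71)
  a <- simulate_two_populations(cfg)
  b <- simulate_two_populations(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$panels$chr1$haplotypes, b$panels$chr1$haplotypes)
  expect_equal(dim(a$genotypes$dosages), c(20L, 100L))
  expect_equal(nrow(a$panels$chr2$haplotypes), 40L)
  # haplotype pairs collapse to the genotype dosages
  expect_equal(unname(cbind(panel_dosages(a$panels$chr1),
                            panel_dosages(a$panels$chr2))),
               unname(a$genotypes$dosages))
})

test_that("realized divergence tracks the F_ST target", {
  # near-panmixia: tiny target gives near-zero realized F_ST
  cfg0 <- synthetic_config(n_samples = 60L, n_chrom = 1L, n_snps = 400L,
                           chrom_length_bp = 2e6, fst_target = 0.001,
                           n_founders = 200L, seed = 72)
  fst0 <- hudson_fst(simulate_two_populations(cfg0)$genotypes)$overall
  expect_lt(abs(fst0), 0.02)
  # moderate divergence is recovered across seeds
  fsts <- vapply(1:5, function(s) {
    cfg <- synthetic_config(n_samples = 50L, n_chrom = 1L, n_snps = 500L,
                            chrom_length_bp = 2e6, fst_target = 0.2,
                            seed = 720L + s)
    hudson_fst(simulate_two_populations(cfg)$genotypes)$overall
  }, numeric(1))
  expect_gt(mean(fsts), 0.15)
  expect_lt(mean(fsts), 0.25)
  # monotone in the target
  m_of <- function(f, s) hudson_fst(simulate_two_populations(
    synthetic_config(n_samples = 40L, n_chrom = 1L, n_snps = 400L,
                     chrom_length_bp = 2e6, fst_target = f,
                     seed = s))$genotypes)$overall
  grid <- vapply(c(0.05, 0.15, 0.35), function(f)
    mean(vapply(1:3, function(s) m_of(f, 7200L + s), numeric(1))),
    numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("a planted sweep raises haplotype homozygosity in the swept population", {
  cfg <- synthetic_config(n_chrom = 1L, n_snps = 800L, chrom_length_bp = 3e6,
                          sweep = list(pop = "popA", chrom = 1L,
                                       focal_pos = 1.5e6,
                                       carrier_fraction = 0.9,
                                       erosion_mean_bp = 1e5),
                          seed = 73)
  sim <- simulate_two_populations(cfg)
  pa <- subset_panels(sim$panels, sim$genotypes, "popA")$chr1
  pb <- subset_panels(sim$panels, sim$genotypes, "popB")$chr1
  core <- which.min(abs(pa$positions - 1.5e6))
  # direct homozygosity at the focal site over a +/- 20-SNP window
  hom <- function(H, win) {
    keys <- apply(H[, win, drop = FALSE], 1, paste, collapse = "")
    cnt <- table(keys)
    sum(cnt * (cnt - 1)) / (nrow(H) * (nrow(H) - 1))
  }
  win <- (core - 20L):(core + 20L)
  expect_gt(hom(pa$haplotypes, win), hom(pb$haplotypes, win))
  # carrier fraction = 1 with near-infinite erosion: swept population is
  # haplotype-monomorphic, EHH = 1 everywhere
  cfg_fix <- synthetic_config(n_samples = 6L, n_chrom = 1L, n_snps = 60L,
                              chrom_length_bp = 5e5,
                              sweep = list(pop = "popA", chrom = 1L,
                                           focal_pos = 2.5e5,
                                           carrier_fraction = 1,
                                           erosion_mean_bp = 1e12),
                              seed = 74)
  sim_fix <- simulate_two_populations(cfg_fix)
  pfix <- subset_panels(sim_fix$panels, sim_fix$genotypes, "popA")$chr1
  expect_equal(nrow(unique(pfix$haplotypes)), 1L)
  cv <- ehh_curve(pfix, 30L, "right")
  expect_true(all(cv$ehh == 1))
})

test_that("the scan sign follows which population carries the sweep", {
  cfg <- synthetic_config(n_samples = 25L, n_chrom = 1L, n_snps = 600L,
                          chrom_length_bp = 3e6,
                          sweep = list(pop = "popA", chrom = 1L,
                                       focal_pos = 1.5e6,
                                       carrier_fraction = 0.9,
                                       erosion_mean_bp = 2e5),
                          seed = 75)
  sim <- simulate_two_populations(cfg)
  pa <- subset_panels(sim$panels, sim$genotypes, "popA")
  pb <- subset_panels(sim$panels, sim$genotypes, "popB")
  tr <- normalize_scores(xpehh_scan(pa, pb))
  i <- which.max(abs(tr$z))
  expect_gt(tr$z[i], 0)
  expect_lt(abs(tr$pos[i] - 1.5e6), 2e5)
  tr_swap <- normalize_scores(xpehh_scan(pb, pa))
  j <- which.max(abs(tr_swap$z))
  expect_lt(tr_swap$z[j], 0)
})

test_that("LD extent shrinks as founder copying switches faster", {
  ext_of <- function(csr) {
    cfg <- synthetic_config(n_chrom = 1L, copy_switch_rate = csr, seed = 76)
    sim <- simulate_two_populations(cfg)
    pops <- split_by_population(sim$genotypes)
    cv <- ld_decay_curve(pairwise_r2(pops$popA, 5e5), bin_width_bp = 1e4,
                         max_distance_bp = 5e5)
    ld_extent(cv, 0.3)
  }
  exts <- vapply(c(1e-6, 4e-6, 1.2e-5), ext_of, numeric(1))
  expect_true(all(diff(exts) < 0))
})

test_that("written fixtures round trip and the planted QTL case survives", {
  dir <- file.path(tempdir(), "fixture_test")
  cfg <- synthetic_config(n_samples = 8L, n_chrom = 2L, n_snps = 40L,
                          chrom_length_bp = 4e6,
                          sweep = list(pop = "popA", chrom = 1L,
                                       focal_pos = 2e6,
                                       carrier_fraction = 0.8,
                                       erosion_mean_bp = 1e5),
                          seed = 77)
  sim <- simulate_two_populations(cfg)
  files <- write_fixture(sim, dir)
  g <- read_genotypes(files["vcf"], "vcf", pops = files["pops"])
  expect_equal(unname(g$dosages), unname(sim$genotypes$dosages))
  expect_equal(g$pop_labels, sim$genotypes$pop_labels)
  panels <- read_haplotypes(files["vcf"], "vcf")
  expect_equal(panels$chr1$haplotypes, sim$panels$chr1$haplotypes,
               ignore_attr = TRUE)
  sizes <- read_chrom_sizes(files["chrom_sizes"])
  expect_equal(sizes, sim$chrom_sizes)
  truth <- jsonlite::read_json(files["truth"])
  expect_equal(truth$sweep$focal_pos, 2e6)
  expect_equal(truth$sweep$pop, "popA")
  # the bundled QTL table carries exactly one over-length record, and
  # prepare_qtl drops exactly it
  qtl <- read_qtl(files["qtl"])
  expect_equal(qtl$qtl_id[qtl$length > 1e6], "planted_long")
  cleaned <- prepare_qtl(qtl)
  expect_false("planted_long" %in% cleaned$qtl_id)
  # the planted 83%-overlap pair merged into one record
  expect_false(all(c("planted_ovl_a", "planted_ovl_b") %in% cleaned$qtl_id))
  genes <- read_genes(files["genes"], "bed")
  expect_true(nrow(genes) > 0)
})
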