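---
title: "Detecting selection between two populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection between two populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistics it implements,
the choices that were genuinely open, and what the synthetic-data tests
do and do not establish about real data.

## The problem

Two populations of the same species — in the motivating setting, two
chicken breeds under different selection regimes — are genotyped at
genome-wide SNPs. Loci under recent positive selection in one population
leave a footprint: a long haplotype at unusually high frequency, locally
elevated homozygosity, and a large allele-frequency difference between
the populations. The package detects such footprints three ways and then
reduces SNP-level signals to annotated candidate regions:

1. **XP-EHH** — a haplotype-length contrast between the populations;
2. **EigenGWAS** — single-marker regression of a PCA eigenvector on
   genotypes, with genomic-control deflation;
3. **Expedited mixed-model association** — kinship-corrected per-marker
   tests on the same eigenvector phenotypes.

## Genotype representation and filters

Genotypes are alt-allele dosages in {0, 1, 2}; missing calls are `NA`
and never conflated with the homozygous-reference 0 — the call-rate and
MAF arithmetic depends on that distinction. Variant QC applies four
rules: quality >= 20, chromosome in a whitelist of assembled
chromosomes (dropping unplaced scaffolds), call rate >= 90%, and pooled
minor allele frequency >= 5%, all inclusive at the boundary. Each
dropped variant is attributed to its *first* failing rule in that fixed
order so filter reports are deterministic. MAF is computed on the pooled
two-population sample because one merged SNP set is filtered before any
population-specific analysis.

## PCA and LD decay

PCA is the eigendecomposition of the sample covariance of the centered,
per-variant standardized dosage matrix, the population-genetics norm;
a centered-only variant is available (`standardize = FALSE`) since a
bare "eigendecomposition" leaves the scaling open. Missing dosages are
mean-imputed per variant for PCA only. `var_explained` is eigenvalue
over trace, eigenvalues descending.

LD is the squared Pearson correlation of dosage vectors, computed
within populations over intra-chromosomal pairs up to 1 Mb, binned at
10 kb. The decay curve averages per-chromosome bin means with equal
chromosome weights — the literal reading of "means across all
chromosomes" — with pair-weighted pooling behind a flag. The reported
"LD extent" at r² = 0.3 interpolates linearly between the midpoints of
the bracketing bins; a curve that starts below the threshold has extent
0 and a curve that never reaches it returns `NA` flagged
`beyond_range`.

## XP-EHH

For a core SNP, EHH at marker `m` is the probability that two
haplotypes drawn without replacement are identical at every marker from
the core out to `m` (counted over group sizes as
`sum C(n_k, 2) / C(n, 2)`). The statistic is
`ln(I_A / I_B)`: the log ratio of the trapezoid integrals of EHH over
physical distance in the observed (A) versus reference (B) population.
Raw scores are normalized genome-wide and referred to a standard normal
two-sidedly; sites with `p < 0.01` are outlier loci, positive z marking
selection in the observed population.

Decisions the method statement leaves open, and what this package does:

* **Allele handling at the core.** EHH is computed over *all*
  haplotypes, unconditional on the core allele — the cross-population
  statistic's convention; allele-stratified EHH belongs to the
  single-population tests, which are out of scope.
* **Integration boundary.** Both integrals stop where the EHH of the
  *pooled* panel falls below 0.05 (configurable). A shared boundary is
  what makes `ln(I_A/I_B)` comparable across sites; the boundary marker
  itself is included so the crossing is bracketed.
* **Distance.** Physical bp stand in for genetic distance; with any
  constant cM/Mb the scale factor cancels in the ratio.
* **Chromosome ends.** Cores whose window hits an end before the
  cutoff are scored but flagged `truncated`; `strict = TRUE` drops
  them. Sites with a zero integral are unscorable.
* **Normalization scope.** Genome-wide (not per chromosome, not
  frequency-binned) — the simplest single-normal-null reading. The z
  normalization uses the population (1/n) standard deviation.

The scan kernel is compiled (Rcpp); a pure-R reference engine
(`engine = "r"`) produces identical output and the suite asserts that,
plus exact agreement of EHH with a brute-force pairwise-identity count.

## From outliers to regions

Same-sign outlier loci closer than 10 kb (strict) merge transitively
into sections; sections grow 10 kb flanks on both sides, clipped to
`[1, chromosome length]`. Region length is `end - start` in bp: a
single-SNP region is then exactly 20.000 kb, which is also what pins
the flank default — every single-SNP region in the motivating study's
per-chromosome table has length exactly 20 kb, forcing flank = 10 kb
together with the `end - start` convention. Opposite-sign sections are
never merged (they mark different selected populations). When wide
flanks make same-sign regions touch, a post-pass merges them (on by
default). Summary tables report lengths in kb; coverage fractions use a
chromosome-sizes table.

## EigenGWAS and genomic control

Each selected eigenvector is regressed on each SNP's dosage (OLS with
intercept, missing dosages mean-imputed, monomorphic SNPs untested);
the Wald statistic `(beta/se)^2` is referred to a 1-df chi-square.
Drift between populations inflates these statistics genome-wide, so the
scan is deflated by `lambda_gc = median(chi2) / 0.4549364` (the 1-df
chi-square median). Components 2-5 are the plotting default; the
leading eigenvector simply encodes the gross two-population split and
is typically run separately. No automatic rule excludes any component —
that judgement is qualitative and left to the analyst.

## Expedited mixed-model association

Kinship comes from mean identity-by-state sharing (default) or the
standardized dosage cross-product. Variance components of
`y ~ N(Xb, sigma_g^2 K + sigma_e^2 I)` are fit once under the null by
REML, profiling `delta = sigma_e^2 / sigma_g^2` on the spectral
decomposition of K over a 100-point log grid on [1e-5, 1e5] with
golden-section refinement — deterministic, no random starts. Each SNP
is then tested by GLS with the components held fixed (the "expedited"
approximation; exact per-marker REML is out of scope). The Wald test
uses a residual-scaled standard error, so with `K = I` and zero genetic
variance the scan reduces *exactly* to the OLS scan — a reduction the
suite asserts at 1e-8. With an identity kinship the two components are
identifiable only through their sum; the fitted total then matches the
OLS residual variance.

## Annotation

Genes attach to regions by any-overlap (>= 1 shared bp, 1-based
inclusive intervals). QTL tables are cleaned first: records longer than
1 Mb (strictly) are dropped, and pairs overlapping by more than 50% *of
the shorter interval* merge into their union iteratively to a fixed
point — the denominator is a declared choice (a reciprocal-overlap flag
preserves the alternative), since the source rule says only ">50%".
QTL-to-region matching then requires *containment* in either direction;
partial overlaps do not count. These two different rules (any-overlap
for genes, containment for QTL) are both deliberate: they follow the
stated procedures for each case. Term enrichment is an upper-tail
hypergeometric test at a nominal 0.05 with no multiple-testing
correction applied to the call (a Benjamini-Hochberg column is emitted
for information); the original study's tool-specific enrichment
statistic is database- and version-dependent and is not reproduced.

## The synthetic-data generator

Real reduced-representation genotypes for two breeds cannot ship with
the package, so every stage is exercised on a generator that emulates
the three features the scans consume:

* **Divergence**: ancestral frequencies uniform on
  `(maf_floor, 1 - maf_floor)`, per-population frequencies
  Balding-Nichols Beta draws at `F = fst_target`.
* **Haplotype LD**: each population has `n_founders` founder
  haplotypes; sample haplotypes are Markov mosaics of founders with
  per-bp switch rate `copy_switch_rate` (a Li-Stephens-flavored copier
  rather than a coalescent: desk-scale, seed-deterministic, and
  sufficient to produce decaying EHH and r²).
* **A hard sweep**: a chosen founder haplotype overwrites a
  `carrier_fraction` of one population's haplotypes over
  `[focal - L, focal + R]`, `L, R ~ Exp(mean = erosion_mean_bp)` per
  carrier, mimicking recombination erosion.

Two refinements proved necessary for the generator to express the LD
the pipeline is supposed to summarize. Site-wise independent founder
alleles cap inter-site r² near `1/(n_founders - 1)` (~0.03 at 30
founders), so the r² = 0.3 extent would always be zero; founder alleles
therefore follow a latent-uniform Markov process along the chromosome
(`founder_block_rate`). Even then r² is bounded by allele-frequency
mismatch between sites, so ancestral frequencies are autocorrelated
through a Gaussian copula (`freq_corr_rate`) that leaves all marginals
— hence the realized F_ST — unchanged. Per-site drift stays
independent: correlating the Balding-Nichols draws themselves creates
long near-fixed runs that act as false sweeps, which is a property of
that modeling shortcut, not of breed divergence.

Defaults (2 x 50 samples, 2 chromosomes x 5 Mb x 2,000 SNPs,
`fst_target = 0.2`, 30 founders, switch rate 5e-6/bp, founder block
rate 5e-6/bp, frequency correlation 3e-5/bp) were calibrated once so
that each designed feature is expressed: realized Hudson F_ST ~ 0.2,
LD extent at r² = 0.3 in the 10-20 kb range (closer to the
short-extent breed of the motivating study than to its long-extent
one), and a default sweep (carrier fraction 0.9, erosion mean 200 kb)
that is the genome-wide top signal. The full pipeline on this fixture
runs in well under a minute.

What passing on this generator does *not* show: robustness to phasing
error (panels are perfect), to genotyping error and allele flips, to
variable recombination and SNP density, to more than two populations or
admixture, or to soft sweeps. The generator's LD ceiling (~0.4-0.5 r²
at short range) is also milder than the strongest livestock panels.

## Problem sizes and numerical choices

The test suite fixes its own study conditions: 50 seeded replicates of
the default sweep fixture for localization power (top region within
50 kb of the focal site, correct sign, >= 90% of runs); 50 replicates
at n = 200 for heritability recovery (mean in [0.4, 0.6] at a planted
0.5); 50 structured-null replicates of 3,500 SNPs x 50 samples for the
calibration comparison (mixed-model lambda closer to 1 than OLS lambda
in >= 45) — the marker count there is chosen so lambda's own sampling
noise (~1/sqrt(m)) does not dominate the comparison; 20 replicates of
10,000 iid SNPs for null genomic control in [0.9, 1.1]; and 100 random
panels for exact EHH-oracle agreement. Trapezoid integration, the
golden-section REML refinement tolerance (sqrt machine epsilon), and
the population-SD normalization are the only numerical knobs; ties and
duplicate positions are rejected upstream by the container invariants.

## Known limitations

* Biallelic SNPs only; multi-allelic records are rejected, not split.
* Phased, complete haplotype panels are an input contract — phasing
  and imputation live upstream.
* One kinship, one variance-component pair per phenotype; no
  covariates beyond the intercept by default.
* The containment-only QTL rule is conservative by construction;
  partially overlapping QTL are invisible to it.
* Physical distance stands in for genetic distance throughout.
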