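#' @name xpehh
#' @title Cross-population extended haplotype homozygosity scan
#' @description
#' EHH at a marker m, for a core site c, is the probability that two
#' haplotypes drawn without replacement from the panel are identical at
#' every marker from c out to m:
#' `EHH = sum_k C(n_k, 2) / C(n, 2)` over the groups of haplotypes sharing
#' the extended haplotype. The cross-population statistic for a core is
#' `ln(I_A / I_B)` where I_A and I_B are the trapezoid integrals of EHH
#' over physical distance in the observed (A) and reference (B)
#' populations, both truncated where the EHH of the *pooled* panel decays
#' below a cutoff so that the two integrals share limits. Positive values
#' indicate unusually long haplotype homozygosity — recent selection — in
#' the observed population.
NULL

# homozygosity of a grouping: sum C(n_k,2) / C(n,2)
group_homozygosity <- function(counts, n) {
  sum(counts * (counts - 1)) / (n * (n - 1))
}

# refine a haplotype grouping by the alleles at one marker; returns compact
# integer group ids in 1..k
refine_groups <- function(g, alleles) {
  key <- g * 2L + alleles
  match(key, unique(key))
}

#' EHH decay curve from a core site
#'
#' Steps marker by marker away from the core, refining haplotype identity
#' classes; the identity window always includes the core marker. The curve
#' is anchored at distance 0 with EHH = 1 and is non-increasing.
#'
#' @param panel a [haplotype_panel()].
#' @param core_index 1-based index of the core SNP.
#' @param side `"left"` or `"right"`.
#' @param cutoff stop once EHH falls below this value (that marker is still
#'   reported); 0 walks to the chromosome end.
#' @return list of class `ehh_curve`: `core_index`, `side`, `distances`
#'   (bp offsets, starting at 0), `ehh` (aligned homozygosity values),
#'   `hit_end` (`TRUE` when the chromosome end was reached before the
#'   cutoff).
#' @export
ehh_curve <- function(panel, core_index, side = c("left", "right"),
                      cutoff = 0) {
  side <- match.arg(side)
  H <- panel$haplotypes
  n <- nrow(H)
  if (n < 2L) stop("need at least two haplotypes")
  m <- length(panel$positions)
  stopifnot(core_index >= 1L, core_index <= m)
  step <- if (side == "left") -1L else 1L
  g <- refine_groups(rep(1L, n), H[, core_index])
  dist <- 0; ehh <- 1
  j <- core_index + step
  hit_end <- TRUE
  while (j >= 1L && j <= m) {
    g <- refine_groups(g, H[, j])
    h <- group_homozygosity(tabulate(g), n)
    dist <- c(dist, abs(panel$positions[j] - panel$positions[core_index]))
    ehh <- c(ehh, h)
    if (h < cutoff) { hit_end <- FALSE; break }
    j <- j + step
  }
  if (cutoff <= 0) hit_end <- FALSE
  structure(list(core_index = core_index, side = side,
                 distances = dist, ehh = ehh, hit_end = hit_end),
            class = "ehh_curve")
}

#' Integrate a pair of EHH curves
#'
#' Trapezoid-rule integral of EHH over physical distance, left side plus
#' right side (units: bp of homozygosity). A degenerate single-point side
#' contributes 0.
#'
#' @param left,right `ehh_curve` objects (or any list with `distances` and
#'   `ehh`) from the same core.
#' @return numeric integral in bp.
#' @export
integrate_ehh <- function(left, right) {
  trap <- function(cv) {
    if (length(cv$distances) < 2L) return(0)
    d <- diff(cv$distances)
    sum(d * (utils::head(cv$ehh, -1L) + utils::tail(cv$ehh, -1L)) / 2)
  }
  trap(left) + trap(right)
}

# one side of the cross-population integration for one core: walks outward
# refining obs / ref / combined groupings together, stopping when combined
# EHH < cutoff (boundary marker included) or the chromosome ends.
# Returns side integrals for obs and ref plus a truncation flag.
xpehh_side <- function(Hobs, Href, Hcomb, pos, core, step, cutoff) {
  n1 <- nrow(Hobs); n2 <- nrow(Href); nc <- nrow(Hcomb)
  g1 <- refine_groups(rep(1L, n1), Hobs[, core])
  g2 <- refine_groups(rep(1L, n2), Href[, core])
  gc_ <- refine_groups(rep(1L, nc), Hcomb[, core])
  m <- length(pos)
  last_d <- 0; e1_prev <- 1; e2_prev <- 1
  I1 <- 0; I2 <- 0
  j <- core + step
  truncated <- FALSE
  repeat {
    if (j < 1L || j > m) { truncated <- TRUE; break }
    gc_ <- refine_groups(gc_, Hcomb[, j])
    hc <- group_homozygosity(tabulate(gc_), nc)
    g1 <- refine_groups(g1, Hobs[, j])
    g2 <- refine_groups(g2, Href[, j])
    e1 <- group_homozygosity(tabulate(g1), n1)
    e2 <- group_homozygosity(tabulate(g2), n2)
    d <- abs(pos[j] - pos[core])
    I1 <- I1 + (d - last_d) * (e1_prev + e1) / 2
    I2 <- I2 + (d - last_d) * (e2_prev + e2) / 2
    last_d <- d; e1_prev <- e1; e2_prev <- e2
    if (hc < cutoff) break
    j <- j + step
  }
  list(I_obs = I1, I_ref = I2, truncated = truncated)
}

#' XP-EHH scan over matched haplotype panels
#'
#' For every core SNP, EHH is integrated outward in both directions until
#' the EHH of the pooled observed+reference panel falls below `ehh_cutoff`
#' (a shared boundary, so the two integrals are comparable), or the
#' chromosome ends (the site is then flagged `truncated`; `strict = TRUE`
#' drops such sites). The raw score is `ln(I_obs / I_ref)`. Sites where
#' either integral is zero are flagged unscorable.
#'
#' @param panels_obs,panels_ref [haplotype_panel()] objects (or lists of
#'   them, one per chromosome) with identical positions.
#' @param ehh_cutoff pooled-EHH integration boundary (default 0.05).
#' @param strict drop truncated sites instead of scoring them.
#' @param obs_label,ref_label population names recorded on the track.
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (reference
#'   implementation); both produce identical output.
#' @return A `score_track` data.frame: chrom, pos, raw, z (NA until
#'   [normalize_scores()]), p (NA until [scores_to_pvalues()]), truncated,
#'   scorable.
#' @export
xpehh_scan <- function(panels_obs, panels_ref, ehh_cutoff = 0.05,
                       strict = FALSE, obs_label = "obs",
                       ref_label = "ref", engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(panels_obs, "haplotype_panel")) panels_obs <- list(panels_obs)
  if (inherits(panels_ref, "haplotype_panel")) panels_ref <- list(panels_ref)
  if (length(panels_obs) != length(panels_ref))
    stop("panel lists differ in chromosome count")
  out <- vector("list", length(panels_obs))
  for (i in seq_along(panels_obs)) {
    po <- panels_obs[[i]]; pr <- panels_ref[[i]]
    if (!identical(po$positions, pr$positions) ||
        !identical(po$chrom, pr$chrom))
      stop("observed and reference panels must share positions")
    pos <- po$positions
    m <- length(pos)
    if (engine == "cpp") {
      res <- .xpehh_chrom_cpp(po$haplotypes, pr$haplotypes, pos, ehh_cutoff)
      raw <- res$raw; trunc <- res$truncated; scor <- res$scorable
    } else {
      Hc <- rbind(po$haplotypes, pr$haplotypes)
      raw <- rep(NA_real_, m); trunc <- logical(m); scor <- logical(m)
      for (core in seq_len(m)) {
        L <- xpehh_side(po$haplotypes, pr$haplotypes, Hc, pos, core, -1L,
                        ehh_cutoff)
        R <- xpehh_side(po$haplotypes, pr$haplotypes, Hc, pos, core, 1L,
                        ehh_cutoff)
        I_obs <- L$I_obs + R$I_obs
        I_ref <- L$I_ref + R$I_ref
        trunc[core] <- L$truncated || R$truncated
        if (I_obs > 0 && I_ref > 0) {
          scor[core] <- TRUE
          raw[core] <- log(I_obs / I_ref)
        }
      }
    }
    if (strict) scor <- scor & !trunc
    out[[i]] <- data.frame(chrom = po$chrom, pos = pos, raw = raw,
                           z = NA_real_, p = NA_real_,
                           truncated = trunc, scorable = scor)
  }
  track <- do.call(rbind, out)
  rownames(track) <- NULL
  if (!any(track$scorable)) stop("all sites unscorable")
  track$raw[!track$scorable] <- NA_real_
  attr(track, "obs_label") <- obs_label
  attr(track, "ref_label") <- ref_label
  class(track) <- c("score_track", "data.frame")
  track
}

#' Genome-wide normalization of raw scan scores
#'
#' Centers and scales raw scores to z-scores using the genome-wide mean and
#' population (1/n) standard deviation over all scorable sites, pooled
#' across chromosomes. By construction mean(z) = 0 and sd(z) = 1.
#'
#' @param track a `score_track` with `raw` filled.
#' @return the track with `z` filled.
#' @export
normalize_scores <- function(track) {
  x <- track$raw[track$scorable]
  if (length(x) < 2L) stop("need at least two scorable sites")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  if (sdev == 0) stop("raw scores have zero variance")
  track$z <- (track$raw - mu) / sdev
  track
}

#' Two-sided normal p-values for normalized scores
#'
#' `p = 2 * (1 - Phi(|z|))` under the standard normal null the empirical
#' score distribution is referred to.
#'
#' @param track a `score_track` with `z` filled.
#' @return the track with `p` filled.
#' @export
scores_to_pvalues <- function(track) {
  if (all(is.na(track$z))) stop("normalize scores first")
  track$p <- 2 * stats::pnorm(-abs(track$z))
  track
}
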