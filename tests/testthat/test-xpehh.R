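test_that("EHH equals the brute-force pairwise identity count on random panels", {
  set.seed(21)
  for (rep in 1:25) {
    n_hap <- 2L * sample(2:8, 1L)
    m <- sample(5:25, 1L)
    p <- random_panel(n_hap, m)
    core <- sample(seq_len(m), 1L)
    for (side in c("left", "right")) {
      got <- ehh_curve(p, core, side)
      want <- brute_ehh(p$haplotypes, core, side)
      expect_equal(got$ehh, want, tolerance = 1e-12,
                   info = sprintf("rep %d core %d %s", rep, core, side))
      expect_true(all(diff(got$ehh) <= 1e-12))   # monotone non-increasing
      expect_equal(got$ehh[1L], 1)
    }
  }
})

test_that("EHH hits the textbook anchor cases", {
  pos <- c(100L, 200L, 300L)
  # 4 identical haplotypes: EHH 1 everywhere
  H1 <- matrix(1L, nrow = 4, ncol = 3)
  p1 <- haplotype_panel("chr1", pos, H1, rep(c("a", "b"), each = 2))
  expect_equal(ehh_curve(p1, 1L, "right")$ehh, c(1, 1, 1))
  # two groups of two past the core: 1 -> 2*C(2,2)/C(4,2) = 1/3
  H2 <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 1L), c(1L, 1L, 1L))
  p2 <- haplotype_panel("chr1", pos, H2, rep(c("a", "b"), each = 2))
  expect_equal(ehh_curve(p2, 1L, "right")$ehh[2L], 1 / 3)
  # all-distinct haplotypes past the core: EHH 0
  H3 <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  p3 <- haplotype_panel("chr1", pos, H3, rep(c("a", "b"), each = 2))
  expect_equal(ehh_curve(p3, 1L, "right")$ehh[3L], 0)
})

test_that("EHH integration follows the trapezoid rule", {
  # constant EHH = 1 over 10 kb per side: rectangle of 20,000
  cv <- function(d, e) list(distances = d, ehh = e)
  expect_equal(integrate_ehh(cv(c(0, 10000), c(1, 1)),
                             cv(c(0, 10000), c(1, 1))), 20000)
  # single trapezoid: [0, 1000] x [1, 0.5] -> 750
  expect_equal(integrate_ehh(cv(c(0, 1000), c(1, 0.5)), cv(0, 1)), 750)
  # degenerate single-point side contributes 0
  expect_equal(integrate_ehh(cv(0, 1), cv(0, 1)), 0)
  # random step curve vs a fine-grid Riemann sum
  set.seed(22)
  d <- cumsum(c(0, sample.int(500, 20)))
  e <- c(1, sort(stats::runif(20), decreasing = TRUE))
  grid <- seq(0, max(d), by = 0.25)
  lin <- stats::approx(d, e, xout = grid)$y
  riemann <- sum((lin[-1] + lin[-length(lin)]) / 2 * diff(grid))
  expect_equal(integrate_ehh(cv(d, e), cv(0, 1)), riemann,
               tolerance = 1e-9)
})

test_that("identical panels score 0 and swapping panels negates raw scores", {
  set.seed(23)
  p_obs <- random_panel(12, 40)
  p_ref <- random_panel(12, 40)
  p_ref$positions <- p_obs$positions
  tr_same <- xpehh_scan(p_obs, p_obs, ehh_cutoff = 0.05)
  expect_true(all(abs(tr_same$raw[tr_same$scorable]) < 1e-12))
  tr <- xpehh_scan(p_obs, p_ref, ehh_cutoff = 0.05)
  tr_swap <- xpehh_scan(p_ref, p_obs, ehh_cutoff = 0.05)
  expect_equal(tr$scorable, tr_swap$scorable)
  expect_equal(tr$raw[tr$scorable], -tr_swap$raw[tr_swap$scorable],
               tolerance = 1e-12)
  expect_equal(tr$truncated, tr_swap$truncated)
})

test_that("homogeneous observed vs diverse reference panel forces raw > 0", {
  pos <- sort(sample.int(1e5, 15))
  H_obs <- matrix(rep(c(0L, 1L), length.out = 15 * 8), nrow = 8,
                  ncol = 15, byrow = TRUE)   # 8 identical haplotypes
  set.seed(24)
  H_ref <- matrix(stats::rbinom(8 * 15, 1, 0.5), nrow = 8)
  p_obs <- haplotype_panel("chr1", pos, H_obs, rep(paste0("o", 1:4), each = 2))
  p_ref <- haplotype_panel("chr1", pos, H_ref, rep(paste0("r", 1:4), each = 2))
  tr <- xpehh_scan(p_obs, p_ref, ehh_cutoff = 0.05)
  expect_true(all(tr$raw[tr$scorable] > 0))
})

test_that("the scan reproduces an end-to-end hand computation on 8 haplotypes", {
  # deterministic panels small enough to integrate by hand rules in R
  pos <- c(1000L, 3000L, 6000L, 10000L, 15000L)
  H_obs <- rbind(c(0L, 1L, 0L, 1L, 0L),
                 c(0L, 1L, 0L, 1L, 1L),
                 c(1L, 1L, 0L, 0L, 0L),
                 c(1L, 1L, 1L, 0L, 0L))
  H_ref <- rbind(c(0L, 0L, 1L, 1L, 0L),
                 c(1L, 0L, 1L, 0L, 1L),
                 c(0L, 1L, 0L, 1L, 0L),
                 c(1L, 1L, 0L, 0L, 1L))
  p_obs <- haplotype_panel("chr1", pos, H_obs, rep(c("o1", "o2"), each = 2))
  p_ref <- haplotype_panel("chr1", pos, H_ref, rep(c("r1", "r2"), each = 2))
  core <- 3L
  cutoff <- 0.05
  # oracle: walk outward with brute-force EHH on each panel, pooled panel
  # deciding the stopping marker, trapezoid integrals per side
  oracle_side <- function(step) {
    Hc <- rbind(H_obs, H_ref)
    win <- core
    I <- c(obs = 0, ref = 0)
    last <- c(0, 1, 1)  # distance, ehh_obs, ehh_ref
    j <- core + step
    while (j >= 1 && j <= length(pos)) {
      win <- sort(c(win, j))
      idset <- function(H) {
        keys <- apply(H[, win, drop = FALSE], 1, paste, collapse = "")
        cnt <- table(keys)
        sum(cnt * (cnt - 1)) / (nrow(H) * (nrow(H) - 1))
      }
      d <- abs(pos[j] - pos[core])
      e_obs <- idset(H_obs); e_ref <- idset(H_ref); e_c <- idset(Hc)
      I["obs"] <- I["obs"] + (d - last[1]) * (last[2] + e_obs) / 2
      I["ref"] <- I["ref"] + (d - last[1]) * (last[3] + e_ref) / 2
      last <- c(d, e_obs, e_ref)
      if (e_c < cutoff) break
      j <- j + step
    }
    I
  }
  IL <- oracle_side(-1L); IR <- oracle_side(1L)
  want <- log((IL["obs"] + IR["obs"]) / (IL["ref"] + IR["ref"]))
  tr <- xpehh_scan(p_obs, p_ref, ehh_cutoff = cutoff)
  expect_equal(tr$raw[core], unname(want), tolerance = 1e-12)
})

test_that("compiled and reference scan engines produce identical tracks", {
  set.seed(25)
  p_obs <- random_panel(10, 30)
  p_ref <- random_panel(10, 30)
  p_ref$positions <- p_obs$positions
  a <- xpehh_scan(p_obs, p_ref, engine = "cpp")
  b <- xpehh_scan(p_obs, p_ref, engine = "r")
  expect_identical(a$scorable, b$scorable)
  expect_equal(a$raw, b$raw, tolerance = 1e-12)
  expect_identical(a$truncated, b$truncated)
})

test_that("normalization yields zero-mean unit-sd z and is affine invariant", {
  tr <- mk_track("chr1", c(100L, 200L, 300L), c(0, 0, 0))
  tr$raw <- c(-1, 0, 1)
  nz <- normalize_scores(tr)
  expect_equal(nz$z, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  set.seed(26)
  tr2 <- mk_track("chr1", sort(sample.int(1e6, 500)), stats::rnorm(500))
  tr2$raw <- stats::rnorm(500)
  nz2 <- normalize_scores(tr2)
  expect_lt(abs(mean(nz2$z)), 1e-6)
  expect_lt(abs(sqrt(mean(nz2$z^2)) - 1), 1e-6)
  tr3 <- tr2
  tr3$raw <- 3.7 * tr2$raw - 2.2
  expect_equal(normalize_scores(tr3)$z, nz2$z, tolerance = 1e-9)
})

test_that("two-sided normal p-values hit their anchor quantiles", {
  tr <- mk_track("chr1", c(100L, 200L, 300L), c(0, 0, 0))
  tr$z <- c(0, stats::qnorm(1 - 0.005), -stats::qnorm(1 - 0.005))
  pv <- scores_to_pvalues(tr)
  expect_equal(pv$p[1L], 1)
  expect_equal(pv$p[2L], 0.01, tolerance = 1e-12)
  expect_equal(pv$p[2L], pv$p[3L])
  expect_equal(2 * (1 - stats::pnorm(2.575829)), 0.01, tolerance = 1e-4)
})
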