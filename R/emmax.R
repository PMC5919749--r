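#' Genome-wide kinship matrix
#'
#' `"ibs"`: mean identity-by-state sharing over non-missing sites,
#' `1 - |d_i - d_j| / 2` averaged across SNPs (diagonal 1).
#' `"standardized"`: cross-product of centered, sd-scaled dosages divided
#' by the SNP count (diagonal approx. 1 + inbreeding). Monomorphic SNPs
#' are skipped by the standardized estimator.
#'
#' @param g a [genotype_matrix()].
#' @param method `"ibs"` (default) or `"standardized"`.
#' @return symmetric n x n matrix of class `kinship_matrix` with sample
#'   ids as dimnames.
#' @export
compute_kinship <- function(g, method = c("ibs", "standardized")) {
  method <- match.arg(method)
  D <- g$dosages
  storage.mode(D) <- "double"
  if (method == "ibs") {
    n <- nrow(D)
    K <- matrix(0, n, n)
    obs <- !is.na(D)
    D0 <- D; D0[!obs] <- 0
    # sum over shared non-missing sites of (1 - |di - dj|/2), pairwise:
    # |di-dj| decomposed via indicator matrices for dosages 0/1/2
    I0 <- (D0 == 0) & obs; I1 <- (D0 == 1) & obs; I2 <- (D0 == 2) & obs
    n_shared <- tcrossprod(obs * 1)
    absdiff <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
      tcrossprod(I1, I2) + tcrossprod(I2, I1) +
      2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
    if (any(n_shared == 0)) stop("sample pair with no shared non-missing SNPs")
    K <- 1 - absdiff / (2 * n_shared)
  } else {
    Z <- standardize_dosages(D, scale = TRUE)
    if (ncol(Z) == 0L) stop("no polymorphic SNPs")
    K <- tcrossprod(Z) / ncol(Z)
  }
  dimnames(K) <- list(g$samples, g$samples)
  K <- (K + t(K)) / 2
  class(K) <- c("kinship_matrix", class(K))
  K
}

#' One-shot REML variance components under a kinship covariance
#'
#' Fits `y ~ N(X beta, sigma_g^2 K + sigma_e^2 I)` by restricted maximum
#' likelihood, profiling over `delta = sigma_e^2 / sigma_g^2` on the
#' spectral decomposition of K: a 100-point log-spaced grid on
#' [1e-5, 1e5] followed by golden-section refinement around the grid
#' optimum. Deterministic; no random starts. With `K = I` the split of the
#' total variance is not identifiable — only the total is meaningful.
#'
#' @param y numeric phenotype vector.
#' @param K kinship matrix (PSD).
#' @param X fixed-effect design matrix including the intercept (default:
#'   intercept only).
#' @return list of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `delta`, `h2`, `reml_loglik`, and the reusable spectral pieces
#'   (`eigen_K`).
#' @export
reml_fit <- function(y, K, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (nrow(K) != n || nrow(X) != n) stop("dimension mismatch")
  if (stats::sd(y) == 0) stop("constant phenotype")
  eK <- eigen(unclass(K), symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(abs(eK$values)))
    stop("kinship matrix is not positive semidefinite")
  S <- pmax(eK$values, 0)
  U <- eK$vectors
  ys <- as.vector(crossprod(U, y))
  Xs <- crossprod(U, X)
  p <- ncol(X)
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  # restricted log-likelihood profiled over sigma_g2, as a function of delta
  rll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (S + delta)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    beta <- solve(XtWX, XtWy)
    r <- ys - Xs %*% beta
    rss <- sum(w * r^2)
    sg2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * sg2) + (n - p) +
              sum(log(S + delta)) +
              determinant(XtWX, logarithm = TRUE)$modulus - ldXX)
  }
  grid <- seq(log(1e-5), log(1e5), length.out = 100L)
  vals <- vapply(grid, rll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  best_ll <- max(opt$objective, vals[i])
  log_delta <- if (opt$objective >= vals[i]) opt$maximum else grid[i]
  delta <- exp(log_delta)
  w <- 1 / (S + delta)
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  rss <- sum(w * (ys - Xs %*% beta)^2)
  sg2 <- rss / (n - p)
  se2 <- sg2 * delta
  structure(list(sigma_g2 = sg2, sigma_e2 = se2, delta = delta,
                 h2 = sg2 / (sg2 + se2),
                 reml_loglik = as.numeric(best_ll),
                 grid_logdelta = grid, grid_loglik = vals,
                 eigen_K = list(values = S, vectors = U)),
            class = "variance_components")
}

#' Expedited mixed-model association scan
#'
#' Variance components are estimated once under the null model
#' ([reml_fit()]) and then held fixed; each SNP is tested by generalized
#' least squares under covariance `sigma_g^2 K + sigma_e^2 I`, implemented
#' by rotating phenotype, intercept and dosage into the kinship
#' eigenbasis and whitening by the per-coordinate variances. The Wald
#' chi-square uses the residual-scaled standard error, so with `K = I` and
#' `sigma_g^2 = 0` the scan reduces exactly to the OLS scan.
#'
#' @param g a [genotype_matrix()].
#' @param y phenotype vector.
#' @param K kinship matrix used in `vc`.
#' @param vc a `variance_components` fit from [reml_fit()] on the same K.
#' @param phenotype_id label stored on the track.
#' @return an `association_track` (chrom, pos, beta, se, chi2, p_raw,
#'   tested).
#' @export
emmax_scan <- function(g, y, K, vc, phenotype_id = "pheno") {
  n <- length(y)
  if (nrow(g$dosages) != n) stop("dimension mismatch")
  S <- vc$eigen_K$values; U <- vc$eigen_K$vectors
  w <- 1 / sqrt(vc$sigma_g2 * S + vc$sigma_e2)
  yt <- w * as.vector(crossprod(U, y))
  it <- w * as.vector(crossprod(U, rep(1, n)))   # transformed intercept
  X <- g$dosages
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na)) X[na] <- mu[na[, 2L]]
  mono <- apply(X, 2L, stats::sd) == 0
  Xt <- crossprod(U, X) * w
  # per-SNP 2x2 GLS with columns (intercept_t, snp_t), closed form
  a11 <- sum(it^2)
  a12 <- as.vector(crossprod(Xt, it))
  a22 <- colSums(Xt^2)
  b1 <- sum(it * yt)
  b2 <- as.vector(crossprod(Xt, yt))
  det <- a11 * a22 - a12^2
  tested <- !mono & det > .Machine$double.eps * a11 * a22
  beta <- ifelse(tested, (a11 * b2 - a12 * b1) / det, NA_real_)
  alpha <- ifelse(tested, (a22 * b1 - a12 * b2) / det, NA_real_)
  yty <- sum(yt^2)
  rss <- pmax(yty - (alpha * b1 + beta * b2), 0)
  s2 <- rss / (n - 2L)
  se <- ifelse(tested & s2 > 0, sqrt(s2 * a11 / det), NA_real_)
  chi2 <- ifelse(tested & !is.na(se), (beta / se)^2, NA_real_)
  out <- data.frame(chrom = g$variants$chrom, pos = g$variants$pos,
                    beta = beta, se = se, chi2 = chi2,
                    p_raw = stats::pchisq(chi2, 1L, lower.tail = FALSE),
                    tested = tested & !is.na(chi2))
  attr(out, "phenotype_id") <- phenotype_id
  class(out) <- c("association_track", "data.frame")
  out
}

#' Q-Q plot coordinates for an association track
#'
#' Sorted observed -log10 p against the uniform expectation, for parity
#' with the usual Manhattan/Q-Q diagnostics of mixed-model scans.
#'
#' @param track an `association_track`.
#' @param use_gc use `p_gc` when present.
#' @return data.frame with `expected` and `observed` -log10 p columns.
#' @export
qq_points <- function(track, use_gc = FALSE) {
  p <- if (use_gc && !is.null(track$p_gc)) track$p_gc else track$p_raw
  p <- sort(p[track$tested & !is.na(p)])
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(p))
}

#' Write / read a kinship matrix as square TSV
#'
#' @param K kinship matrix.
#' @param path TSV path (sample ids as header row and first column).
#' @return `path` / the matrix.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(sample = rownames(K), unclass(K), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  K <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(K) <- tab[[1L]]
  class(K) <- c("kinship_matrix", class(K))
  K
}
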