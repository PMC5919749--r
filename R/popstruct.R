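#' Principal-component analysis of a genotype matrix
#'
#' Eigendecomposition of the sample covariance of the centered,
#' per-variant standardized dosage matrix, the usual population-genetics
#' PCA. Missing dosages are mean-imputed per variant (PCA only; scans keep
#' their own missing-data rules); zero-variance (monomorphic) variants are
#' skipped. Eigenvalues come back in descending order and
#' `var_explained[i] = eigenvalue[i] / trace`.
#'
#' @param g a [genotype_matrix()].
#' @param k number of components to report; at most `min(n_samples - 1,
#'   n_variants)`.
#' @param standardize scale each variant by its dosage standard deviation
#'   (default); `FALSE` centers only.
#' @return list of class `eigen_result`: `eigenvalues`, `eigenvectors`
#'   (samples x k score matrix, unit-norm columns), `var_explained`,
#'   `n_components`.
#' @export
compute_pca <- function(g, k = 2L, standardize = TRUE) {
  X <- standardize_dosages(g$dosages, scale = standardize)
  if (ncol(X) == 0L) stop("no polymorphic variants for PCA")
  n <- nrow(X)
  if (k > min(n - 1L, ncol(X))) stop("k exceeds the available rank")
  C <- tcrossprod(X) / ncol(X)        # sample x sample covariance
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  ev <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(ev) <- g$samples
  colnames(ev) <- paste0("EV", seq_len(k))
  structure(list(eigenvalues = lam[seq_len(k)],
                 eigenvectors = ev,
                 var_explained = lam[seq_len(k)] / sum(lam),
                 n_components = k),
            class = "eigen_result")
}

# center columns, optionally scale by sd; NA -> column mean; drops
# zero-variance columns
standardize_dosages <- function(dos, scale = TRUE) {
  X <- dos
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na)) X[na] <- mu[na[, 2L]]
  X <- sweep(X, 2L, mu)
  sds <- apply(X, 2L, stats::sd)
  keep <- which(sds > 0)
  X <- X[, keep, drop = FALSE]
  if (scale) X <- sweep(X, 2L, sds[keep], "/")
  X
}

#' Pairwise genotype r-squared within chromosomes
#'
#' Squared Pearson correlation of dosage vectors for every intra-chromosome
#' SNP pair closer than `max_distance_bp`, computed over samples non-missing
#' at both sites. LD is population-specific: pass a single-population
#' matrix (see [split_by_population()]). Zero-variance pairs have undefined
#' correlation and are skipped (tallied in the `n_skipped` attribute).
#'
#' @param g a [genotype_matrix()] for one population.
#' @param max_distance_bp largest inter-SNP distance retained (default 1 Mb).
#' @return data.frame with columns chrom, pos_i, pos_j, distance, r2;
#'   attribute `n_skipped`.
#' @export
pairwise_r2 <- function(g, max_distance_bp = 1e6) {
  out <- list(); skipped <- 0L
  for (ch in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == ch)
    if (length(idx) < 2L) next
    pos <- g$variants$pos[idx]
    D <- g$dosages[, idx, drop = FALSE]
    storage.mode(D) <- "double"
    suppressWarnings(
      R <- stats::cor(D, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(R), arr.ind = TRUE)
    dist <- pos[pr[, 2L]] - pos[pr[, 1L]]
    keep <- dist <= max_distance_bp
    pr <- pr[keep, , drop = FALSE]; dist <- dist[keep]
    r <- R[pr]
    und <- is.na(r)
    skipped <- skipped + sum(und)
    out[[ch]] <- data.frame(chrom = ch,
                            pos_i = pos[pr[!und, 1L]],
                            pos_j = pos[pr[!und, 2L]],
                            distance = dist[!und],
                            r2 = r[!und]^2)
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(0), pos_i = integer(0),
                         pos_j = integer(0), distance = integer(0),
                         r2 = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}

#' LD-decay curve over distance bins
#'
#' Bins r-squared records by inter-SNP distance and, per bin, averages the
#' per-chromosome mean r-squared with chromosomes weighted equally (set
#' `weight_by_pairs = TRUE` for plain pair-weighted pooling). Empty bins
#' keep `n_pairs = 0` and `mean_r2 = NA`.
#'
#' @param records output of [pairwise_r2()] for one population.
#' @param bin_width_bp distance bin width (default 10 kb).
#' @param max_distance_bp upper end of the binned range (default 1 Mb).
#' @param weight_by_pairs pool pairs directly instead of averaging
#'   per-chromosome means.
#' @return data.frame of class `ld_decay_curve`: bin_start, bin_end,
#'   bin_mid, mean_r2, n_pairs.
#' @export
ld_decay_curve <- function(records, bin_width_bp = 1e4,
                           max_distance_bp = 1e6,
                           weight_by_pairs = FALSE) {
  if (nrow(records) == 0L) stop("no LD records to bin")
  edges <- seq(0, max_distance_bp, by = bin_width_bp)
  if (edges[length(edges)] < max_distance_bp)
    edges <- c(edges, max_distance_bp)
  nb <- length(edges) - 1L
  bin <- findInterval(records$distance, edges, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= nb
  bin <- bin[ok]
  r2 <- records$r2[ok]
  ch <- records$chrom[ok]
  n_pairs <- tabulate(bin, nbins = nb)
  if (weight_by_pairs) {
    sums <- tapply_num(r2, bin, nb, sum)
    mean_r2 <- ifelse(n_pairs > 0L, sums / n_pairs, NA_real_)
  } else {
    # unweighted mean of per-chromosome bin means
    key <- paste(ch, bin, sep = "\r")
    per <- tapply(r2, key, mean)
    bin_of <- as.integer(sub("^.*\r", "", names(per)))
    cnt <- tabulate(bin_of, nbins = nb)
    sums <- tapply_num(per, bin_of, nb, sum)
    mean_r2 <- ifelse(cnt > 0L, sums / cnt, NA_real_)
  }
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_end = edges[-1L],
                    bin_mid = (edges[-length(edges)] + edges[-1L]) / 2,
                    mean_r2 = mean_r2, n_pairs = n_pairs)
  class(out) <- c("ld_decay_curve", "data.frame")
  out
}

tapply_num <- function(x, g, nb, f) {
  out <- numeric(nb)
  agg <- tapply(x, g, f)
  out[as.integer(names(agg))] <- agg
  out
}

#' Distance at which LD decays to a threshold
#'
#' Walks the decay curve outward and reports the distance at which mean
#' r-squared first crosses `threshold` from above, linearly interpolated
#' between the midpoints of the bracketing bins. Returns 0 when the curve
#' already starts below the threshold, and `NA` with attribute
#' `beyond_range = TRUE` when it never reaches it.
#'
#' @param curve an [ld_decay_curve()].
#' @param threshold r-squared level, in (0, 1); the conventional reporting
#'   level is 0.3.
#' @return distance in bp (possibly `NA`, see above).
#' @export
ld_extent <- function(curve, threshold = 0.3) {
  stopifnot(threshold > 0, threshold < 1)
  cv <- curve[curve$n_pairs > 0L & !is.na(curve$mean_r2), , drop = FALSE]
  if (nrow(cv) < 2L) stop("need at least two non-empty bins")
  if (cv$mean_r2[1L] < threshold) return(0)
  below <- which(cv$mean_r2 < threshold)
  if (length(below) == 0L)
    return(structure(NA_real_, beyond_range = TRUE))
  j <- below[1L]; i <- j - 1L
  x0 <- cv$bin_mid[i]; x1 <- cv$bin_mid[j]
  y0 <- cv$mean_r2[i]; y1 <- cv$mean_r2[j]
  x0 + (y0 - threshold) / (y0 - y1) * (x1 - x0)
}
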