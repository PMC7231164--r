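#' Per-locus allele counts and frequencies
#'
#' Counts the reference allele per locus within each group and pooled over
#' groups, excluding missing calls from the allele totals.
#'
#' @param G a [genotype_matrix()].
#' @return A data frame of class `locus_stats` with one row per locus:
#'   `x_<group>`, `n_<group>`, `p_<group>` for every group plus pooled
#'   columns `x_pooled`, `n_pooled`, `p_pooled`. `x` is the reference-allele
#'   count, `n` the called allele total (2 x non-missing individuals).
#' @export
allele_frequencies <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  groups <- levels(G$groups)
  out <- data.frame(locus = colnames(G$calls), row.names = NULL)
  for (g in groups) {
    sub <- G$calls[G$groups == g, , drop = FALSE]
    x <- colSums(sub, na.rm = TRUE)
    n <- 2 * colSums(!is.na(sub))
    out[[paste0("x_", g)]] <- unname(x)
    out[[paste0("n_", g)]] <- unname(n)
    out[[paste0("p_", g)]] <- unname(ifelse(n > 0, x / n, NA_real_))
  }
  out$x_pooled <- rowSums(as.matrix(out[paste0("x_", groups)]))
  out$n_pooled <- rowSums(as.matrix(out[paste0("n_", groups)]))
  out$p_pooled <- ifelse(out$n_pooled > 0, out$x_pooled / out$n_pooled, NA_real_)
  class(out) <- c("locus_stats", "data.frame")
  out
}

#' Multi-locus Weir-Cockerham F_ST between two groups
#'
#' Weir & Cockerham's (1984) theta for two populations, combined across loci
#' as the ratio of summed variance components (sum(a) / sum(a + b + c)).
#' Near-zero differentiation can give slightly negative estimates, as is
#' standard for this estimator.
#'
#' @param G a [genotype_matrix()].
#' @param group_pair character vector of two group labels.
#' @return The multi-locus estimate (scalar). Per-locus components are
#'   attached as attribute `"components"`. Returns `NA` with a warning when
#'   every locus is monomorphic across both groups.
#' @export
pairwise_fst <- function(G, group_pair) {
  stopifnot(inherits(G, "genotype_matrix"), length(group_pair) == 2)
  comp <- vapply(seq_len(ncol(G$calls)), function(j) {
    fst_components(G$calls[G$groups == group_pair[1], j],
                   G$calls[G$groups == group_pair[2], j])
  }, numeric(3))
  a <- comp[1, ]; b <- comp[2, ]; c_ <- comp[3, ]
  ok <- is.finite(a)
  if (!any(ok) || sum(a[ok] + b[ok] + c_[ok]) == 0) {
    warning("F_ST undefined: all loci monomorphic")
    return(NA_real_)
  }
  theta <- sum(a[ok]) / sum(a[ok] + b[ok] + c_[ok])
  attr(theta, "components") <- data.frame(
    locus = colnames(G$calls), a = a, b = b, c = c_)
  theta
}

# Weir & Cockerham (1984) per-locus variance components a, b, c for r = 2
# samples; returns NA components for loci unusable in either sample.
fst_components <- function(calls1, calls2) {
  n1 <- sum(!is.na(calls1)); n2 <- sum(!is.na(calls2))
  if (n1 < 1 || n2 < 1) return(c(NA_real_, NA_real_, NA_real_))
  p1 <- sum(calls1, na.rm = TRUE) / (2 * n1)
  p2 <- sum(calls2, na.rm = TRUE) / (2 * n2)
  h1 <- sum(calls1 == 1L, na.rm = TRUE) / n1
  h2 <- sum(calls2 == 1L, na.rm = TRUE) / n2
  if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) {
    return(c(0, 0, 0))  # monomorphic across both samples: no information
  }
  r <- 2
  nbar <- (n1 + n2) / 2
  if (nbar <= 1) return(c(NA_real_, NA_real_, NA_real_))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  c(a, b, c_)
}

#' Genotype PCA coordinates
#'
#' Principal components of the calls matrix with per-locus mean imputation
#' of missing genotypes, centering, and (by default) unit-variance scaling.
#' The sign of each axis is fixed so that its loading sum is non-negative,
#' making coordinates deterministic.
#'
#' @param G a [genotype_matrix()].
#' @param locus_subset locus ids or indices to use (default all).
#' @param scale logical; scale loci to unit variance (default `TRUE`).
#' @param n_axes number of leading axes to return (default 2).
#' @return A numeric matrix of individual coordinates (rows named by
#'   individual id, columns `PC1`, `PC2`, ...), with the proportion of
#'   variance per axis in attribute `"var_explained"` and the loadings in
#'   attribute `"loadings"`.
#' @export
pca_coordinates <- function(G, locus_subset = NULL, scale = TRUE, n_axes = 2) {
  stopifnot(inherits(G, "genotype_matrix"))
  sub <- if (is.null(locus_subset)) G else subset_genotypes(G, loci = locus_subset)
  m <- sub$calls
  if (nrow(m) < 2) stop("PCA needs at least two individuals")
  storage.mode(m) <- "double"
  # mean imputation (2p per locus)
  mu <- colMeans(m, na.rm = TRUE)
  for (j in which(colSums(is.na(m)) > 0)) {
    m[is.na(m[, j]), j] <- mu[j]
  }
  v <- apply(m, 2, stats::var)
  poly <- v > 0
  if (!any(poly)) stop("all loci monomorphic in the chosen subset")
  m <- m[, poly, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  k <- min(n_axes, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: non-negative loading sum per axis
  for (i in seq_len(k)) {
    s <- sum(load[, i])
    if (s < 0 || (s == 0 && load[which.max(abs(load[, i])), i] < 0)) {
      scores[, i] <- -scores[, i]
      load[, i] <- -load[, i]
    }
  }
  attr(scores, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  attr(scores, "loadings") <- load
  scores
}
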