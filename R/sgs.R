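#' Monte-Carlo null draws of the allele frequency difference
#'
#' Draws from the sampling null of the single-generation selection (SGS)
#' test. The null models two variance sources for the observed difference in
#' allele frequency between two samples drawn from one panmictic gene pool:
#' uncertainty about the common pool frequency, captured by a conjugate Beta
#' posterior on the pooled counts, and binomial sampling noise in each
#' sample. Each draw takes `p* ~ Beta(x_pool + a, n_pool - x_pool + b)`, then
#' `x1* ~ Bin(n1, p*)`, `x2* ~ Bin(n2, p*)` and returns
#' `|x1*/n1 - x2*/n2|`.
#'
#' @param x_pool pooled reference-allele count.
#' @param n_pool pooled called-allele total (must be > 0).
#' @param n1_alleles,n2_alleles called-allele totals of the two samples.
#' @param n_iter number of draws (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param prior Beta prior parameters `c(a, b)` (default flat, `c(1, 1)`).
#' @return Numeric vector of `n_iter` null differences.
#' @export
sgs_null_draws <- function(x_pool, n_pool, n1_alleles, n2_alleles,
                           n_iter = 10000, seed = NULL, prior = c(1, 1)) {
  stopifnot(n_pool > 0, x_pool >= 0, x_pool <= n_pool,
            n1_alleles >= 2, n2_alleles >= 2, n_iter >= 1,
            length(prior) == 2, all(prior > 0))
  if (!is.null(seed)) set.seed(seed)
  p_star <- stats::rbeta(n_iter, x_pool + prior[1], n_pool - x_pool + prior[2])
  x1 <- stats::rbinom(n_iter, n1_alleles, p_star)
  x2 <- stats::rbinom(n_iter, n2_alleles, p_star)
  abs(x1 / n1_alleles - x2 / n2_alleles)
}

#' Single-generation selection test for one locus
#'
#' Tests whether the observed allele frequency difference between two
#' same-generation samples exceeds what random sampling from a common gene
#' pool can explain. The P-value is the add-one Monte-Carlo estimator
#' `(1 + #\{dp* >= dp_obs\}) / (n_iter + 1)`, never exactly zero; ties count
#' as extreme.
#'
#' @param x1,n1 reference-allele count and called-allele total in sample 1.
#' @param x2,n2 likewise for sample 2.
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed optional integer seed.
#' @param prior Beta prior on the pool frequency (default `c(1, 1)`).
#' @return A one-row data frame: `p1`, `p2`, `delta_p`, `p_value`, `n_iter`,
#'   `monomorphic` (TRUE when the pooled locus is fixed, in which case
#'   `delta_p = 0` and `p_value = 1`).
#' @export
sgs_test_locus <- function(x1, n1, x2, n2, n_iter = 10000, seed = NULL,
                           prior = c(1, 1)) {
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2, n1 >= 2, n2 >= 2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  delta <- abs(p1 - p2)
  x_pool <- x1 + x2
  n_pool <- n1 + n2
  if (x_pool == 0 || x_pool == n_pool) {
    return(data.frame(p1 = p1, p2 = p2, delta_p = 0, p_value = 1,
                      n_iter = n_iter, monomorphic = TRUE))
  }
  draws <- sgs_null_draws(x_pool, n_pool, n1, n2, n_iter = n_iter,
                          seed = seed, prior = prior)
  p_value <- (1 + sum(draws >= delta - 1e-12)) / (n_iter + 1)
  data.frame(p1 = p1, p2 = p2, delta_p = delta, p_value = p_value,
             n_iter = n_iter, monomorphic = FALSE)
}

#' Equal-tailed Beta credibility interval for an allele frequency
#'
#' Posterior interval for the gene-pool frequency given `x` reference
#' alleles out of `n` called, under a `Beta(a, b)` prior. Used for the
#' baseline (pre-selection) sample against which post-selection frequencies
#' are classified. `level = 0` degenerates to the posterior median.
#'
#' @param x reference-allele count.
#' @param n called-allele total (>= 1).
#' @param level interval mass (default 0.90).
#' @param prior Beta prior parameters (default `c(1, 1)`).
#' @return Numeric `c(lo, hi)`.
#' @export
baseline_credibility_interval <- function(x, n, level = 0.90,
                                          prior = c(1, 1)) {
  stopifnot(x >= 0, x <= n, n >= 1, level >= 0, level <= 1)
  alpha <- (1 - level) / 2
  q <- stats::qbeta(c(alpha, 1 - alpha), x + prior[1], n - x + prior[2])
  stats::setNames(q, c("lo", "hi"))
}

# deterministic per-locus substream so scan results do not depend on locus
# order or parallel chunking; 2^31-safe
locus_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(index)) %% 2147483629)
}

#' Genome-wide single-generation selection scan
#'
#' Applies [sgs_test_locus()] to every locus, comparing two post-selection
#' groups, and summarizes the baseline (pre-selection) group with an
#' equal-tailed credibility interval per locus. Each locus uses its own RNG
#' substream derived from `seed` and the locus index, so results are
#' independent of scan order.
#'
#' @param G a [genotype_matrix()].
#' @param group_a,group_b the two group labels to compare.
#' @param baseline baseline group label (`NULL` to skip baseline columns).
#' @param n_iter Monte-Carlo iterations per locus (default 10000).
#' @param seed master integer seed (default 1).
#' @param level credibility-interval mass for the baseline (default 0.90).
#' @param prior Beta prior for both the null and the interval.
#' @return A data frame of class `sgs_scan` with one row per locus:
#'   `locus`, `p_base`, `ci_lo`, `ci_hi`, `p_a`, `p_b`, `delta_p`,
#'   `p_value`, `monomorphic`. Group labels are kept in attributes.
#' @export
sgs_scan <- function(G, group_a, group_b, baseline = NULL, n_iter = 10000,
                     seed = 1, level = 0.90, prior = c(1, 1)) {
  stopifnot(inherits(G, "genotype_matrix"))
  st <- allele_frequencies(G)
  for (g in c(group_a, group_b, baseline)) {
    if (!paste0("x_", g) %in% names(st)) stop("unknown group '", g, "'")
    if (sum(G$groups == g) < 2) stop("group '", g, "' has fewer than 2 individuals")
  }
  xa <- st[[paste0("x_", group_a)]]; na <- st[[paste0("n_", group_a)]]
  xb <- st[[paste0("x_", group_b)]]; nb <- st[[paste0("n_", group_b)]]
  res <- lapply(seq_len(nrow(st)), function(i) {
    sgs_test_locus(xa[i], na[i], xb[i], nb[i], n_iter = n_iter,
                   seed = locus_seed(seed, i), prior = prior)
  })
  res <- do.call(rbind, res)
  out <- data.frame(locus = st$locus, stringsAsFactors = FALSE)
  if (!is.null(baseline)) {
    xb0 <- st[[paste0("x_", baseline)]]
    nb0 <- st[[paste0("n_", baseline)]]
    ci <- t(mapply(baseline_credibility_interval, xb0, pmax(nb0, 1),
                   MoreArgs = list(level = level, prior = prior)))
    out$p_base <- ifelse(nb0 > 0, xb0 / nb0, NA_real_)
    out$ci_lo <- ci[, "lo"]
    out$ci_hi <- ci[, "hi"]
  }
  out$p_a <- res$p1
  out$p_b <- res$p2
  out$delta_p <- res$delta_p
  out$p_value <- res$p_value
  out$monomorphic <- res$monomorphic
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "baseline") <- baseline
  attr(out, "n_iter") <- n_iter
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  class(out) <- c("sgs_scan", "data.frame")
  out
}

#' Outlier loci of a scan at a nominal threshold
#'
#' @param scan an `sgs_scan`.
#' @param threshold nominal P-value threshold (or vector of thresholds).
#' @return For one threshold, the character vector of outlier locus ids; for
#'   several, a named list of such vectors.
#' @export
outlier_loci <- function(scan, threshold) {
  stopifnot(inherits(scan, "sgs_scan"))
  pick <- function(t) scan$locus[scan$p_value < t]
  if (length(threshold) == 1) return(pick(threshold))
  stats::setNames(lapply(threshold, pick), as.character(threshold))
}

#' Classify scan outliers against the baseline sample
#'
#' For each locus, flags whether the baseline frequency is intermediate to
#' the two post-selection frequencies, whether either post-selection
#' frequency lies outside the baseline credibility interval, and the
#' direction of major-allele change in each group (major allele defined in
#' the baseline sample).
#'
#' @param scan an `sgs_scan` computed with a baseline group.
#' @return A data frame: `locus`, `intermediate`, `outside_ci`, `dir_a`,
#'   `dir_b` (each direction in -1/0/1 on the baseline major-allele scale).
#' @export
classify_outliers_vs_baseline <- function(scan) {
  stopifnot(inherits(scan, "sgs_scan"))
  if (is.null(scan$p_base)) stop("scan was run without a baseline group")
  major_ref <- scan$p_base >= 0.5
  to_major <- function(p) ifelse(major_ref, p, 1 - p)
  pa <- to_major(scan$p_a)
  pb <- to_major(scan$p_b)
  p0 <- to_major(scan$p_base)
  data.frame(
    locus = scan$locus,
    intermediate = pmin(pa, pb) <= p0 & p0 <= pmax(pa, pb),
    outside_ci = scan$p_a < scan$ci_lo | scan$p_a > scan$ci_hi |
      scan$p_b < scan$ci_lo | scan$p_b > scan$ci_hi,
    dir_a = sign(pa - p0),
    dir_b = sign(pb - p0)
  )
}

#' Write scan results to TSV
#'
#' @param scan an `sgs_scan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
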