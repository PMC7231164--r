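#' Exact test of Hardy-Weinberg equilibrium
#'
#' Full-enumeration exact test conditioned on the observed allele counts:
#' every heterozygote count compatible with the allele counts is enumerated,
#' its conditional probability computed, and the two-sided P-value obtained
#' by summing the probabilities of all configurations no more probable than
#' the observed one.
#'
#' @param n_ref_hom,n_het,n_alt_hom genotype counts at one locus.
#' @return Two-sided exact P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom) {
  stopifnot(n_ref_hom >= 0, n_het >= 0, n_alt_hom >= 0)
  n <- n_ref_hom + n_het + n_alt_hom
  if (n == 0) return(1)
  n_ref <- 2L * n_ref_hom + n_het     # reference allele count
  n_alt <- 2L * n_alt_hom + n_het
  rare <- min(n_ref, n_alt)
  if (rare == 0) return(1)            # monomorphic: single configuration
  # possible het counts share the parity of the rare allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  hom_rare <- (rare - hets) / 2
  hom_common <- (n - hets - hom_rare)
  # log P(het = h | allele counts) up to a shared constant
  logp <- lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(hets + 1) -
    lgamma(hom_common + 1) + hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  if (is.na(obs)) stop("observed heterozygote count incompatible with allele counts")
  # tolerance guards ties against floating-point noise
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

locus_genotype_counts <- function(calls) {
  c(n_ref_hom = sum(calls == 2L, na.rm = TRUE),
    n_het = sum(calls == 1L, na.rm = TRUE),
    n_alt_hom = sum(calls == 0L, na.rm = TRUE))
}

#' Filter loci on missingness, minor allele frequency and HWE
#'
#' A locus is retained when (i) its fraction of missing calls is at most
#' `max_missing_frac` within every group, (ii) its pooled minor allele
#' frequency is at least `maf_min`, and (iii) the exact Hardy-Weinberg test
#' P-value is at least `hwe_alpha` within every group. Defaults follow the
#' usual RAD-seq post-export practice (10% missingness per sample, 1% MAF,
#' HWE P \eqn{\ge 10^{-3}}).
#'
#' @param G a [genotype_matrix()].
#' @param max_missing_frac maximum within-group missing fraction.
#' @param maf_min minimum pooled minor allele frequency.
#' @param hwe_alpha minimum within-group exact HWE P-value.
#' @return A list with elements `genotypes` (the filtered matrix) and
#'   `report` (a `filter_report`, see [print.filter_report()]).
#' @export
filter_loci <- function(G, max_missing_frac = 0.10, maf_min = 0.01,
                        hwe_alpha = 1e-3) {
  stopifnot(inherits(G, "genotype_matrix"),
            max_missing_frac >= 0, max_missing_frac <= 1,
            maf_min >= 0, maf_min <= 1, hwe_alpha >= 0, hwe_alpha <= 1)
  groups <- levels(G$groups)
  if (any(table(G$groups) == 0)) stop("every group needs at least one individual")
  loci <- colnames(G$calls)

  miss_by_group <- sapply(groups, function(g) {
    colMeans(is.na(G$calls[G$groups == g, , drop = FALSE]))
  })
  fail_miss <- apply(miss_by_group > max_missing_frac, 1, any)

  x <- colSums(G$calls, na.rm = TRUE)
  n <- 2 * colSums(!is.na(G$calls))
  p <- ifelse(n > 0, x / n, NA_real_)
  maf <- pmin(p, 1 - p)
  fail_maf <- is.na(maf) | maf < maf_min

  hwe_p <- sapply(groups, function(g) {
    sub <- G$calls[G$groups == g, , drop = FALSE]
    apply(sub, 2, function(calls) {
      cnt <- locus_genotype_counts(calls)
      hwe_exact_test(cnt[1], cnt[2], cnt[3])
    })
  })
  if (is.null(dim(hwe_p))) hwe_p <- matrix(hwe_p, nrow = 1, dimnames = list(loci, groups))
  fail_hwe <- apply(hwe_p < hwe_alpha, 1, any)

  keep <- !(fail_miss | fail_maf | fail_hwe)
  report <- structure(
    list(
      stats = data.frame(
        locus = loci,
        max_group_missing = apply(miss_by_group, 1, max),
        maf = maf,
        min_group_hwe_p = apply(hwe_p, 1, min),
        removed_missing = fail_miss,
        removed_maf = fail_maf,
        removed_hwe = fail_hwe,
        retained = keep,
        row.names = NULL
      ),
      thresholds = c(max_missing_frac = max_missing_frac,
                     maf_min = maf_min, hwe_alpha = hwe_alpha),
      n_tested = length(loci),
      n_removed = sum(!keep)
    ),
    class = "filter_report"
  )
  list(genotypes = subset_genotypes(G, loci = which(keep)), report = report)
}

#' Allele read-depth balance filter
#'
#' Detects systematic read-count bias toward one allele. Per locus, the
#' allele with the lowest total read count across individuals is identified;
#' for each heterozygote the ratio of that allele's depth to the total depth
#' is computed and the mean ratio tested against the expected value 0.5 with
#' a one-sided one-sample t-test. Loci with P below `alpha` are removed.
#' Loci with fewer than two usable heterozygotes pass with a warning flag.
#'
#' @param G a [genotype_matrix()] with allele depths attached.
#' @param alpha rejection threshold for the one-sided t-test.
#' @return A list with elements `genotypes` and `report` (per-locus t
#'   statistic, P-value, heterozygote count and decision).
#' @export
allele_balance_filter <- function(G, alpha = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (is.null(G$ref_depth) || is.null(G$alt_depth)) {
    stop("allele depths are required for the balance filter")
  }
  loci <- colnames(G$calls)
  res <- lapply(seq_along(loci), function(j) {
    het <- which(G$calls[, j] == 1L)
    rd <- G$ref_depth[het, j]
    ad <- G$alt_depth[het, j]
    ok <- !is.na(rd) & !is.na(ad) & (rd + ad) > 0
    rd <- rd[ok]; ad <- ad[ok]
    # allele with the lowest overall read count across individuals
    low_is_ref <- sum(rd) <= sum(ad)
    ratio <- if (low_is_ref) rd / (rd + ad) else ad / (rd + ad)
    if (length(ratio) < 2) {
      # untestable: fewer than two usable heterozygotes -> pass
      return(data.frame(locus = loci[j], n_het = length(ratio),
                        mean_ratio = if (length(ratio)) mean(ratio) else NA_real_,
                        t_stat = NA_real_, p_value = NA_real_,
                        untestable = TRUE, removed = FALSE))
    }
    if (stats::sd(ratio) == 0) {
      # degenerate t: constant ratios give t = 0 (mean at 0.5, retained)
      # or t = -Inf (mean below 0.5, removed)
      below <- mean(ratio) < 0.5
      return(data.frame(locus = loci[j], n_het = length(ratio),
                        mean_ratio = mean(ratio),
                        t_stat = if (below) -Inf else 0,
                        p_value = if (below) 0 else 1,
                        untestable = FALSE, removed = below))
    }
    tt <- stats::t.test(ratio, mu = 0.5, alternative = "less")
    data.frame(locus = loci[j], n_het = length(ratio),
               mean_ratio = mean(ratio),
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               untestable = FALSE, removed = tt$p.value < alpha)
  })
  stats_df <- do.call(rbind, res)
  if (any(stats_df$untestable)) {
    warning(sum(stats_df$untestable),
            " locus/loci had <2 usable heterozygotes; passed untested")
  }
  report <- structure(
    list(stats = stats_df, thresholds = c(alpha = alpha),
         n_tested = length(loci), n_removed = sum(stats_df$removed)),
    class = "filter_report"
  )
  list(genotypes = subset_genotypes(G, loci = which(!stats_df$removed)),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_tested, "loci tested,", x$n_removed, "removed,",
      x$n_tested - x$n_removed, "retained\n")
  cat("thresholds:", paste(names(x$thresholds), signif(x$thresholds, 3),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a filter report to TSV
#'
#' @param report a `filter_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report$stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
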