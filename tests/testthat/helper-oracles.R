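# Independent oracles used to pin down expected values. Each one recomputes
# the target quantity by direct enumeration or a textbook formula, on a path
# separate from the package implementation.

# Exact joint distribution of (x1*, x2*) under the beta-binomial
# posterior-predictive null: p* ~ Beta(x_pool + a, n_pool - x_pool + b),
# x1* ~ Bin(n1, p*), x2* ~ Bin(n2, p*). Marginalizing p* analytically gives
# P(i, j) = C(n1,i) C(n2,j) B(a + x + i + j, b + n - x + n1 + n2 - i - j)
#           / B(a + x, b + n - x).
oracle_sgs_joint <- function(x_pool, n_pool, n1, n2, prior = c(1, 1)) {
  s <- 0:(n1 + n2)
  lw <- lbeta(prior[1] + x_pool + s,
              prior[2] + n_pool - x_pool + n1 + n2 - s) -
    lbeta(prior[1] + x_pool, prior[2] + n_pool - x_pool)
  lp <- outer(lchoose(n1, 0:n1), lchoose(n2, 0:n2), "+") +
    matrix(lw[outer(0:n1, 0:n2, "+") + 1], n1 + 1)
  list(P = exp(lp), d = abs(outer(0:n1 / n1, 0:n2 / n2, "-")))
}

# Exact tail P(delta_p* >= d_obs) and the atom P(delta_p* == d_obs)
oracle_sgs_tail <- function(x1, n1, x2, n2, prior = c(1, 1)) {
  jt <- oracle_sgs_joint(x1 + x2, n1 + n2, n1, n2, prior)
  d_obs <- abs(x1 / n1 - x2 / n2)
  list(tail = sum(jt$P[jt$d >= d_obs - 1e-12]),
       atom = sum(jt$P[abs(jt$d - d_obs) < 1e-12]))
}

# HWE exact test by direct enumeration of genotype configurations given the
# allele counts: P(n_het) = n! / (nAA! nAB! naa!) * 2^nAB * nA! na! / (2n)!
oracle_hwe_p <- function(n_ref_hom, n_het, n_alt_hom) {
  n <- n_ref_hom + n_het + n_alt_hom
  n_ref <- 2 * n_ref_hom + n_het
  n_alt <- 2 * n_alt_hom + n_het
  hets <- seq(n_ref %% 2, min(n_ref, n_alt), by = 2)
  prob1 <- function(h) {
    aa <- (n_ref - h) / 2
    bb <- (n_alt - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(n_ref) + lfactorial(n_alt) -
          lfactorial(2 * n))
  }
  p <- vapply(hets, prob1, numeric(1))
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Two-sided Fisher exact P by hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher_p <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  support <- max(0, k - n2):min(n1, k)
  p <- dhyper(support, n1, n2, k)
  obs <- dhyper(x1, n1, n2, k)
  sum(p[p <= obs * (1 + 1e-7)])
}

# Weir-Cockerham theta via the ANOVA sums-of-squares route (Weir 1996),
# a computational path distinct from the direct a/b/c formulas: alleles are
# decomposed into between-population, between-individual-within-population
# and within-individual mean squares.
oracle_wc_theta <- function(calls_by_group) {
  comp <- sapply(calls_by_group_loci(calls_by_group), function(locus) {
    groups <- locus
    n_i <- vapply(groups, length, numeric(1))
    r <- length(groups)
    n_tot <- sum(n_i)
    p_i <- vapply(groups, function(g) mean(g) / 2, numeric(1))
    pbar <- sum(n_i * p_i) / n_tot
    all_calls <- unlist(groups)
    ss_g <- sum(all_calls == 1) / 2                     # within individuals
    ss_i <- 2 * sum(unlist(mapply(function(g, p) (g / 2 - p)^2, groups,
                                  p_i, SIMPLIFY = FALSE)))
    ss_p <- 2 * sum(n_i * (p_i - pbar)^2)
    msg <- ss_g / n_tot
    msi <- ss_i / (n_tot - r)
    msp <- ss_p / (r - 1)
    nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
    sig_p <- (msp - msi) / (2 * nc)
    sig_i <- (msi - msg) / 2
    c(a = sig_p, bc = sig_i + msg)
  })
  sum(comp["a", ]) / sum(comp["a", ] + comp["bc", ])
}

# reshape list(group -> matrix ind x loci) into per-locus list of per-group
# call vectors
calls_by_group_loci <- function(calls_by_group) {
  n_loci <- ncol(calls_by_group[[1]])
  lapply(seq_len(n_loci), function(j) {
    lapply(calls_by_group, function(m) m[, j])
  })
}

# deterministic post-selection allele frequency for the fitness scheme
# wAA = 1+s, wAa = 1, waa = 1-s
oracle_p_prime <- function(p, s) {
  q <- 1 - p
  wbar <- p^2 * (1 + s) + 2 * p * q + q^2 * (1 - s)
  (p^2 * (1 + s) + p * q) / wbar
}

# bilinear interpolation at one point from a lattice (x, y, z)
oracle_bilinear <- function(grid, xp, yp) {
  i <- findInterval(xp, grid$x, rightmost.closed = TRUE)
  j <- findInterval(yp, grid$y, rightmost.closed = TRUE)
  x0 <- grid$x[i]; x1 <- grid$x[i + 1]
  y0 <- grid$y[j]; y1 <- grid$y[j + 1]
  tx <- (xp - x0) / (x1 - x0)
  ty <- (yp - y0) / (y1 - y0)
  (1 - tx) * (1 - ty) * grid$z[i, j] + tx * (1 - ty) * grid$z[i + 1, j] +
    (1 - tx) * ty * grid$z[i, j + 1] + tx * ty * grid$z[i + 1, j + 1]
}
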