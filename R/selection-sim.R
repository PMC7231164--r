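#' Configuration for one-generation viability-selection simulations
#'
#' Fitness follows the symmetric single-locus viability scheme
#' \eqn{\omega_{AA} = 1 + s}, \eqn{\omega_{Aa} = 1},
#' \eqn{\omega_{aa} = 1 - s}, where A is the reference allele. Selection
#' operates only on the second sample; the first is drawn neutrally.
#'
#' @param N population size in diploid individuals (default 10000).
#' @param n1,n2 sample sizes in diploid individuals (default 100 each).
#' @param p initial reference-allele frequency.
#' @param s selection coefficient, |s| < 1.
#' @param reps replicates per parameter combination (default 100).
#' @param alpha test level used for power estimates (default 0.05).
#' @param seed master integer seed.
#' @param survivor_scheme `"bernoulli"`: each individual survives
#'   independently with probability \eqn{\omega_g / \max \omega} and `n2`
#'   individuals are then drawn from the survivors; `"weighted"`: `n2`
#'   survivors are drawn directly without replacement with
#'   fitness-proportional weights.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N = 10000, n1 = 100, n2 = 100, p = 0.5, s = 0,
                       reps = 100, alpha = 0.05, seed = 1,
                       survivor_scheme = c("bernoulli", "weighted")) {
  survivor_scheme <- match.arg(survivor_scheme)
  stopifnot(N >= 1, n1 >= 1, n2 >= 1, N >= max(n1, n2),
            p >= 0, p <= 1, abs(s) < 1, reps >= 1,
            alpha > 0, alpha < 1)
  structure(list(N = N, n1 = n1, n2 = n2, p = p, s = s, reps = reps,
                 alpha = alpha, seed = seed,
                 survivor_scheme = survivor_scheme),
            class = "sim_config")
}

# multivariate hypergeometric draw of k individuals from class counts
rmvhyper <- function(counts, k) {
  out <- integer(length(counts))
  remaining <- sum(counts)
  for (i in seq_along(counts)) {
    if (k <= 0) break
    if (i == length(counts)) {
      out[i] <- k
      break
    }
    out[i] <- stats::rhyper(1, counts[i], remaining - counts[i], k)
    remaining <- remaining - counts[i]
    k <- k - out[i]
  }
  out
}

#' Simulate one replicate of single-generation viability selection
#'
#' One generation in a finite panmictic population: the standing frequency
#' drifts via one binomial draw of `2N` alleles, genotypes form at HWE, a
#' first sample of `n1` individuals is taken without selection, and a second
#' sample of `n2` individuals is taken after viability selection (see
#' [sim_config()] for the two survivor schemes). Genotype classes are indexed
#' by reference-allele copies (2, 1, 0).
#'
#' @param cfg a [sim_config()].
#' @return A list: `x1`, `n1_alleles`, `x2`, `n2_alleles` (reference-allele
#'   counts and allele totals of the two samples), `p_pop` (post-drift
#'   population frequency), `geno1`, `geno2` (genotype counts per sample,
#'   ordered AA/Aa/aa), `redraws` (survivor redraw count, bernoulli scheme).
#' @export
simulate_replicate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  N <- cfg$N
  # drift layer: one binomial realization of the standing frequency
  p_pop <- stats::rbinom(1, 2 * N, cfg$p) / (2 * N)
  geno_prob <- c(p_pop^2, 2 * p_pop * (1 - p_pop), (1 - p_pop)^2)
  pop <- as.integer(stats::rmultinom(1, N, geno_prob))
  # sample 1: neutral, without replacement
  geno1 <- rmvhyper(pop, cfg$n1)
  w <- c(1 + cfg$s, 1, 1 - cfg$s)
  redraws <- 0L
  if (cfg$survivor_scheme == "bernoulli") {
    repeat {
      surv <- stats::rbinom(3, pop, w / max(w))
      if (sum(surv) >= cfg$n2) break
      redraws <- redraws + 1L
      if (redraws > 1000L) stop("selection too extreme: survivors < n2")
    }
    if (redraws > 0L) {
      message(redraws, " survivor redraw(s) at s = ", cfg$s)
    }
    geno2 <- rmvhyper(surv, cfg$n2)
  } else {
    classes <- rep.int(c(2L, 1L, 0L), pop)
    picked <- sample(classes, cfg$n2, replace = FALSE,
                     prob = rep.int(w, pop))
    geno2 <- c(sum(picked == 2L), sum(picked == 1L), sum(picked == 0L))
  }
  list(x1 = 2L * geno1[1] + geno1[2], n1_alleles = 2L * cfg$n1,
       x2 = 2L * geno2[1] + geno2[2], n2_alleles = 2L * cfg$n2,
       p_pop = p_pop, geno1 = geno1, geno2 = geno2, redraws = redraws)
}

#' Deterministic post-selection genotype probabilities
#'
#' Expected genotype frequencies after one round of viability selection on
#' HWE proportions at frequency `p` with the fitness scheme of
#' [sim_config()]. Used both as the infinite-population oracle for the
#' simulator's mean behavior and by the synthetic cohort generator.
#'
#' @param p reference-allele frequency before selection.
#' @param s selection coefficient.
#' @return Numeric genotype probabilities `c(AA, Aa, aa)` (reference copies
#'   2, 1, 0), with the post-selection allele frequency as attribute
#'   `"p_prime"`.
#' @export
viability_selection_probs <- function(p, s) {
  stopifnot(p >= 0, p <= 1, abs(s) < 1)
  w <- c(1 + s, 1, 1 - s)
  g <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * w
  g <- g / sum(g)
  structure(g, p_prime = g[1] + g[2] / 2)
}

#' Two-sided Fisher's exact test on a 2x2 allele-count table
#'
#' The classical test for genetic differentiation the SGS test is benchmarked
#' against: Fisher's exact test on
#' `[[x1, n1 - x1], [x2, n2 - x2]]`.
#'
#' @param x1,n1 reference-allele count and allele total in sample 1.
#' @param x2,n2 likewise for sample 2.
#' @return Two-sided P-value; 1 when a table margin is empty.
#' @export
fisher_exact <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Power of the SGS test and Fisher's exact test over a (p, s) grid
#'
#' For every combination of initial frequency and selection coefficient,
#' simulates `cfg_base$reps` replicates of one-generation viability
#' selection and records the fraction of replicates each test rejects at
#' level `cfg_base$alpha`. The `s = 0` rows measure type-I error.
#'
#' @param p_values initial allele frequencies.
#' @param s_values selection coefficients.
#' @param cfg_base a [sim_config()] providing `N`, `n1`, `n2`, `reps`,
#'   `alpha`, `seed` and the survivor scheme.
#' @param n_iter_sgs Monte-Carlo iterations per SGS test (default 2000;
#'   ample resolution at the usual 5% level).
#' @return A data frame of class `power_grid`: `p`, `s`, `power_sgs`,
#'   `power_fisher`, `se_sgs`, `se_fisher`, `reps`.
#' @export
power_grid <- function(p_values, s_values, cfg_base = sim_config(),
                       n_iter_sgs = 2000) {
  stopifnot(length(p_values) >= 1, length(s_values) >= 1,
            inherits(cfg_base, "sim_config"))
  cells <- expand.grid(p = p_values, s = s_values)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- cfg_base
    cfg$p <- cells$p[i]
    cfg$s <- cells$s[i]
    set.seed(locus_seed(cfg_base$seed, i))
    rej_sgs <- rej_fis <- logical(cfg$reps)
    for (r in seq_len(cfg$reps)) {
      rep_ <- simulate_replicate(cfg)
      p_sgs <- sgs_test_locus(rep_$x1, rep_$n1_alleles, rep_$x2,
                              rep_$n2_alleles, n_iter = n_iter_sgs)$p_value
      p_fis <- fisher_exact(rep_$x1, rep_$n1_alleles, rep_$x2,
                            rep_$n2_alleles)
      rej_sgs[r] <- p_sgs < cfg$alpha
      rej_fis[r] <- p_fis < cfg$alpha
    }
    pw_s <- mean(rej_sgs)
    pw_f <- mean(rej_fis)
    data.frame(p = cfg$p, s = cfg$s, power_sgs = pw_s, power_fisher = pw_f,
               se_sgs = sqrt(pw_s * (1 - pw_s) / cfg$reps),
               se_fisher = sqrt(pw_f * (1 - pw_f) / cfg$reps),
               reps = cfg$reps)
  })
  out <- do.call(rbind, res)
  attr(out, "alpha") <- cfg_base$alpha
  attr(out, "n_iter_sgs") <- n_iter_sgs
  class(out) <- c("power_grid", "data.frame")
  out
}
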