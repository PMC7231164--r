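test_that("allele orientation follows the between-group contrast", {
  calls <- cbind(
    L1 = c(2L, 2L, 1L, 0L, 0L, 0L),  # ref common in group a
    L2 = c(0L, 0L, 1L, 2L, 2L, 2L),  # alt common in group a
    L3 = c(1L, 1L, 1L, 1L, 1L, 1L)   # tie
  )
  rownames(calls) <- paste0("i", 1:6)
  G <- make_G(calls, groups = rep(c("a", "b"), each = 3))
  st <- allele_frequencies(G)
  ori <- orient_alleles(st, "a", "b")
  expect_equal(ori$a_allele, c("ref", "alt", "ref"))
  expect_equal(ori$tie, c(FALSE, FALSE, TRUE))
  # antisymmetry: swapping the groups swaps favored labels at non-ties
  ori_sw <- orient_alleles(st, "b", "a")
  nt <- !ori$tie
  expect_true(all(ori_sw$a_allele[nt] != ori$a_allele[nt]))
})

test_that("polygenic scores satisfy the complementarity identity", {
  co <- generate_cohort(n_baseline = 10, n_juv_a = 20, n_juv_b = 20,
                        n_loci = 67, n_selected = 10, seed = 23)
  G <- co$genotypes
  st <- allele_frequencies(G)
  ori <- orient_alleles(st, "brackish", "marine")
  sc <- polygenic_scores(G, ori)
  # complete data: score_a + score_b = 2 x loci, exactly, for everyone
  expect_true(all(sc$score_a + sc$score_b == 2L * 67L))
  # per-cell counting oracle
  a_ref <- ori$a_allele == "ref"
  manual_a <- apply(G$calls, 1, function(g)
    sum(ifelse(a_ref, g, 2 - g), na.rm = TRUE))
  expect_equal(sc$score_a, unname(manual_a))
  # with missing data the identity bends by 2 per missing call
  G2 <- G
  G2$calls[1, 1:5] <- NA
  sc2 <- polygenic_scores(G2, ori)
  expect_equal(sc2$score_a + sc2$score_b, 2L * (67L - sc2$n_missing))
  expect_equal(sc2$n_missing[1], 5L)
  # an individual homozygous for every A-favored allele
  G3 <- G
  G3$calls[1, ] <- ifelse(a_ref, 2L, 0L)
  sc3 <- polygenic_scores(G3, ori)
  expect_equal(sc3$score_a[1], 134L)
  expect_equal(sc3$score_b[1], 0L)
  expect_error(polygenic_scores(G, ori, locus_set = character(0)), "empty")
})

test_that("threshold sweep equals direct computation at a single threshold", {
  co <- generate_cohort(n_loci = 200, n_selected = 15, s_range = c(0.4, 0.5),
                        seed = 29)
  G <- co$genotypes
  scan <- sgs_scan(G, "brackish", "marine", n_iter = 500, seed = 4)
  ph <- co$phenotypes
  k <- condition_factor(ph$length_mm, ph$weight_g)
  trait <- setNames(as.numeric(k), ph$id)
  habitat <- setNames(ph$habitat, ph$id)
  sw <- threshold_sweep(scan, G, trait, habitat,
                        thresholds = c(0.001, 0.01, 0.1), score = "A")
  # rows ordered largest -> smallest threshold; counts non-increasing
  expect_true(all(diff(sw$n_loci) <= 0))
  # direct recomputation at t = 0.01
  loci <- scan$locus[scan$p_value < 0.01]
  st <- allele_frequencies(G)
  ori <- orient_alleles(st, "brackish", "marine", loci = loci)
  sc <- polygenic_scores(G, ori)
  v <- setNames(sc$score_a, sc$id)
  ids <- intersect(names(trait), rownames(G$calls))
  fit <- ancova_interaction(trait[ids], v[ids], habitat[ids])
  row <- sw[sw$threshold == 0.01, ]
  expect_equal(row$n_loci, length(loci))
  expect_equal(row$r_squared, fit$r_squared, tolerance = 1e-12)
  expect_equal(row$interaction_p, fit$interaction_p, tolerance = 1e-12)
  # empty threshold cell flagged, not an error
  sw2 <- threshold_sweep(scan, G, trait, habitat,
                         thresholds = c(1e-9, 0.05), score = "A")
  expect_true(sw2$empty[sw2$threshold == 1e-9])
})

test_that("GWA recovers a planted additive effect and applies tag Bonferroni", {
  set.seed(37)
  n <- 200
  calls <- sapply(runif(30, 0.2, 0.8), function(p) rbinom(n, 2, p))
  rownames(calls) <- paste0("i", 1:n)
  tags <- rep(paste0("tag", 1:10), each = 3)
  G <- make_G(calls, groups = rep(c("a", "b"), each = n / 2), tags = tags)
  y <- 0.5 * scale(calls[, 7])[, 1] + rnorm(n)
  names(y) <- rownames(calls)
  res <- gwa_linear(G, y, model = "simple")
  expect_equal(attr(res, "n_effective"), 10L)
  expect_equal(attr(res, "threshold"), 0.05 / 10)
  expect_lt(res$p_value[7], attr(res, "threshold"))
  # calibration of the others: no wild anti-conservatism
  expect_lt(mean(res$p_value[-7] < 0.05, na.rm = TRUE), 0.25)
  # interaction model reports the interaction-term P of the per-SNP lm
  E <- setNames(rep(c("a", "b"), each = n / 2), rownames(calls))
  y2 <- 1.5 * calls[, 3] * (E == "b") + rnorm(n)
  names(y2) <- rownames(calls)
  res3 <- gwa_linear(G, y2, E = E, model = "interaction")
  direct <- summary(lm(y2 ~ calls[, 3] * factor(E)))$coefficients[4, 4]
  expect_equal(res3$p_value[3], direct, tolerance = 1e-12)
  expect_lt(res3$p_value[3], 0.05 / 10)
  # monomorphic locus skipped
  G$calls[, 1] <- 2L
  res4 <- gwa_linear(G, y, model = "simple")
  expect_true(res4$skipped[1])
})

test_that("independent association guards and detects", {
  set.seed(43)
  n <- 30
  s <- rnorm(n)
  tr <- 0.45 * s + sqrt(1 - 0.45^2) * rnorm(n)
  names(s) <- names(tr) <- paste0("larv", 1:n)
  fit <- independent_association(s, tr)
  expect_equal(fit$n, 30)
  expect_gt(fit$slope, 0)
  # overlap with the discovery sample is an error
  expect_error(independent_association(s, tr, discovery_ids = "larv5"),
               "overlap")
  # constant score errors
  expect_error(independent_association(setNames(rep(2, n), names(s)), tr),
               "constant")
  # planted r = 0.45 at n = 30 detected in most replicates
  hits <- replicate(60, {
    s <- rnorm(n); tr <- 0.45 * s + sqrt(1 - 0.45^2) * rnorm(n)
    names(s) <- names(tr) <- paste0("x", 1:n)
    independent_association(s, tr)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.5)
})
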