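test_that("KDE lattice integrates to 1 and peaks at the data mode", {
  set.seed(3)
  pts <- cbind(rnorm(500, 2, 0.3), rnorm(500, -1, 0.3))
  d <- kde2d_grid(pts, grid_n = 80)
  expect_equal(lattice_integral(d), 1, tolerance = 0.01)
  idx <- which(d$z == max(d$z), arr.ind = TRUE)
  expect_lt(abs(d$x[idx[1]] - 2), 0.2)
  expect_lt(abs(d$y[idx[2]] + 1), 0.2)
  # large-n standard normal: density at the mode near 1/(2*pi)
  set.seed(4)
  big <- matrix(rnorm(16000), ncol = 2)
  db <- kde2d_grid(big, grid_n = 80)
  i0 <- which.min(abs(db$x)); j0 <- which.min(abs(db$y))
  expect_equal(db$z[i0, j0], 1 / (2 * pi), tolerance = 0.1)
  # degenerate axis errors
  expect_error(kde2d_grid(cbind(rep(1, 10), rnorm(10))), "bandwidth")
})

test_that("survival surface is the density difference on a shared lattice", {
  set.seed(5)
  pre <- matrix(rnorm(400), ncol = 2)
  # identical groups: z identically zero
  s0 <- survival_surface(pre, pre)
  expect_equal(max(abs(s0$z)), 0)
  # post-selection group shifted along PC1
  post <- sweep(pre, 2, c(1.2, 0), "+")
  s1 <- survival_surface(post, pre)
  mid_x <- mean(range(s1$x))
  left <- s1$x < mid_x - 0.5
  right <- s1$x > mid_x + 0.5
  expect_lt(sum(s1$z[left, ]), 0)
  expect_gt(sum(s1$z[right, ]), 0)
  # both densities conserve mass; their difference integrates to ~0
  expect_equal(lattice_integral(s1$dens_post), 1, tolerance = 0.01)
  expect_equal(lattice_integral(s1$dens_pre), 1, tolerance = 0.01)
  expect_lt(abs(lattice_integral(s1)), 0.02)
})

test_that("projection interpolates bilinearly and flags clipping", {
  set.seed(6)
  pre <- matrix(rnorm(300), ncol = 2)
  post <- sweep(pre, 2, c(0.8, -0.3), "+")
  s <- survival_surface(post, pre, grid_n = 60)
  # lattice nodes reproduce node values exactly
  nodes <- cbind(s$x[c(5, 30)], s$y[c(7, 41)])
  sc <- project_survival_scores(nodes, s)
  expect_equal(unname(sc), c(s$z[5, 7], s$z[30, 41]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # interior points match the hand bilinear formula
  qry <- cbind(runif(25, min(s$x), max(s$x)), runif(25, min(s$y), max(s$y)))
  sc2 <- project_survival_scores(qry, s)
  manual <- vapply(seq_len(25), function(i)
    oracle_bilinear(s, qry[i, 1], qry[i, 2]), numeric(1))
  expect_equal(unname(sc2), manual, tolerance = 1e-6, ignore_attr = TRUE)
  # out-of-hull points are clipped and flagged
  far <- rbind(c(min(s$x) - 5, 0), c(0, 0))
  sc3 <- project_survival_scores(far, s)
  expect_equal(attr(sc3, "clipped"), c(TRUE, FALSE))
  expect_false(any(is.na(sc3)))
  # a zero surface projects everyone to zero
  s0 <- s
  s0$z[] <- 0
  sc4 <- project_survival_scores(qry, s0)
  expect_true(all(sc4 == 0))
  expect_equal(attr(sc4, "positive_fraction"), 0)
})

test_that("surface and scores are invariant to axis sign flips", {
  set.seed(7)
  pre <- matrix(rnorm(200), ncol = 2)
  post <- sweep(pre, 2, c(0.7, 0.2), "+")
  s <- survival_surface(post, pre, grid_n = 50)
  sc <- project_survival_scores(pre, s)
  flip <- function(m) cbind(-m[, 1], m[, 2])
  s_f <- survival_surface(flip(post), flip(pre), grid_n = 50)
  sc_f <- project_survival_scores(flip(pre), s_f)
  expect_equal(unname(sc_f), unname(sc), tolerance = 1e-9)
})

test_that("antagonistic cohorts yield an opposite-slope survival trade-off", {
  co <- generate_cohort(n_loci = 300, n_selected = 12, s_range = c(0.5, 0.5),
                        seed = 47)
  G <- co$genotypes
  pcs <- pca_coordinates(G, locus_subset = co$truth$selected)
  ids <- function(g) names(G$groups)[G$groups == g]
  sA <- survival_surface(pcs[ids("brackish"), ], pcs[ids("larvae"), ])
  sB <- survival_surface(pcs[ids("marine"), ], pcs[ids("larvae"), ])
  st <- allele_frequencies(G)
  ori <- orient_alleles(st, "brackish", "marine", loci = co$truth$selected)
  psc <- polygenic_scores(G, ori)
  score_a <- setNames(psc$score_a, psc$id)
  juv_scores <- c(project_survival_scores(pcs[ids("brackish"), ], sA),
                  project_survival_scores(pcs[ids("marine"), ], sB))
  habitat <- setNames(as.character(G$groups), names(G$groups))
  fit <- survival_tradeoff_ancova(juv_scores, score_a, habitat)
  expect_gt(fit$slopes["brackish"], 0)
  expect_lt(fit$slopes["marine"], 0)
  expect_lt(fit$interaction_p, 0.01)
  # larvae with many brackish alleles score oppositely on the two surfaces
  larv <- ids("larvae")
  top <- larv[order(score_a[larv], decreasing = TRUE)[1:10]]
  expect_gt(mean(project_survival_scores(pcs[top, ], sA)), 0)
  expect_lt(mean(project_survival_scores(pcs[top, ], sB)), 0)
  # constant polygenic score is rejected
  expect_error(
    survival_tradeoff_ancova(juv_scores,
                             setNames(rep(1, length(score_a)),
                                      names(score_a)), habitat),
    "rank|constant|confounded"
  )
})
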