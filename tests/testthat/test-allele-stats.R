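test_that("allele frequencies match direct counting", {
  calls <- matrix(c(2L, 1L, 1L, 0L), 4, 1,
                  dimnames = list(paste0("i", 1:4), "L1"))
  G <- make_G(calls, groups = rep("g", 4))
  st <- allele_frequencies(G)
  expect_equal(st$x_g, 4)
  expect_equal(st$n_g, 8)
  expect_equal(st$p_g, 0.5)
  # a missing call drops two alleles from the total
  calls[2, 1] <- NA
  st2 <- allele_frequencies(make_G(calls, groups = rep("g", 4)))
  expect_equal(st2$n_g, 6)
  expect_equal(st2$x_g, 3)
})

test_that("group counts sum to pooled counts on random matrices", {
  G <- make_null_G(p = runif(30, 0.05, 0.95), seed = 21)
  G$calls[sample(length(G$calls), 100)] <- NA
  st <- allele_frequencies(G)
  groups <- levels(G$groups)
  # brute-force per-cell counting oracle
  for (g in groups) {
    sub <- G$calls[G$groups == g, ]
    expect_equal(st[[paste0("x_", g)]],
                 unname(apply(sub, 2, function(v) sum(v[!is.na(v)]))))
    expect_equal(st[[paste0("n_", g)]],
                 unname(apply(sub, 2, function(v) 2 * sum(!is.na(v)))))
  }
  expect_equal(st$x_pooled, rowSums(sapply(groups, function(g)
    st[[paste0("x_", g)]])))
  expect_equal(st$n_pooled, rowSums(sapply(groups, function(g)
    st[[paste0("n_", g)]])))
})

test_that("Weir-Cockerham F_ST matches the ANOVA-route oracle", {
  set.seed(31)
  # small two-group instances with <=5 loci
  for (rep in 1:8) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    L <- sample(2:5, 1)
    c1 <- matrix(rbinom(n1 * L, 2, runif(L, 0.2, 0.8)[rep(1:L, each = n1)]),
                 n1, L)
    c2 <- matrix(rbinom(n2 * L, 2, runif(L, 0.2, 0.8)[rep(1:L, each = n2)]),
                 n2, L)
    if (all(colSums(rbind(c1, c2)) %in% c(0, 2 * (n1 + n2)))) next
    G <- make_G(rbind(c1, c2), groups = rep(c("a", "b"), c(n1, n2)))
    theta <- pairwise_fst(G, c("a", "b"))
    expect_equal(as.numeric(theta),
                 oracle_wc_theta(list(a = c1, b = c2)), tolerance = 1e-12)
  }
})

test_that("F_ST behaves at the differentiation extremes", {
  # fixed alternative alleles across many loci -> theta ~ 1
  n <- 30; L <- 40
  G <- make_G(rbind(matrix(2L, n, L), matrix(0L, n, L)),
              groups = rep(c("a", "b"), each = n))
  expect_gt(as.numeric(pairwise_fst(G, c("a", "b"))), 0.95)
  # a group against an identical copy of itself: |theta| <= 1/(n-1)
  set.seed(41)
  calls <- matrix(rbinom(n * L, 2, 0.4), n, L)
  G2 <- make_G(rbind(calls, calls), groups = rep(c("a", "b"), each = n))
  expect_lt(abs(as.numeric(pairwise_fst(G2, c("a", "b")))), 1 / (n - 1))
  # same gene pool, large samples -> near zero
  set.seed(42)
  p <- runif(200, 0.1, 0.9)
  big <- sapply(p, function(pp) rbinom(300, 2, pp))
  G3 <- make_G(big, groups = rep(c("a", "b"), each = 150))
  expect_lt(abs(as.numeric(pairwise_fst(G3, c("a", "b")))), 0.005)
  # monomorphic everywhere -> NA with warning
  G4 <- make_G(matrix(2L, 10, 3), groups = rep(c("a", "b"), each = 5))
  expect_warning(expect_true(is.na(pairwise_fst(G4, c("a", "b")))),
                 "monomorphic")
})

test_that("PCA separates discrete clusters and matches the eigensolver", {
  # two clusters of identical multilocus genotypes
  a <- rep(c(2L, 0L, 2L, 0L, 1L), 4)
  b <- rep(c(0L, 2L, 0L, 2L, 1L), 4)
  calls <- rbind(matrix(a, 6, 20, byrow = TRUE),
                 matrix(b, 6, 20, byrow = TRUE))
  G <- make_G(calls, groups = rep(c("a", "b"), each = 6))
  pcs <- pca_coordinates(G, scale = FALSE)
  expect_equal(sd(pcs[1:6, 1]), 0, tolerance = 1e-10)
  expect_equal(sd(pcs[7:12, 1]), 0, tolerance = 1e-10)
  expect_gt(abs(pcs[1, 1] - pcs[7, 1]), 1)

  # coordinates reproduce the eigendecomposition of the centered covariance
  G5 <- make_null_G(p = runif(25, 0.1, 0.9), seed = 51)
  G5$calls[sample(length(G5$calls), 30)] <- NA
  pcs5 <- pca_coordinates(G5, scale = FALSE, n_axes = 3)
  m <- G5$calls
  storage.mode(m) <- "double"
  mu <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  m <- m[, apply(m, 2, var) > 0, drop = FALSE]
  m <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(m) / (nrow(m) - 1), symmetric = TRUE)
  proj <- m %*% eig$vectors[, 1:3]
  for (k in 1:3) {
    expect_equal(abs(pcs5[, k]), abs(proj[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("PCA coordinates are stable under individual reordering", {
  G <- make_null_G(p = runif(15, 0.2, 0.8), seed = 61)
  pcs <- pca_coordinates(G)
  perm <- sample(nrow(G$calls))
  Gp <- subset_genotypes(G, individuals = perm)
  pcs_p <- pca_coordinates(Gp)
  expect_equal(pcs_p, pcs[perm, ], tolerance = 1e-8, ignore_attr = TRUE)
  # monomorphic subset errors
  Gm <- make_G(matrix(1L, 6, 2), groups = rep("a", 6))
  Gm$calls[, ] <- 2L
  expect_error(pca_coordinates(Gm), "monomorphic")
})
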