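test_that("diversity closed forms: monomorphic, He correction, pi", {
  mono <- matrix(0L, 6, 10)
  d <- diversity(mono, rep("A", 6), total_sites = 100)
  expect_equal(d$pi, 0); expect_equal(d$he, 0)
  # all-het single site, n = 10 diploids: p = 0.5, He = (20/19) * 0.5
  hets <- matrix(1L, 10, 1)
  d2 <- diversity(hets, rep("A", 10), total_sites = 1)
  expect_equal(d2$he, 20 / 19 * 0.5, tolerance = 1e-12)
  # two haplotypes differing at 1 of 100 sites: pi = 0.01
  one_ind <- matrix(c(1L, rep(0L, 99)), 1, 100)
  d3 <- suppressWarnings(diversity(one_ind, "A", total_sites = 100))
  expect_equal(d3$pi, 0.01)
  expect_error(diversity(hets, rep("A", 10), total_sites = 0), "smaller")
})

test_that("pairwise F'ST spans 0 to 1 and matches the brute-force oracle", {
  same <- rbind(matrix(rep(c(0L, 1L, 2L), 5), 5, 3, byrow = TRUE),
                matrix(rep(c(0L, 1L, 2L), 5), 5, 3, byrow = TRUE))
  pops <- rep(c("A", "B"), each = 5)
  pf <- pairwise_fst(same, pops, n_perm = 0)
  expect_equal(pf$fst["A", "B"], 0)
  expect_equal(pf$gst["A", "B"], 0)
  fixed <- rbind(matrix(0L, 6, 4), matrix(2L, 6, 4))
  pf2 <- pairwise_fst(fixed, rep(c("A", "B"), each = 6), n_perm = 0)
  expect_equal(pf2$fst["A", "B"], 1)
  # p1 = 0.2, p2 = 0.8, n = 20 each, single locus: exact oracle agreement
  g1 <- c(rep(0L, 12), rep(1L, 8)) # p = 0.2
  g2 <- c(rep(2L, 12), rep(1L, 8)) # p = 0.8
  g <- matrix(c(g1, g2), ncol = 1)
  pops40 <- rep(c("A", "B"), each = 20)
  pf3 <- pairwise_fst(g, pops40, n_perm = 0)
  oracle <- oracle_gst_pair(g, pops40, c("A", "B"))
  expect_equal(pf3$gst["A", "B"], unname(oracle["gst"]), tolerance = 1e-10)
  expect_equal(pf3$fst["A", "B"], unname(oracle["gpst"]), tolerance = 1e-10)
  # monomorphic pair flagged
  pfm <- pairwise_fst(matrix(0L, 10, 3), pops, n_perm = 0)
  expect_true(is.na(pfm$fst["A", "B"]))
  expect_match(pfm$flags, "monomorphic")
})

test_that("standardisation inflates differentiation: F'ST >= GST", {
  set.seed(5)
  for (rep_i in 1:5) {
    g <- rbind(matrix(rbinom(8 * 12, 2, runif(1, 0.2, 0.5)), 8),
               matrix(rbinom(8 * 12, 2, runif(1, 0.4, 0.8)), 8))
    pf <- pairwise_fst(g, rep(c("A", "B"), each = 8), n_perm = 0)
    if (!is.na(pf$fst["A", "B"])) {
      expect_gte(pf$fst["A", "B"], pf$gst["A", "B"] - 1e-12)
    }
  }
})

test_that("AMOVA reproduces the maximal and null cases and the oracle", {
  pops <- rep(c("A", "B"), each = 6)
  # identical composition: among-population component ~ 0
  block <- matrix(rbinom(6 * 10, 2, 0.4), 6, 10)
  am0 <- suppressWarnings(amova(rbind(block, block), pops, n_perm = 49))
  expect_lt(am0$percent["among_populations"], 1e-9)
  # alternate fixation: 100% among populations, PhiST = 1
  fixed <- rbind(matrix(0L, 6, 5), matrix(2L, 6, 5))
  am1 <- amova(fixed, pops, n_perm = 49)
  expect_equal(unname(am1$percent["among_populations"]), 100)
  expect_equal(unname(am1$phi["phi_st"]), 1)
  expect_lt(am1$p_value["phi_st"], 0.05)
  # 3 pops x 10 individuals x 20 loci vs the ANOVA-route oracle
  set.seed(6)
  g <- rbind(matrix(rbinom(200, 2, 0.2), 10),
             matrix(rbinom(200, 2, 0.5), 10),
             matrix(rbinom(200, 2, 0.8), 10))
  pops3 <- rep(c("A", "B", "C"), each = 10)
  grp <- rep(c("g1", "g1", "g2"), each = 10)
  am2 <- amova(g, pops3, n_perm = 0)
  expect_equal(unname(am2$sigma),
               unname(oracle_amova(g, pops3)), tolerance = 1e-10)
  am3 <- amova(g, pops3, grp, n_perm = 0)
  expect_equal(unname(am3$sigma),
               unname(pmax(oracle_amova(g, pops3, grp), 0)), tolerance = 1e-10)
  expect_equal(sum(am3$percent), 100, tolerance = 0.1)
  # zero variance: flagged, components zero
  amz <- amova(matrix(1L, 12, 4), pops, n_perm = 9)
  expect_true(all(amz$sigma == 0))
  expect_true(all(is.na(amz$phi)))
})

test_that("covariance PCA separates clusters and matches direct eigen", {
  two <- rbind(matrix(rep(c(2L, 2L, 0L, 0L), 4), 4, 4, byrow = TRUE),
               matrix(rep(c(0L, 0L, 2L, 2L), 4), 4, 4, byrow = TRUE))
  p <- pca_covariance(two)
  expect_equal(p$percent_variance[1], 100, tolerance = 1e-8)
  expect_gt(abs(diff(range(p$coordinates[c(1, 5), 1]))), 0.1)
  expect_true(all(diff(p$percent_variance) <= 1e-12))
  expect_lte(sum(p$percent_variance), 100 + 1e-8)
  # 6 x 4 toy matrix equals a direct eigen-solver oracle up to sign
  set.seed(7)
  g <- matrix(rbinom(24, 2, 0.5), 6, 4)
  p2 <- pca_covariance(g)
  X <- scale(g, scale = FALSE)
  e <- eigen(tcrossprod(X) / 4, symmetric = TRUE)
  oracle_coords <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  for (ax in 1:3) {
    expect_true(isTRUE(all.equal(p2$coordinates[, ax], oracle_coords[, ax],
                                 tolerance = 1e-8)) ||
                isTRUE(all.equal(p2$coordinates[, ax], -oracle_coords[, ax],
                                 tolerance = 1e-8)))
  }
  expect_error(pca_covariance(two[1:2, ]), "3 individuals")
})

test_that("folded SFS counts minor alleles and matches the neutral shape", {
  mono <- matrix(0L, 5, 8)
  s <- folded_sfs(mono, rep("A", 5), "A")
  expect_true(all(s$bins == 0))
  expect_equal(s$monomorphic_sites, 8)
  single <- matrix(0L, 10, 1); single[1, 1] <- 1L
  s2 <- folded_sfs(single, rep("A", 10), "A")
  expect_equal(unname(s2$bins["1"]), 1)
  # sites with missing calls are excluded and counted
  miss <- single; miss[2, 1] <- NA
  s3 <- folded_sfs(miss, rep("A", 10), "A")
  expect_equal(s3$excluded_missing, 1)
  # constant-Ne simulation: folded bins near theta * (1/i + 1/(2n - i))
  n_loci <- 10000; N <- 2000; mu <- 5e-7; L <- 100
  sim <- simulate_coalescent(c(P = 5), c(P = N), n_loci = n_loci, mu = mu,
                             locus_length = L, seed = 15)
  per_locus <- t(vapply(sim$loci, function(l) {
    s <- folded_sfs_from_haplotypes(l$matrix, total_sites = L)
    as.numeric(s$bins)
  }, numeric(5)))
  bins <- colSums(per_locus)
  theta <- 4 * N * mu * L * n_loci
  se <- sqrt(n_loci) * apply(per_locus, 2, sd) # empirical across loci
  for (i in 1:4) {
    expected <- theta * (1 / i + 1 / (10 - i))
    expect_lt(abs(bins[i] - expected), 3 * se[i])
  }
  expect_lt(abs(bins[5] - theta / 5), 3 * se[5]) # fold point counted once
})

test_that("relative migration network follows the Sundqvist construction", {
  set.seed(8)
  # mirror-symmetric two-population system: both directed edges at 1
  block_a <- matrix(rbinom(60, 2, 0.3), 6)
  g_ab <- rbind(block_a, 2L - block_a)
  net2 <- relative_migration_network(g_ab, rep(c("A", "B"), each = 6),
                                     n_boot = 0)
  expect_equal(unname(net2$relative["A", "B"]), 1)
  expect_equal(unname(net2$relative["B", "A"]), 1)
  # 3-population frequency table vs the naive transcription
  g3 <- rbind(matrix(rbinom(80, 2, 0.2), 8),
              matrix(rbinom(80, 2, 0.5), 8),
              matrix(rbinom(80, 2, 0.85), 8))
  pops3 <- rep(c("A", "B", "C"), each = 8)
  net3 <- relative_migration_network(g3, pops3, threshold = 0, n_boot = 10,
                                     seed = 2)
  freq <- sapply(c("A", "B", "C"), function(p) {
    colMeans(g3[pops3 == p, ]) / 2
  })
  expect_equal(net3$relative, oracle_migration(freq), tolerance = 1e-10)
  # normalisation: exactly one directed edge at weight 1 before threshold
  expect_equal(sum(net3$relative == 1, na.rm = TRUE), 1)
  # a fixed, isolated population loses its edges at threshold 0.2
  g_iso <- rbind(matrix(rbinom(120, 2, 0.5), 12),
                 matrix(rbinom(120, 2, 0.45), 12),
                 matrix(2L, 12, 10))
  net_iso <- relative_migration_network(g_iso, rep(c("A", "B", "C"), each = 12),
                                        n_boot = 0)
  expect_true(all(is.na(net_iso$weights["C", c("A", "B")])))
  expect_true(all(is.na(net_iso$weights[c("A", "B"), "C"])))
})
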