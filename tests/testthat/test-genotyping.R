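# Builds a genotype_likelihoods object straight from ref/alt read counts so
# the calling stack can be exercised without the assembly stages.
gl_from_count_matrices <- function(nref, nalt, eps = 0.01,
                                   loci = NULL, positions = NULL) {
  ll <- lakerad:::gl_from_counts(nref, nalt, eps)
  n_sites <- ncol(nref)
  inds <- sprintf("ind%02d", seq_len(nrow(nref)))
  dimnames(ll$g0) <- dimnames(ll$g1) <- dimnames(ll$g2) <- list(inds, NULL)
  depth <- nref + nalt
  dimnames(depth) <- list(inds, NULL)
  structure(list(
    sites = data.frame(
      locus_id = loci %||% sprintf("locus_%03d", seq_len(n_sites)),
      position = positions %||% rep(50L, n_sites),
      ref = "A", alt = "C", stringsAsFactors = FALSE),
    loglik = ll, depth = depth, individuals = inds, error_rate = eps,
    dropped_multiallelic = 0L), class = "genotype_likelihoods")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("genotype likelihoods match the hand-computed error model", {
  eps <- 0.01
  # 10 ref reads: likelihood ordering hom-ref > het > hom-alt
  gl <- gl_from_count_matrices(matrix(10), matrix(0), eps)
  expect_true(gl$loglik$g0[1, 1] > gl$loglik$g1[1, 1])
  expect_true(gl$loglik$g1[1, 1] > gl$loglik$g2[1, 1])
  expect_equal(unname(gl$loglik$g0[1, 1]), 0) # normalised: max at 0
  # 1 ref + 1 alt: het/hom likelihood ratio from first principles
  gl2 <- gl_from_count_matrices(matrix(1), matrix(1), eps)
  p_het <- 0.5 * (1 - eps) + 0.5 * eps / 3
  ratio_oracle <- p_het^2 / ((1 - eps) * (eps / 3))
  expect_equal(ratio_oracle, 74.8, tolerance = 1e-3)
  expect_equal(unname(exp(gl2$loglik$g1[1, 1] - gl2$loglik$g0[1, 1])),
               ratio_oracle)
  # 0 reads: uninformative, all three equal
  gl3 <- gl_from_count_matrices(matrix(0), matrix(0), eps)
  expect_equal(unname(gl3$loglik$g0[1, 1]), unname(gl3$loglik$g2[1, 1]))
  # eps outside (0, 0.75) rejected
  expect_error(genotype_likelihoods(
    data.frame(individual = "a", locus_id = "l", sequence = "ACGT"),
    c(l = "ACGT"), error_rate = 0.8), "error_rate")
})

test_that("EM allele frequencies converge to the truth", {
  # all individuals deeply homozygous alt -> frequency 1
  gl <- gl_from_count_matrices(matrix(0, 5, 1), matrix(10, 5, 1))
  expect_equal(estimate_allele_frequencies(gl), 1, tolerance = 1e-6)
  # deep balanced hets -> 0.5
  gl2 <- gl_from_count_matrices(matrix(15, 8, 1), matrix(15, 8, 1))
  expect_equal(estimate_allele_frequencies(gl2), 0.5, tolerance = 1e-6)
  # 50 individuals at true p = 0.3, depth 20: within 3 binomial SE
  set.seed(21)
  p <- 0.3
  g_true <- rbinom(50, 2, p)
  nalt <- matrix(rbinom(50, 20, g_true / 2), ncol = 1)
  gl3 <- gl_from_count_matrices(matrix(20 - nalt, ncol = 1), nalt)
  se <- sqrt(p * (1 - p) / (2 * 50))
  expect_lt(abs(estimate_allele_frequencies(gl3) - p), 3 * se)
  gl0 <- gl_from_count_matrices(matrix(0), matrix(0))
  expect_error(estimate_allele_frequencies(gl0), "depth > 0")
})

test_that("calling applies the 0.95 posterior and the depth rule", {
  gl <- gl_from_count_matrices(matrix(c(10, 1), 2, 1),
                               matrix(c(0, 1), 2, 1))
  cfg3 <- genotyping_config(min_depth = 3)
  calls3 <- call_genotypes(gl, 0.5, cfg3)
  expect_equal(unname(calls3$calls[1, 1]), 0)       # 10 ref reads: confident hom ref
  expect_gt(unname(calls3$posterior[1, 1]), 0.95)
  expect_true(is.na(calls3$calls[2, 1]))    # 2 reads < min_depth 3: missing
  cfg1 <- genotyping_config(min_depth = 1)
  calls1 <- call_genotypes(gl, 0.5, cfg1)
  expect_equal(unname(calls1$calls[2, 1]), 1)       # Bayes: het at ~0.987
  expect_equal(unname(calls1$posterior[2, 1]), 0.987, tolerance = 1e-3)
})

test_that("posteriors are normalised wherever there is data", {
  set.seed(31)
  nref <- matrix(rpois(60, 6), 10, 6)
  nalt <- matrix(rpois(60, 2), 10, 6)
  gl <- gl_from_count_matrices(nref, nalt)
  p <- estimate_allele_frequencies(gl)
  w <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)
  for (j in 1:6) for (i in 1:10) {
    li <- exp(c(gl$loglik$g0[i, j], gl$loglik$g1[i, j], gl$loglik$g2[i, j]))
    post <- li * w[, j] / sum(li * w[, j])
    expect_equal(sum(post), 1, tolerance = 1e-12)
  }
})

test_that("site filters apply indel windows, depth percentiles, missingness", {
  set.seed(41)
  n_ind <- 100
  nref <- matrix(8, n_ind, 4)
  nalt <- matrix(rbinom(n_ind * 4, 8, 0.3), n_ind, 4)
  gl <- gl_from_count_matrices(nref, nalt,
                               loci = c("L1", "L1", "L2", "L3"),
                               positions = c(30, 41, 50, 60))
  calls <- call_genotypes(gl, estimate_allele_frequencies(gl),
                          genotyping_config(min_depth = 1, posterior_min = 0.5))
  # SNP 10 bases from a declared indel is removed; 11 bases away is kept
  indels <- data.frame(locus_id = "L1", position = 20)
  f <- filter_sites(calls, indels, genotyping_config())
  expect_false(any(f$sites$locus_id == "L1" & f$sites$position == 30))
  expect_true(any(f$sites$locus_id == "L1" & f$sites$position == 41))
  expect_equal(unname(attr(f, "filter_report")["indel_window"]), 1)
  # uniform depth: percentile rule removes nothing
  expect_equal(unname(attr(f, "filter_report")["depth_percentile"]), 0)
  # 31% missing under max_missing 0.30 is removed, 30% is kept
  calls31 <- calls
  calls31$calls[1:31, 3] <- NA
  calls31$calls[1:30, 4] <- NA
  f31 <- filter_sites(calls31, NULL, genotyping_config(max_missing = 0.30))
  expect_false(any(f31$sites$locus_id == "L2"))
  expect_true(any(f31$sites$locus_id == "L3"))
})

test_that("one random SNP per locus is kept, deterministically per seed", {
  set.seed(51)
  nref <- matrix(6, 20, 7)
  nalt <- matrix(rbinom(140, 6, 0.4), 20, 7)
  gl <- gl_from_count_matrices(nref, nalt,
                               loci = c("L1", "L1", "L1", "L2", "L2", "L3", "L4"),
                               positions = c(10, 20, 30, 10, 20, 10, 10))
  calls <- call_genotypes(gl, estimate_allele_frequencies(gl),
                          genotyping_config(min_depth = 1, posterior_min = 0.5))
  thin <- thin_one_snp_per_locus(calls, seed = 7)
  expect_equal(ncol(thin$calls), length(unique(thin$sites$locus_id)))
  expect_equal(sort(unique(thin$sites$locus_id)), c("L1", "L2", "L3", "L4"))
  thin2 <- thin_one_snp_per_locus(calls, seed = 7)
  expect_identical(thin$sites, thin2$sites)
  # a locus with exactly one SNP keeps that SNP
  expect_true("L4" %in% thin$sites$locus_id)
})

test_that("the filter grid is monotone and matches a brute-force filter", {
  set.seed(61)
  n_ind <- 30; n_sites <- 40
  depth <- matrix(rnbinom(n_ind * n_sites, size = 3, mu = 8), n_ind, n_sites)
  g_true <- matrix(rbinom(n_ind * n_sites, 2, 0.35), n_ind, n_sites)
  nalt <- matrix(rbinom(n_ind * n_sites, depth, g_true / 2), n_ind, n_sites)
  gl <- gl_from_count_matrices(depth - nalt, nalt,
                               loci = sprintf("L%02d", rep(1:20, each = 2)),
                               positions = rep(c(25, 75), 20))
  p <- estimate_allele_frequencies(gl)
  grid <- run_filter_grid(gl, p)
  # monotone in missingness at fixed depth and in depth at fixed missingness
  for (d in unique(grid$min_depth)) {
    sub <- grid[grid$min_depth == d, ]
    sub <- sub[order(-sub$max_missing), ]
    expect_true(all(diff(sub$n_snps) <= 0))
  }
  for (m in unique(grid$max_missing)) {
    sub <- grid[grid$max_missing == m, ]
    sub <- sub[order(sub$min_depth), ]
    expect_true(all(diff(sub$n_snps) <= 0))
  }
  # brute-force oracle for one cell: loci with >= 1 polymorphic site whose
  # missingness (posterior/depth rules applied directly) passes the cap
  cfg <- genotyping_config(min_depth = 3, max_missing = 0.10)
  calls <- call_genotypes(gl, p, cfg)
  ok_sites <- colMeans(is.na(calls$calls)) <= 0.10 &
    !is.na(calls$maf) & calls$maf > 0
  # uniform-ish depth: reproduce the percentile rule of filter_sites
  sd_all <- colSums(calls$depth)
  lo <- sort(sd_all)[max(1, ceiling(0.01 * length(sd_all)))]
  hi <- sort(sd_all)[ceiling(0.99 * length(sd_all))]
  ok_sites <- ok_sites & sd_all >= lo & sd_all <= hi
  oracle_count <- length(unique(gl$sites$locus_id[ok_sites]))
  cell <- grid$n_snps[grid$min_depth == 3 & grid$max_missing == 0.10]
  expect_equal(cell, oracle_count)
})

test_that("deep error-free data is called identically to the truth", {
  fx <- tiny_readset(seed = 23, n_loci = 30, error_rate = 0, depth_mean = 30,
                     fixed_depth = TRUE)
  catg <- assemble_loci(fx$reads$reads, fx$reads$barcodes)
  gl <- genotype_likelihoods(catg$stacks, catg$reference)
  calls <- call_genotypes(gl, estimate_allele_frequencies(gl),
                          genotyping_config())
  truth_g <- genotype_matrix(fx$sim)
  # map each called site back to its true locus/position via the variant
  # truth table (reference locus ids differ from genome ids)
  ref_truth <- setNames(substr(fx$genome$loci, 6, nchar(fx$genome$loci)),
                        names(fx$genome$loci))
  match_ref <- lakerad:::`.assign_reads_cpp`(unname(catg$reference),
                                             unname(ref_truth), NA_integer_)
  checked <- 0L
  locus_attr <- attr(truth_g, "locus")
  for (j in seq_len(ncol(calls$calls))) {
    rid <- calls$sites$locus_id[j]
    tru_locus <- names(ref_truth)[match_ref[match(rid, names(catg$reference)), 1]]
    li <- match(tru_locus, fx$reads$host_ids)
    if (is.na(li)) next
    vars <- fx$reads$variants[fx$reads$variants$locus == tru_locus, ]
    # called position is remnant-stripped; truth positions are full-locus
    vrow <- which(vars$position == calls$sites$position[j] + 5)
    if (!length(vrow)) next
    pos_in_sim <- which(fx$sim$loci[[li]]$positions == vars$position[vrow])
    site_cols <- which(locus_attr == li)
    tru_col <- truth_g[, site_cols[pos_in_sim], drop = TRUE]
    # consensus reference may carry the derived allele: align polarity
    if (calls$sites$ref[j] == vars$derived[vrow]) tru_col <- 2L - tru_col
    called <- calls$calls[, j]
    ind_match <- match(rownames(calls$calls), rownames(truth_g))
    ok <- !is.na(called)
    expect_identical(unname(called[ok]),
                     unname(tru_col[ind_match][ok]))
    checked <- checked + 1L
  }
  expect_gt(checked, 10)
})

test_that("missingness accounting agrees across margins", {
  m <- matrix(c(0, 1, NA, 2, NA, NA, 0, 0), 2, 4)
  calls <- structure(list(calls = m), class = "genotype_calls")
  rep_ <- missingness_report(calls)
  expect_equal(mean(rep_$by_individual), rep_$total)
  expect_equal(mean(rep_$by_site), rep_$total)
  expect_equal(rep_$total, 3 / 8)
})
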