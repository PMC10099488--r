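# Independent brute-force oracles used across the suite. These transcribe
# the underlying formulas as plainly as possible (explicit loops, no matrix
# shortcuts) so they stay independent of the package's implementations.

# Construct an sfs object directly from bins.
make_sfs <- function(bins, n_alleles, total_sites) {
  structure(list(bins = setNames(bins, seq_along(bins)),
                 n_alleles = n_alleles,
                 monomorphic_sites = total_sites - sum(bins),
                 excluded_missing = 0L, total_sites = total_sites,
                 population = "test"), class = "sfs")
}

# Nei & Chesser HS/HT and Hedrick G''ST for two populations, naive loops.
oracle_gst_pair <- function(g, pops, pair) {
  hs_list <- c(); ht_list <- c()
  for (j in seq_len(ncol(g))) {
    p <- c(); n <- c(); ho <- c()
    for (pp in pair) {
      col <- g[pops == pp, j]
      col <- col[!is.na(col)]
      if (!length(col)) { p <- NULL; break }
      n <- c(n, length(col))
      p <- c(p, sum(col) / (2 * length(col)))
      ho <- c(ho, mean(col == 1))
    }
    if (is.null(p) || (all(p == 0) || all(p == 1))) next
    nh <- 2 / (1 / n[1] + 1 / n[2])
    hs_hat <- (2 * p[1] * (1 - p[1]) + 2 * p[2] * (1 - p[2])) / 2
    hobs <- (ho[1] + ho[2]) / 2
    hs <- nh / (nh - 1) * (hs_hat - hobs / (2 * nh))
    pbar <- (p[1] + p[2]) / 2
    ht <- 2 * pbar * (1 - pbar) + hs / (2 * nh) - hobs / (4 * nh)
    hs_list <- c(hs_list, hs); ht_list <- c(ht_list, ht)
  }
  HS <- mean(hs_list); HT <- mean(ht_list)
  gst <- (HT - HS) / HT
  gpst <- 2 * (HT - HS) / ((2 * HT - HS) * (1 - HS))
  c(gst = gst, gpst = gpst)
}

# Nested AMOVA components via classical per-locus ANOVA sums of squares on
# allele counts (no distance matrices anywhere) — an algebraically distinct
# route that must agree with the distance-based decomposition for complete
# data.
oracle_amova <- function(g, pops, groups = NULL) {
  N <- nrow(g)
  ss_t <- 0; ss_wp <- 0; ss_wg <- 0
  for (l in seq_len(ncol(g))) {
    x <- g[, l]
    ss_t <- ss_t + sum((x - mean(x))^2)
    for (p in unique(pops)) {
      xi <- x[pops == p]
      ss_wp <- ss_wp + sum((xi - mean(xi))^2)
    }
    if (!is.null(groups)) {
      for (gg in unique(groups)) {
        xi <- x[groups == gg]
        ss_wg <- ss_wg + sum((xi - mean(xi))^2)
      }
    }
  }
  n_p <- table(pops)
  P <- length(n_p)
  if (is.null(groups)) {
    df_ap <- P - 1; df_wp <- N - P
    ms_ap <- (ss_t - ss_wp) / df_ap; ms_wp <- ss_wp / df_wp
    n1 <- (N - sum(n_p^2) / N) / df_ap
    sc <- ms_wp; sb <- (ms_ap - sc) / n1
    return(c(among_populations = sb, within_populations = sc))
  }
  grp_of_pop <- sapply(names(n_p), function(p) unique(groups[pops == p])[1])
  N_g <- table(groups)
  G <- length(N_g)
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  ss_ag <- ss_t - ss_wg; ss_ap <- ss_wg - ss_wp
  sum_np2_over_Ng <- sum(sapply(names(N_g), function(gg) {
    sum(n_p[grp_of_pop == gg]^2) / N_g[gg]
  }))
  n1 <- (N - sum_np2_over_Ng) / df_ap
  n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  sc <- ss_wp / df_wp
  sb <- (ss_ap / df_ap - sc) / n1
  sa <- (ss_ag / df_ag - sc - n2 * sb) / n3
  c(among_groups = sa, among_populations = sb, within_populations = sc)
}

# Sundqvist directional relative migration, naive transcription.
oracle_migration <- function(freq) {
  pops <- colnames(freq)
  k <- length(pops)
  nm <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    hs_terms <- c(); ht_terms <- c()
    for (s in seq_len(nrow(freq))) {
      pb <- freq[s, b]
      ppool <- (freq[s, a] + freq[s, b]) / 2
      hs_terms <- c(hs_terms, (2 * pb * (1 - pb) + 2 * ppool * (1 - ppool)) / 2)
      pm <- (pb + ppool) / 2
      ht_terms <- c(ht_terms, 2 * pm * (1 - pm))
    }
    gst <- (mean(ht_terms) - mean(hs_terms)) / mean(ht_terms)
    nm[a, b] <- (1 / gst - 1) / 4
  }
  nm / max(nm, na.rm = TRUE)
}

# Exact Mantel p by explicit enumeration with an explicit Pearson formula.
oracle_mantel_exact <- function(d1, d2) {
  n <- nrow(d1)
  pearson <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  vec <- function(m) {
    out <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) out <- c(out, m[i, j])
    out
  }
  x <- vec(d1)
  r_obs <- pearson(x, vec(d2))
  perms <- lakerad:::all_permutations(n)
  cnt <- 0L
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    if (pearson(x, vec(d2[p, p])) >= r_obs - 1e-12) cnt <- cnt + 1L
  }
  list(r = r_obs, p = cnt / nrow(perms))
}

# Monte-Carlo folded-SFS oracle under a piecewise-constant single-population
# history: simulates inter-coalescent times T_k by inverting the cumulative
# hazard (vectorised over replicates) and Rao-Blackwellises the mutation
# step through E[xi_i | genealogy] = sum_k k T_k P(i|k) mu L.
oracle_mc_folded_sfs <- function(n, boundaries_gen, sizes, mu, L, reps, seed) {
  set.seed(seed)
  bounds <- c(0, boundaries_gen, Inf)
  xi <- matrix(0, reps, n - 1)
  t_now <- rep(0, reps)
  for (k in n:2) {
    lam0 <- k * (k - 1) / 2
    e <- rexp(reps)
    t_next <- rep(NA_real_, reps)
    remaining <- e
    t_cur <- t_now
    for (ep in seq_along(sizes)) {
      rate <- lam0 / (2 * sizes[ep])
      lo <- pmax(t_cur, bounds[ep]); hi <- bounds[ep + 1]
      span_haz <- (hi - lo) * rate
      span_haz[lo >= hi] <- 0
      done <- is.na(t_next) & remaining <= span_haz
      t_next[done] <- pmax(t_cur, bounds[ep])[done] + remaining[done] / rate
      remaining <- remaining - pmax(span_haz, 0)
      remaining[remaining < 0] <- 0
    }
    Tk <- t_next - t_now
    t_now <- t_next
    pk <- lakerad::p_subtend(n, k)
    xi <- xi + outer(k * Tk, pk)
  }
  mean_xi <- colMeans(xi) * mu * L
  lakerad:::fold_spectrum(mean_xi)
}

# Error-free small metapopulation + reads fixture shared by assembly and
# genotyping tests.
tiny_readset <- function(seed = 11, n_loci = 40, error_rate = 0,
                         depth_mean = 6, fixed_depth = TRUE,
                         n_contaminant = 0, n_repeat = 0) {
  cfg <- demography_config(n_lakes = 2, n_sea = 1, seed = seed)
  sim <- simulate_metapopulation(cfg, c(Sea01 = 3, Lake01 = 3, Lake02 = 3),
                                 n_loci = n_loci)
  genome <- synthetic_genome(n_loci, n_contaminant = n_contaminant,
                             n_repeat = n_repeat, seed = seed)
  rd <- generate_ddrad_reads(genome, sim, depth_mean = depth_mean,
                             error_rate = error_rate,
                             fixed_depth = fixed_depth, seed = seed)
  list(cfg = cfg, sim = sim, genome = genome, reads = rd)
}
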