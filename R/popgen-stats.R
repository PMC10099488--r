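# Population-genomic summaries: diversity, differentiation (Nei GST and the
# Hedrick-standardised G''ST used as the normalised fixation index F'ST),
# nested AMOVA on squared allele-count distances, PCA on the genotype
# covariance matrix, folded site-frequency spectra, and the Sundqvist-style
# relative migration network.

as_call_matrix <- function(calls) {
  if (inherits(calls, "genotype_calls")) calls$calls else as.matrix(calls)
}

#' Within-population diversity
#'
#' Per population: expected heterozygosity He (small-sample corrected,
#' `(2n/(2n-1)) * (1 - p^2 - q^2)` per site) averaged over the population's
#' variable sites; nucleotide diversity pi as the same per-site quantity
#' summed over all sites and divided by `total_sites` (variable plus
#' invariant); observed heterozygosity Ho. Populations of fewer than two
#' individuals are computed with a warning.
#'
#' @param calls Genotype matrix (individuals x sites, 0/1/2/NA) or
#'   `genotype_calls` object.
#' @param populations Population label per individual.
#' @param total_sites Total callable sites (>= number of variable sites).
#' @return data.frame population, n, pi, he, ho, n_variable_sites.
#' @export
diversity <- function(calls, populations, total_sites) {
  g <- as_call_matrix(calls)
  stopifnot(length(populations) == nrow(g))
  if (total_sites < ncol(g)) {
    stop("total_sites (", total_sites, ") is smaller than the number of ",
         "assayed sites (", ncol(g), ")")
  }
  out <- lapply(unique(populations), function(pop) {
    sub <- g[populations == pop, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning("population '", pop, "' has fewer than 2 individuals; ",
              "estimates are unreliable")
    }
    n_called <- colSums(!is.na(sub))
    p <- colSums(sub, na.rm = TRUE) / (2 * n_called)
    usable <- n_called >= 1
    two_n <- 2 * n_called
    h_site <- ifelse(two_n > 1, two_n / (two_n - 1) * 2 * p * (1 - p), 0)
    variable <- usable & !is.na(p) & p > 0 & p < 1
    he <- if (any(variable)) mean(h_site[variable]) else 0
    pi <- sum(h_site[variable]) / total_sites
    ho <- mean(sub == 1, na.rm = TRUE)
    data.frame(population = pop, n = nrow(sub), pi = pi, he = he,
               ho = ifelse(is.nan(ho), 0, ho),
               n_variable_sites = sum(variable), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Nei & Chesser (1983) unbiased HS/HT for a set of populations at one site,
# from genotype counts. Returns c(hs, ht) or NA if undefined.
nei_hs_ht <- function(freqs, ns, hos) {
  k <- length(freqs)
  nh <- k / sum(1 / ns) # harmonic mean sample size
  hs_hat <- mean(2 * freqs * (1 - freqs))
  ho <- mean(hos)
  hs <- nh / (nh - 1) * (hs_hat - ho / (2 * nh))
  pbar <- mean(freqs)
  ht <- 2 * pbar * (1 - pbar) + hs / (nh * k) - ho / (2 * nh * k)
  c(hs = hs, ht = ht)
}

# Multi-locus GST and Hedrick G''ST for two populations given a genotype
# matrix and labels; averages HS and HT across sites before forming ratios.
pair_gst <- function(g, populations, pair) {
  sel <- populations %in% pair
  sub <- g[sel, , drop = FALSE]
  pops <- populations[sel]
  hs_all <- ht_all <- numeric(0)
  for (j in seq_len(ncol(sub))) {
    col <- sub[, j]
    ns <- vapply(pair, function(p) sum(!is.na(col[pops == p])), numeric(1))
    if (any(ns < 1)) next
    freqs <- vapply(pair, function(p) {
      v <- col[pops == p]
      sum(v, na.rm = TRUE) / (2 * sum(!is.na(v)))
    }, numeric(1))
    hos <- vapply(pair, function(p) mean(col[pops == p] == 1, na.rm = TRUE),
                  numeric(1))
    if (all(freqs == 0) || all(freqs == 1)) next # monomorphic in the pair
    hh <- nei_hs_ht(freqs, ns, hos)
    hs_all <- c(hs_all, hh["hs"]); ht_all <- c(ht_all, hh["ht"])
  }
  if (!length(hs_all)) return(c(gst = NA_real_, gpst = NA_real_))
  HS <- mean(hs_all); HT <- mean(ht_all)
  if (HT <= 0) return(c(gst = NA_real_, gpst = NA_real_))
  gst <- (HT - HS) / HT
  k <- 2
  gpst <- k * (HT - HS) / ((k * HT - HS) * (1 - HS))
  c(gst = gst, gpst = gpst)
}

#' Pairwise differentiation: GST and normalised F'ST
#'
#' Nei GST from unbiased HS/HT (Nei & Chesser small-sample corrections,
#' HS and HT averaged over sites) and the Meirmans & Hedrick standardised
#' G''ST = k(HT - HS) / ((k HT - HS)(1 - HS)) with k = 2, reported as the
#' normalised fixation index F'ST. Negative estimates are clamped to 0 and
#' flagged; monomorphic pairs are NA with a flag. Permutation p-values
#' shuffle individuals between the two populations.
#'
#' @param calls Genotype matrix or `genotype_calls`.
#' @param populations Population label per individual.
#' @param n_perm Permutations for the p-values (0 to skip).
#' @param seed Integer seed.
#' @return List of class `pairwise_differentiation`: matrices `gst`, `fst`
#'   (= G''ST), `p_value`, plus `flags`.
#' @export
pairwise_fst <- function(calls, populations, n_perm = 999, seed = 1) {
  g <- as_call_matrix(calls)
  pops <- unique(populations)
  if (length(pops) < 2) stop("need at least 2 populations")
  k <- length(pops)
  gst <- fst <- pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(gst) <- diag(fst) <- 0
  flags <- character(0)
  with_seed(seed, {
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
      pair <- c(pops[a], pops[b])
      obs <- pair_gst(g, populations, pair)
      if (is.na(obs["gpst"])) {
        flags <- c(flags, sprintf("%s-%s: monomorphic, F'ST undefined",
                                  pair[1], pair[2]))
        next
      }
      if (obs["gpst"] < 0 || obs["gst"] < 0) {
        flags <- c(flags, sprintf("%s-%s: negative estimate clamped to 0",
                                  pair[1], pair[2]))
      }
      gst[a, b] <- gst[b, a] <- max(0, obs["gst"])
      fst[a, b] <- fst[b, a] <- min(1, max(0, obs["gpst"]))
      if (n_perm > 0) {
        sel <- which(populations %in% pair)
        lab <- populations[sel]
        stat <- obs["gpst"]
        exceed <- 0L
        for (i in seq_len(n_perm)) {
          perm <- sample(lab)
          ps <- pair_gst(g[sel, , drop = FALSE], perm, pair)["gpst"]
          if (!is.na(ps) && ps >= stat) exceed <- exceed + 1L
        }
        pv[a, b] <- pv[b, a] <- (1 + exceed) / (1 + n_perm)
      }
    }
  })
  structure(list(gst = gst, fst = fst, p_value = pv, flags = flags,
                 n_perm = n_perm, seed = seed),
            class = "pairwise_differentiation")
}

# --- AMOVA ------------------------------------------------------------------

# Squared Euclidean distances on 0/1/2 allele counts; loci with a missing
# call in either individual are excluded pairwise and the sum rescaled to
# the full locus count.
amova_dist2 <- function(g) {
  n <- nrow(g)
  d2 <- matrix(0, n, n)
  L <- ncol(g)
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in seq(i + 1, n)) {
      diff <- gi - g[j, ]
      ok <- !is.na(diff)
      d2[i, j] <- d2[j, i] <- if (any(ok)) sum(diff[ok]^2) * L / sum(ok) else 0
    }
  }
  d2
}

# Sum over within-set pairs of d2 divided by set size (Excoffier's SSD).
ssd_within <- function(d2, idx) {
  if (length(idx) < 2) return(0)
  sum(d2[idx, idx]) / 2 / length(idx)
}

amova_components <- function(d2, populations, groups) {
  N <- nrow(d2)
  pops <- unique(populations)
  P <- length(pops)
  ss_t <- ssd_within(d2, seq_len(N))
  ss_wp <- sum(vapply(pops, function(p) ssd_within(d2, which(populations == p)),
                      numeric(1)))
  n_p <- vapply(pops, function(p) sum(populations == p), numeric(1))
  if (is.null(groups)) {
    df_ap <- P - 1; df_wp <- N - P
    ms_ap <- (ss_t - ss_wp) / df_ap
    ms_wp <- ss_wp / df_wp
    n1 <- (N - sum(n_p^2) / N) / df_ap
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n1
    return(list(sigma = c(among_populations = sig_b,
                          within_populations = sig_c),
                ss = c(among_populations = ss_t - ss_wp,
                       within_populations = ss_wp),
                df = c(df_ap, df_wp)))
  }
  grp_of_pop <- vapply(pops, function(p) unique(groups[populations == p])[1],
                       groups[1])
  grps <- unique(groups)
  G <- length(grps)
  ss_wg <- sum(vapply(grps, function(g_) ssd_within(d2, which(groups == g_)),
                      numeric(1)))
  ss_ag <- ss_t - ss_wg
  ss_ap <- ss_wg - ss_wp
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  N_g <- vapply(grps, function(g_) sum(groups == g_), numeric(1))
  sum_np2_by_g <- vapply(grps, function(g_) {
    sum(n_p[grp_of_pop == g_]^2) / sum(N_g[grps == g_])
  }, numeric(1))
  n1 <- (N - sum(sum_np2_by_g)) / df_ap
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  ms_wp <- ss_wp / df_wp
  ms_ap <- ss_ap / df_ap
  ms_ag <- ss_ag / df_ag
  sig_c <- ms_wp
  sig_b <- (ms_ap - sig_c) / n1
  sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
  list(sigma = c(among_groups = sig_a, among_populations = sig_b,
                 within_populations = sig_c),
       ss = c(among_groups = ss_ag, among_populations = ss_ap,
              within_populations = ss_wp),
       df = c(df_ag, df_ap, df_wp))
}

#' Nested analysis of molecular variance (AMOVA)
#'
#' Variance components from nested sums of squares on squared pairwise
#' allele-count distances (Excoffier's SSD decomposition with unequal-size
#' coefficients), Phi statistics, and permutation p-values: PhiST permutes
#' individuals among populations, PhiSC permutes individuals among
#' populations within groups, PhiCT permutes whole populations among
#' groups. Negative components are truncated to 0 with a warning.
#'
#' @param calls Genotype matrix or `genotype_calls`.
#' @param populations Population label per individual.
#' @param groups Optional group label per individual (nested design).
#' @param n_perm Permutations (study default 1000).
#' @param seed Integer seed.
#' @return List of class `amova_result`: `sigma` (components), `percent`,
#'   `phi`, `p_value`, `ss`, `df`, `n_perm`.
#' @export
amova <- function(calls, populations, groups = NULL, n_perm = 1000, seed = 1) {
  g <- as_call_matrix(calls)
  stopifnot(length(populations) == nrow(g))
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(g))
    if (length(unique(groups)) < 2) groups <- NULL
  }
  d2 <- amova_dist2(g)
  obs <- amova_components(d2, populations, groups)
  sigma_raw <- obs$sigma # untruncated: permutation tests need a
                         # continuous statistic free of ties at zero
  sigma <- sigma_raw
  if (any(sigma < 0)) {
    warning("negative variance component(s) truncated to 0")
    sigma[sigma < 0] <- 0
  }
  tot <- sum(sigma)
  if (tot == 0) {
    phi <- rep(NA_real_, length(sigma) - 1)
    names(phi) <- if (is.null(groups)) "phi_st" else c("phi_ct", "phi_sc")
    return(structure(list(sigma = sigma, percent = sigma * 0, phi = phi,
                          p_value = phi, ss = obs$ss, df = obs$df,
                          n_perm = n_perm,
                          flag = "zero total variance: Phi undefined"),
                     class = "amova_result"))
  }
  percent <- 100 * sigma / tot
  with_seed(seed, {
    if (is.null(groups)) {
      phi <- c(phi_st = unname(sigma[1] / tot))
      phi_raw <- sigma_raw[1] / sum(sigma_raw)
      exceed <- 0L
      for (i in seq_len(n_perm)) {
        perm <- sample(populations)
        s <- amova_components(d2, perm, NULL)$sigma
        ph <- s[1] / sum(s)
        if (!is.na(ph) && ph >= phi_raw) exceed <- exceed + 1L
      }
      pv <- c(phi_st = (1 + exceed) / (1 + n_perm))
    } else {
      phi <- c(phi_ct = unname(sigma[1] / tot),
               phi_sc = unname(sigma[2] / (sigma[2] + sigma[3])),
               phi_st = unname((sigma[1] + sigma[2]) / tot))
      phi_raw <- c(ct = sigma_raw[1] / sum(sigma_raw),
                   sc = sigma_raw[2] / (sigma_raw[2] + sigma_raw[3]),
                   st = (sigma_raw[1] + sigma_raw[2]) / sum(sigma_raw))
      ex <- c(0L, 0L, 0L)
      pops <- unique(populations)
      grp_of_pop <- vapply(pops, function(p) unique(groups[populations == p])[1],
                           groups[1])
      for (i in seq_len(n_perm)) {
        # PhiCT: permute populations among groups
        g_perm_pop <- sample(grp_of_pop)
        groups_ct <- g_perm_pop[match(populations, pops)]
        s_ct <- amova_components(d2, populations, groups_ct)$sigma
        # PhiSC: permute individuals among populations within groups
        pop_sc <- populations
        for (gg in unique(groups)) {
          sel <- which(groups == gg)
          pop_sc[sel] <- sample(populations[sel])
        }
        s_sc <- amova_components(d2, pop_sc, groups)$sigma
        # PhiST: permute individuals among populations (everything)
        pop_st <- sample(populations)
        grp_st <- grp_of_pop[match(pop_st, pops)]
        s_st <- amova_components(d2, pop_st, grp_st)$sigma
        f <- function(s, which) {
          switch(which,
                 ct = s[1] / sum(s),
                 sc = s[2] / (s[2] + s[3]),
                 st = (s[1] + s[2]) / sum(s))
        }
        if (isTRUE(f(s_ct, "ct") >= phi_raw["ct"])) ex[1] <- ex[1] + 1L
        if (isTRUE(f(s_sc, "sc") >= phi_raw["sc"])) ex[2] <- ex[2] + 1L
        if (isTRUE(f(s_st, "st") >= phi_raw["st"])) ex[3] <- ex[3] + 1L
      }
      pv <- setNames((1 + ex) / (1 + n_perm), c("phi_ct", "phi_sc", "phi_st"))
    }
    structure(list(sigma = sigma, percent = percent, phi = phi, p_value = pv,
                   ss = obs$ss, df = obs$df, n_perm = n_perm),
              class = "amova_result")
  })
}

#' PCA on the genotype covariance matrix
#'
#' Genotypes are centred per site (missing values mean-imputed, logged via
#' the `n_imputed` attribute) and the individual x individual covariance
#' matrix eigen-decomposed; coordinates are eigenvectors scaled by the
#' square root of their eigenvalues, axes ordered by eigenvalue.
#'
#' @param calls Genotype matrix or `genotype_calls`.
#' @param standardize Divide each site by `sqrt(p(1-p))` before the
#'   decomposition.
#' @return List: `coordinates` (individuals x axes), `percent_variance`,
#'   `eigenvalues`, `n_imputed`.
#' @export
pca_covariance <- function(calls, standardize = FALSE) {
  g <- as_call_matrix(calls)
  if (nrow(g) < 3) stop("need at least 3 individuals")
  mu <- colMeans(g, na.rm = TRUE)
  n_imp <- sum(is.na(g))
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  X <- sweep(g, 2, mu)
  if (standardize) {
    p <- mu / 2
    sdv <- sqrt(pmax(p * (1 - p), 1e-12))
    X <- sweep(X, 2, sdv, `/`)
  }
  C <- tcrossprod(X) / max(1, ncol(X))
  e <- eigen(C, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  coords <- e$vectors %*% diag(sqrt(pos), nrow = length(pos))
  rownames(coords) <- rownames(g)
  pv <- if (sum(pos) > 0) 100 * pos / sum(pos) else pos
  list(coordinates = coords, percent_variance = pv, eigenvalues = e$values,
       n_imputed = n_imp)
}

#' Folded site-frequency spectrum of one population
#'
#' Bins 1..n (n = diploid count): bin i counts sites whose minor-allele
#' count among the 2n alleles is i. Sites with any missing call inside the
#' population are excluded and counted; monomorphic sites are excluded from
#' the bins but reported.
#'
#' @param calls Genotype matrix or `genotype_calls`.
#' @param populations Population label per individual.
#' @param population Which population to spectrum.
#' @param total_sites Optional total callable sites (default: assayed).
#' @return Object of class `sfs`: `bins`, `n_alleles`, `monomorphic_sites`,
#'   `excluded_missing`, `total_sites`, `population`.
#' @export
folded_sfs <- function(calls, populations, population,
                       total_sites = NULL) {
  g <- as_call_matrix(calls)
  sub <- g[populations == population, , drop = FALSE]
  n <- nrow(sub)
  if (n < 1) stop("no individuals in population '", population, "'")
  has_missing <- colSums(is.na(sub)) > 0
  complete <- sub[, !has_missing, drop = FALSE]
  ac <- colSums(complete)
  mac <- pmin(ac, 2 * n - ac)
  bins <- tabulate(mac[mac > 0], nbins = n)
  names(bins) <- seq_len(n)
  structure(list(bins = bins, n_alleles = 2L * n,
                 monomorphic_sites = sum(mac == 0),
                 excluded_missing = sum(has_missing),
                 total_sites = total_sites %||% ncol(g),
                 population = population), class = "sfs")
}

#' Folded SFS straight from simulated haplotypes
#' @param hap 0/1 haplotype matrix (haploids x sites).
#' @param total_sites Total simulated sites.
#' @return `sfs` object (n here is the diploid count, haploids / 2).
#' @export
folded_sfs_from_haplotypes <- function(hap, total_sites = ncol(hap)) {
  nh <- nrow(hap)
  ac <- colSums(hap)
  mac <- pmin(ac, nh - ac)
  n <- nh %/% 2
  bins <- tabulate(mac[mac > 0], nbins = n)
  names(bins) <- seq_len(n)
  structure(list(bins = bins, n_alleles = nh,
                 monomorphic_sites = sum(mac == 0), excluded_missing = 0L,
                 total_sites = total_sites, population = NA_character_),
            class = "sfs")
}

# --- Relative migration network --------------------------------------------

# Plain (uncorrected) multi-locus Nei GST between two frequency vectors;
# used against the hypothetical migrant pool, which has no sample size.
pool_gst <- function(p1, p2) {
  h1 <- 2 * p1 * (1 - p1)
  h2 <- 2 * p2 * (1 - p2)
  pbar <- (p1 + p2) / 2
  hs <- mean((h1 + h2) / 2)
  ht <- mean(2 * pbar * (1 - pbar))
  if (ht <= 0) return(NA_real_)
  (ht - hs) / ht
}

# Directional relative-migration values from per-population allele
# frequencies (sites x pops matrix). mig[a, b] = migration a -> b.
sundqvist_migration <- function(freq) {
  pops <- colnames(freq)
  k <- length(pops)
  nm <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    pool <- (freq[, a] + freq[, b]) / 2
    # gene flow a -> b leaves the recipient b similar to the migrant pool
    g <- pool_gst(freq[, b], pool)
    if (is.na(g)) next
    nm[a, b] <- if (g <= 0) Inf else (1 / g - 1) / 4
  }
  nm
}

#' Relative migration network
#'
#' For each ordered population pair (A -> B) a hypothetical migrant pool is
#' formed from the pair's mean allele frequencies (the Sundqvist
#' construction); the directional migration estimate is Wright's
#' Nm = (1/GST - 1)/4 computed between the recipient and the pool, and all
#' directed values are divided by the global maximum so exactly one edge
#' has weight 1. Edges below `threshold` are removed; bootstrap over loci
#' gives per-edge support (fraction of bootstraps with weight >= threshold).
#'
#' @param calls Genotype matrix or `genotype_calls`.
#' @param populations Population label per individual.
#' @param threshold Minimum retained relative migration (study value 0.2).
#' @param n_boot Bootstrap replicates over loci (study value 1000).
#' @param seed Integer seed.
#' @return List of class `migration_network`: `weights` (directed matrix,
#'   below-threshold edges NA), `relative` (all weights), `support`,
#'   `edges` (data.frame), `flags`.
#' @export
relative_migration_network <- function(calls, populations, threshold = 0.2,
                                       n_boot = 1000, seed = 1) {
  g <- as_call_matrix(calls)
  pops <- unique(populations)
  if (length(pops) < 2) stop("need at least 2 populations")
  freq <- vapply(pops, function(p) {
    sub <- g[populations == p, , drop = FALSE]
    colSums(sub, na.rm = TRUE) / pmax(1, 2 * colSums(!is.na(sub)))
  }, numeric(ncol(g)))
  if (is.null(dim(freq))) freq <- matrix(freq, ncol = length(pops),
                                         dimnames = list(NULL, pops))
  nm <- sundqvist_migration(freq)
  flags <- character(0)
  if (all(is.na(nm[upper.tri(nm) | lower.tri(nm)]))) {
    stop("all population pairs are monomorphic; network undefined")
  }
  finite_max <- max(nm[is.finite(nm)], na.rm = TRUE)
  nm[is.infinite(nm)] <- finite_max * 1.0 # undifferentiated pairs cap at max
  rel <- nm / max(nm, na.rm = TRUE)
  weights <- rel
  weights[!is.na(weights) & weights < threshold] <- NA
  support <- matrix(NA_real_, nrow(rel), ncol(rel), dimnames = dimnames(rel))
  if (n_boot > 0) {
    cnt <- matrix(0, nrow(rel), ncol(rel))
    with_seed(seed, {
      for (bi in seq_len(n_boot)) {
        idx <- sample.int(nrow(freq), nrow(freq), replace = TRUE)
        nb <- sundqvist_migration(freq[idx, , drop = FALSE])
        if (all(is.na(nb))) next
        fm <- suppressWarnings(max(nb[is.finite(nb)], na.rm = TRUE))
        nb[is.infinite(nb)] <- fm
        rb <- nb / max(nb, na.rm = TRUE)
        cnt <- cnt + (!is.na(rb) & rb >= threshold)
      }
    })
    support <- cnt / n_boot
    dimnames(support) <- dimnames(rel)
  }
  idx <- which(!is.na(weights), arr.ind = TRUE)
  edges <- data.frame(from = rownames(rel)[idx[, 1]],
                      to = colnames(rel)[idx[, 2]],
                      weight = weights[idx],
                      support = support[idx], stringsAsFactors = FALSE)
  structure(list(weights = weights, relative = rel, support = support,
                 edges = edges, threshold = threshold, flags = flags,
                 n_boot = n_boot), class = "migration_network")
}
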