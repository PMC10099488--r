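# Genotype likelihoods and calling. The likelihood model is the standard
# symmetric-error diploid model: a read base b given genotype g in {0,1,2}
# alt copies has P(b|g) = (g/2) p_alt + (1 - g/2) p_ref with p_x = 1 - eps
# if b = x else eps/3. Posteriors combine the likelihood with a
# Hardy-Weinberg prior at the EM-estimated global allele frequency, and a
# call is emitted only when the posterior clears `posterior_min` and the
# cell depth clears `min_depth` — everything else is missing.

#' Genotyping configuration
#'
#' @param error_rate Per-base error rate eps of the likelihood model.
#' @param posterior_min Posterior probability required to call (default
#'   0.95, the study's high-confidence threshold).
#' @param min_depth Minimum reads per cell (3 or 10 in the filter grid).
#' @param max_missing Maximum fraction of missing calls per retained site.
#' @param indel_window Bases masked on each side of a declared indel.
#' @param depth_percentiles Site-depth percentile bounds (nearest-rank,
#'   pooled over individuals).
#' @param seed Seed for the one-SNP-per-locus thinning.
#' @return List of class `genotyping_config`.
#' @export
genotyping_config <- function(error_rate = 0.01, posterior_min = 0.95,
                              min_depth = 3, max_missing = 0.30,
                              indel_window = 10, depth_percentiles = c(1, 99),
                              seed = 1) {
  stopifnot(posterior_min > 0, posterior_min < 1, min_depth >= 1)
  if (error_rate <= 0 || error_rate >= 0.75) {
    stop("error_rate must lie in (0, 0.75)")
  }
  structure(list(error_rate = error_rate, posterior_min = posterior_min,
                 min_depth = min_depth, max_missing = max_missing,
                 indel_window = indel_window,
                 depth_percentiles = depth_percentiles, seed = seed),
            class = "genotyping_config")
}

# Per-individual per-locus base counts at every position, from assigned
# stacks. Returns, per locus, a list of 5 x L count matrices by individual.
stack_base_counts <- function(stacks, individuals) {
  by_locus <- split(stacks[c("individual", "sequence")], stacks$locus_id)
  lapply(by_locus, function(df) {
    out <- lapply(split(df$sequence, factor(df$individual, levels = individuals)),
                  function(s) if (length(s)) .base_counts_cpp(s) else NULL)
    out
  })
}

#' Compute genotype likelihoods from read stacks
#'
#' Scans every reference position for candidate biallelic SNPs (ref allele =
#' reference base; alt = the most frequent non-reference base, requiring at
#' least `min_alt_reads` supporting reads pooled over individuals). Sites
#' with two or more distinct non-reference alleles at or above that support
#' are dropped as multi-allelic and logged. Per cell, log-likelihoods for
#' 0/1/2 alt copies are computed from the ref/alt read counts under the
#' symmetric error model and normalised so the maximum is 0.
#'
#' @param stacks data.frame `individual`/`locus_id`/`sequence` from
#'   [assign_reads()].
#' @param reference Named character vector of locus sequences.
#' @param error_rate Per-base error rate eps (rejected outside (0, 0.75)).
#' @param min_alt_reads Pooled alt reads required to nominate a site.
#' @param min_alt_frac Minimum alt fraction of the pooled site depth; the
#'   effective support threshold is
#'   `max(min_alt_reads, ceiling(min_alt_frac * pooled depth))`, which keeps
#'   sequencing errors from nominating sites at deep coverage while leaving
#'   shallow data governed by the absolute count.
#' @return Object of class `genotype_likelihoods`: `sites` (locus_id,
#'   position, ref, alt), `loglik` (list of three individuals x sites
#'   matrices `g0`,`g1`,`g2`), `depth` (individuals x sites, ref+alt reads),
#'   `individuals`, `dropped_multiallelic`.
#' @export
genotype_likelihoods <- function(stacks, reference, error_rate = 0.01,
                                 min_alt_reads = 2, min_alt_frac = 0.005) {
  if (error_rate <= 0 || error_rate >= 0.75) {
    stop("error_rate must lie in (0, 0.75)")
  }
  individuals <- sort(unique(stacks$individual))
  counts <- stack_base_counts(stacks, individuals)
  sites <- list(); nref_l <- list(); nalt_l <- list()
  dropped <- 0L
  for (lid in names(counts)) {
    refseq <- strsplit(reference[[lid]], "")[[1]]
    percell <- counts[[lid]]
    Lp <- min(length(refseq),
              max(vapply(percell, function(m) if (is.null(m)) 0L else ncol(m),
                         integer(1))))
    if (Lp == 0) next
    pooled <- Reduce(`+`, lapply(percell, function(m) {
      if (is.null(m)) return(matrix(0L, 5, Lp))
      out <- matrix(0L, 5, Lp)
      k <- min(ncol(m), Lp)
      out[, seq_len(k)] <- m[, seq_len(k)]
      out
    }))
    for (pos in seq_len(Lp)) {
      rb <- match(refseq[pos], DNA_BASES)
      if (is.na(rb)) next
      nonref <- pooled[1:4, pos]
      nonref[rb] <- 0L
      site_depth <- sum(pooled[1:4, pos])
      min_alt <- max(min_alt_reads, ceiling(min_alt_frac * site_depth))
      cand <- which(nonref >= min_alt)
      if (!length(cand)) next
      if (length(cand) > 1) { dropped <- dropped + 1L; next }
      ab <- cand
      nr <- vapply(percell, function(m) {
        if (is.null(m) || ncol(m) < pos) 0L else m[rb, pos]
      }, integer(1))
      na_ <- vapply(percell, function(m) {
        if (is.null(m) || ncol(m) < pos) 0L else m[ab, pos]
      }, integer(1))
      sites[[length(sites) + 1L]] <- data.frame(
        locus_id = lid, position = pos, ref = DNA_BASES[rb],
        alt = DNA_BASES[ab], stringsAsFactors = FALSE)
      nref_l[[length(nref_l) + 1L]] <- nr
      nalt_l[[length(nalt_l) + 1L]] <- na_
    }
  }
  if (!length(sites)) {
    empty <- matrix(numeric(0), length(individuals), 0,
                    dimnames = list(individuals, NULL))
    return(structure(list(
      sites = data.frame(locus_id = character(0), position = integer(0),
                         ref = character(0), alt = character(0)),
      loglik = list(g0 = empty, g1 = empty, g2 = empty), depth = empty,
      individuals = individuals, error_rate = error_rate,
      dropped_multiallelic = dropped), class = "genotype_likelihoods"))
  }
  nref <- do.call(cbind, nref_l)
  nalt <- do.call(cbind, nalt_l)
  ll <- gl_from_counts(nref, nalt, error_rate)
  dimnames(ll$g0) <- list(individuals, NULL)
  dimnames(ll$g1) <- list(individuals, NULL)
  dimnames(ll$g2) <- list(individuals, NULL)
  depth <- nref + nalt
  dimnames(depth) <- dimnames(ll$g0)
  structure(list(sites = do.call(rbind, sites), loglik = ll, depth = depth,
                 individuals = individuals, error_rate = error_rate,
                 dropped_multiallelic = dropped),
            class = "genotype_likelihoods")
}

# Normalised log-likelihood matrices from ref/alt count matrices.
gl_from_counts <- function(nref, nalt, eps) {
  p_alt <- c(eps / 3, 0.5 * (1 - eps) + 0.5 * eps / 3, 1 - eps) # by g = 0,1,2
  p_ref <- rev(p_alt)
  lls <- lapply(1:3, function(gi) {
    nref * log(p_ref[gi]) + nalt * log(p_alt[gi])
  })
  mx <- pmax(lls[[1]], lls[[2]], lls[[3]])
  mx[!is.finite(mx)] <- 0
  list(g0 = lls[[1]] - mx, g1 = lls[[2]] - mx, g2 = lls[[3]] - mx)
}

#' EM estimate of per-site alt-allele frequencies
#'
#' Fixed-point EM for the likelihood-weighted Hardy-Weinberg model: given
#' frequency p, each individual's genotype posterior is the likelihood times
#' the HWE prior; p is updated to the mean expected alt dosage over
#' individuals with data. Converges to tolerance 1e-8 or 100 iterations.
#'
#' @param gl A [genotype_likelihoods()] object.
#' @return Numeric vector of alt-allele frequencies, one per site.
#' @export
estimate_allele_frequencies <- function(gl) {
  n_sites <- nrow(gl$sites)
  if (n_sites == 0) return(numeric(0))
  if (all(gl$depth == 0)) stop("no individual has depth > 0")
  L0 <- exp(gl$loglik$g0); L1 <- exp(gl$loglik$g1); L2 <- exp(gl$loglik$g2)
  has_data <- gl$depth > 0
  p <- rep(0.2, n_sites)
  for (it in seq_len(100)) {
    w0 <- (1 - p)^2; w1 <- 2 * p * (1 - p); w2 <- p^2
    post0 <- sweep(L0, 2, w0, `*`)
    post1 <- sweep(L1, 2, w1, `*`)
    post2 <- sweep(L2, 2, w2, `*`)
    tot <- post0 + post1 + post2
    dosage <- (post1 + 2 * post2) / tot
    dosage[!has_data] <- NA
    p_new <- colMeans(dosage, na.rm = TRUE) / 2
    p_new[is.nan(p_new)] <- 0
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < 1e-8) break
  }
  p
}

#' Call high-confidence genotypes
#'
#' Posterior of genotype g is the likelihood times the HWE prior
#' ((1-p)^2, 2p(1-p), p^2). The argmax genotype is called iff its posterior
#' is at least `config$posterior_min` and the cell depth is at least
#' `config$min_depth`; otherwise the cell is missing.
#'
#' @param gl A [genotype_likelihoods()] object.
#' @param frequencies Per-site alt frequencies in `[0, 1]`.
#' @param config A [genotyping_config()].
#' @return Object of class `genotype_calls`: `calls` (individuals x sites,
#'   values 0/1/2/NA), `sites`, `depth`, `posterior` (of the called
#'   genotype), `maf` per site.
#' @export
call_genotypes <- function(gl, frequencies, config = genotyping_config()) {
  stopifnot(all(frequencies >= 0 & frequencies <= 1))
  p <- frequencies
  w <- rbind((1 - p)^2, 2 * p * (1 - p), p^2)
  post <- lapply(1:3, function(gi) {
    exp(gl$loglik[[gi]]) * matrix(w[gi, ], nrow(gl$depth), ncol(gl$depth),
                                  byrow = TRUE)
  })
  tot <- post[[1]] + post[[2]] + post[[3]]
  post <- lapply(post, `/`, tot)
  best_post <- pmax(post[[1]], post[[2]], post[[3]])
  g <- (post[[2]] > post[[1]]) + 0L
  g[post[[3]] > pmax(post[[1]], post[[2]])] <- 2L
  ok <- best_post >= config$posterior_min & gl$depth >= config$min_depth
  g[!ok] <- NA_integer_
  maf <- apply(g, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    f <- sum(col) / (2 * length(col))
    min(f, 1 - f)
  })
  structure(list(calls = g, sites = gl$sites, depth = gl$depth,
                 posterior = best_post, maf = maf, config = config),
            class = "genotype_calls")
}

#' Site filters: indel masking, depth percentiles, missingness
#'
#' Removes (in order, with per-rule counts): sites within
#' `config$indel_window` bases of a declared indel on the same locus; sites
#' whose pooled depth falls outside the nearest-rank
#' `config$depth_percentiles` of all site depths; sites whose missing-call
#' fraction exceeds `config$max_missing`.
#'
#' @param calls A [call_genotypes()] object.
#' @param declared_indels data.frame `locus_id`/`position` (e.g. simulator
#'   truth), or `NULL`.
#' @param config A [genotyping_config()].
#' @return Filtered `genotype_calls` with a `filter_report` attribute.
#' @export
filter_sites <- function(calls, declared_indels = NULL,
                         config = genotyping_config()) {
  n0 <- ncol(calls$calls)
  keep <- rep(TRUE, n0)
  n_indel <- 0L
  if (!is.null(declared_indels) && nrow(declared_indels)) {
    for (r in seq_len(nrow(declared_indels))) {
      hit <- calls$sites$locus_id == declared_indels$locus_id[r] &
        abs(calls$sites$position - declared_indels$position[r]) <= config$indel_window
      keep <- keep & !hit
    }
    n_indel <- n0 - sum(keep)
  }
  site_depth <- colSums(calls$depth)
  dp <- site_depth[keep]
  if (length(dp)) {
    lo <- nearest_rank_percentile(dp, config$depth_percentiles[1])
    hi <- nearest_rank_percentile(dp, config$depth_percentiles[2])
    bad_depth <- keep & (site_depth < lo | site_depth > hi)
  } else bad_depth <- rep(FALSE, n0)
  keep2 <- keep & !bad_depth
  miss_frac <- colMeans(is.na(calls$calls))
  bad_miss <- keep2 & miss_frac > config$max_missing
  keep3 <- keep2 & !bad_miss
  out <- subset_calls(calls, keep3)
  attr(out, "filter_report") <- c(sites_in = n0, indel_window = n_indel,
                                  depth_percentile = sum(bad_depth),
                                  missingness = sum(bad_miss),
                                  sites_out = sum(keep3))
  out
}

# Nearest-rank percentile (no interpolation), as used for the depth bounds.
nearest_rank_percentile <- function(x, p) {
  s <- sort(x)
  r <- max(1L, ceiling(p / 100 * length(s)))
  s[r]
}

subset_calls <- function(calls, keep) {
  structure(list(calls = calls$calls[, keep, drop = FALSE],
                 sites = calls$sites[keep, , drop = FALSE],
                 depth = calls$depth[, keep, drop = FALSE],
                 posterior = calls$posterior[, keep, drop = FALSE],
                 maf = calls$maf[keep], config = calls$config),
            class = "genotype_calls")
}

#' Retain one random SNP per RAD locus
#'
#' Keeps only polymorphic sites (MAF > 0 among called genotypes), then one
#' uniformly chosen SNP per locus; deterministic for a given seed.
#'
#' @param calls A `genotype_calls` object.
#' @param seed Integer seed.
#' @return Thinned `genotype_calls`.
#' @export
thin_one_snp_per_locus <- function(calls, seed = 1) {
  poly <- !is.na(calls$maf) & calls$maf > 0
  idx <- which(poly)
  if (!length(idx)) return(subset_calls(calls, logical(ncol(calls$calls))))
  chosen <- with_seed(seed, {
    vapply(split(idx, calls$sites$locus_id[idx]), function(ii) {
      if (length(ii) == 1) ii else ii[sample.int(length(ii), 1L)]
    }, integer(1))
  })
  keep <- rep(FALSE, ncol(calls$calls))
  keep[chosen] <- TRUE
  subset_calls(calls, keep)
}

#' Coverage-by-missingness sensitivity grid
#'
#' Re-calls genotypes and re-filters sites for every combination of minimum
#' depth and maximum missingness (default the study grid {3x, 10x} x
#' {30%, 10%, 5%, 1%}) and reports the SNP count per cell (one SNP per
#' locus, so the count equals the number of loci retaining a polymorphic
#' site). Counts are non-increasing along both axes by construction.
#'
#' @param gl A [genotype_likelihoods()] object.
#' @param frequencies Per-site alt frequencies.
#' @param declared_indels Optional indel truth for [filter_sites()].
#' @param min_depths,max_missings Grid axes.
#' @param config Base [genotyping_config()] supplying the other thresholds.
#' @return data.frame `min_depth`, `max_missing`, `n_snps`; attribute
#'   `cells` holds the thinned `genotype_calls` per cell.
#' @export
run_filter_grid <- function(gl, frequencies, declared_indels = NULL,
                            min_depths = c(3, 10),
                            max_missings = c(0.30, 0.10, 0.05, 0.01),
                            config = genotyping_config()) {
  rows <- list(); cells <- list()
  for (d in min_depths) for (m in max_missings) {
    cfg <- config
    cfg$min_depth <- d
    cfg$max_missing <- m
    calls <- call_genotypes(gl, frequencies, cfg)
    filt <- filter_sites(calls, declared_indels, cfg)
    thin <- thin_one_snp_per_locus(filt, seed = cfg$seed)
    key <- sprintf("d%g_m%g", d, m)
    cells[[key]] <- thin
    rows[[key]] <- data.frame(min_depth = d, max_missing = m,
                              n_snps = ncol(thin$calls))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cells") <- cells
  out
}

#' Per-individual and per-site missingness accounting
#' @param calls A `genotype_calls` object.
#' @return List `by_individual`, `by_site`, `total` (fractions; the two
#'   marginal means equal the total).
#' @export
missingness_report <- function(calls) {
  m <- is.na(calls$calls)
  list(by_individual = rowMeans(m), by_site = colMeans(m), total = mean(m))
}
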