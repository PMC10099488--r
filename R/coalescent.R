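# Structured coalescent engine used by the synthetic-data module.
#
# Time runs backwards in generations from the present (t = 0). Populations
# are diploid with sizes N_p, so a pair of lineages in population p coalesces
# at rate 1/(2 N_p) per generation. Migration is specified backwards in time:
# mig[p, q] is the per-lineage rate at which a lineage currently in p jumps
# to q (i.e. the forward-time fraction of p made up of immigrants from q).
# Scheduled demographic events support founder episodes ("move": every
# lineage in a population relocates instantaneously, closing that
# population) and piecewise-constant size changes ("resize").

# Simulate one genealogy. n_per_pop: named haploid sample counts.
# Returns list(lengths, carriers): one entry per branch below the MRCA,
# carriers being the sampled haploid indices descending from that branch.
sim_genealogy <- function(n_per_pop, pop_sizes, mig = NULL, events = list()) {
  pops <- names(pop_sizes)
  stopifnot(!is.null(pops), all(names(n_per_pop) %in% pops))
  if (is.null(mig)) {
    mig <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  }
  n_tot <- sum(n_per_pop)
  lin_pop <- rep(match(names(n_per_pop), pops), n_per_pop)
  lin_birth <- numeric(n_tot)
  carriers <- as.list(seq_len(n_tot))
  sizes <- as.numeric(pop_sizes)
  out_rate <- rowSums(mig)
  ev_times <- vapply(events, `[[`, numeric(1), "time")
  ev_ord <- order(ev_times)
  events <- events[ev_ord]
  ev_times <- ev_times[ev_ord]
  ev_i <- 1L
  t <- 0
  br_len <- numeric(0)
  br_car <- list()
  while (length(carriers) > 1L) {
    k_by_pop <- tabulate(lin_pop, nbins = length(pops))
    coal_rates <- ifelse(k_by_pop > 1, k_by_pop * (k_by_pop - 1) / 2 / (2 * sizes), 0)
    mig_rates <- k_by_pop * out_rate
    total <- sum(coal_rates) + sum(mig_rates)
    t_ev <- if (ev_i <= length(events)) ev_times[ev_i] else Inf
    dt <- if (total > 0) rexp(1, total) else Inf
    if (t + dt >= t_ev) {
      if (!is.finite(t_ev)) {
        stop("genealogy cannot reach a common ancestor: no coalescence, ",
             "migration, or scheduled event can merge the remaining lineages")
      }
      t <- t_ev
      ev <- events[[ev_i]]
      ev_i <- ev_i + 1L
      if (ev$type == "move") {
        from <- match(ev$from, pops)
        to <- match(ev$to, pops)
        lin_pop[lin_pop == from] <- to
        out_rate[from] <- 0 # closed: nothing migrates out of an empty deme
      } else if (ev$type == "resize") {
        sizes[match(ev$pop, pops)] <- ev$size
      } else {
        stop("unknown event type: ", ev$type)
      }
      next
    }
    t <- t + dt
    u <- runif(1) * total
    cum <- cumsum(c(coal_rates, mig_rates))
    which_ev <- which(u <= cum)[1]
    if (which_ev <= length(pops)) { # coalescence in population `which_ev`
      p <- which_ev
      idx <- which(lin_pop == p)
      pair <- idx[sample.int(length(idx), 2L)]
      for (ch in pair) {
        br_len <- c(br_len, t - lin_birth[ch])
        br_car <- c(br_car, carriers[ch])
      }
      merged <- c(carriers[[pair[1]]], carriers[[pair[2]]])
      keep <- setdiff(seq_along(carriers), pair)
      carriers <- c(carriers[keep], list(merged))
      lin_pop <- c(lin_pop[keep], p)
      lin_birth <- c(lin_birth[keep], t)
    } else { # migration
      p <- which_ev - length(pops)
      idx <- which(lin_pop == p)
      mover <- idx[sample.int(length(idx), 1L)]
      dest_rates <- mig[p, ]
      lin_pop[mover] <- sample.int(length(pops), 1L, prob = dest_rates)
    }
  }
  list(lengths = br_len, carriers = br_car)
}

#' Simulate haplotypes under a structured coalescent
#'
#' Generates independent genealogies for `n_loci` loci under an arbitrary
#' multi-population demography (diploid sizes, backward migration rates,
#' scheduled founder/resize events) and drops infinite-sites mutations onto
#' the branches at rate `mu` per site per generation.
#'
#' @param sample_sizes Named integer vector: diploid individuals sampled per
#'   population (haploid count is twice this).
#' @param pop_sizes Named numeric vector of diploid effective sizes.
#' @param migration Square backward migration-rate matrix (per lineage per
#'   generation), rows = source (present) population; `NULL` for none.
#' @param events List of events, each `list(time=, type="move", from=, to=)`
#'   or `list(time=, type="resize", pop=, size=)`, times in generations ago.
#' @param n_loci Number of independent loci.
#' @param mu Mutation rate per site per generation.
#' @param locus_length Sites per locus.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `coalescent_sim`: `loci` (per locus a list with
#'   0/1 haplotype `matrix` of haploids x segregating sites and the mutated
#'   `positions`), `samples` (data.frame of haploid row metadata), and the
#'   echoed parameters.
#' @export
simulate_coalescent <- function(sample_sizes, pop_sizes, migration = NULL,
                                events = list(), n_loci = 100,
                                mu = 1.1e-8, locus_length = 144, seed = 1) {
  stopifnot(length(sample_sizes) >= 1, all(pop_sizes > 0), mu >= 0)
  if (any(sample_sizes == 0)) {
    stop("zero sample size requested for population(s): ",
         paste(names(sample_sizes)[sample_sizes == 0], collapse = ", "))
  }
  if (any(2 * sample_sizes > 2 * pop_sizes[names(sample_sizes)])) {
    stop("sample sizes exceed twice the population sizes")
  }
  n_hap <- 2L * as.integer(sample_sizes)
  names(n_hap) <- names(sample_sizes)
  samples <- data.frame(
    population = rep(names(sample_sizes), n_hap),
    individual = rep(unlist(lapply(names(sample_sizes), function(p) {
      sprintf("%s_ind%02d", p, seq_len(sample_sizes[[p]]))
    })), each = 2L),
    haplotype = rep(1:2, sum(sample_sizes)),
    stringsAsFactors = FALSE
  )
  loci <- with_seed(seed, lapply(seq_len(n_loci), function(l) {
    g <- sim_genealogy(n_hap, pop_sizes, migration, events)
    n_mut_br <- rpois(length(g$lengths), mu * locus_length * g$lengths)
    tot <- sum(n_mut_br)
    if (tot > locus_length) {
      warning("locus ", l, ": more mutations than sites; truncating to ",
              locus_length, " (infinite-sites approximation violated)")
      # drop excess mutations from the largest branches deterministically
      keep <- rep(seq_along(n_mut_br), n_mut_br)[seq_len(locus_length)]
      n_mut_br <- tabulate(keep, nbins = length(n_mut_br))
      tot <- locus_length
    }
    if (tot == 0) {
      return(list(matrix = matrix(0L, sum(n_hap), 0L), positions = integer(0)))
    }
    pos <- sort(sample.int(locus_length, tot))
    mat <- matrix(0L, sum(n_hap), tot)
    j <- 1L
    for (b in seq_along(n_mut_br)) {
      if (n_mut_br[b] == 0) next
      for (r in seq_len(n_mut_br[b])) {
        mat[g$carriers[[b]], j] <- 1L
        j <- j + 1L
      }
    }
    list(matrix = mat, positions = pos)
  }))
  structure(list(loci = loci, samples = samples, pop_sizes = pop_sizes,
                 mu = mu, locus_length = locus_length, seed = seed),
            class = "coalescent_sim")
}
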