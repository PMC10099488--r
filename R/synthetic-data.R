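# Synthetic-data module: emulates the study design the downstream pipeline
# assumes — an ancestral sea source seeding marine-lake populations through
# founder events after the Last Glacial Maximum (~8-10 kyr ago), per-lake
# bottlenecks, migration scaled by each lake's tidal connection c, ddRAD
# loci flanked by SphI/MluCI cut sites, barcoded error-prone reads, and
# planted high-GC contaminant plus low-complexity loci.

#' Demographic configuration for the lake metapopulation simulator
#'
#' Defaults encode the study conditions: lakes founded ~9000 years ago
#' (generation time 1 year), mutation rate 1.1e-8 per site per generation,
#' a large panmictic sea source, small bottlenecked lake populations, and
#' migration from sea into each lake proportional to the lake's tidal
#' connection fraction c (c = 1 for open sea).
#'
#' @param n_lakes Number of lake populations.
#' @param n_sea Number of sea (source) populations.
#' @param founding_time Years before present at which lakes were seeded.
#' @param founder_size Diploid effective size per lake after founding.
#' @param ancestral_size Diploid effective size of the sea source.
#' @param migration_rate_base Per-generation backward migration fraction for
#'   a fully connected lake (c = 1); each lake uses `migration_rate_base * c`.
#' @param connection Numeric vector in `[0, 1]`, one c per lake (recycled);
#'   defaults to an even spread over `[0.1, 0.8]` as observed across the
#'   sampled lakes.
#' @param mutation_rate Per-site per-generation mutation rate.
#' @param generation_time Years per generation.
#' @param seed Integer seed.
#' @return Object of class `demography_config`.
#' @export
demography_config <- function(n_lakes = 9, n_sea = 2, founding_time = 9000,
                              founder_size = 500, ancestral_size = 50000,
                              migration_rate_base = 1e-4, connection = NULL,
                              mutation_rate = 1.1e-8, generation_time = 1,
                              seed = 1) {
  if (is.null(connection)) {
    connection <- if (n_lakes == 1) 0.4 else seq(0.1, 0.8, length.out = n_lakes)
  }
  connection <- rep_len(connection, n_lakes)
  stopifnot(n_lakes >= 1, n_sea >= 1, founder_size >= 1,
            ancestral_size >= 1, migration_rate_base >= 0,
            mutation_rate >= 0, generation_time > 0, founding_time > 0)
  if (any(connection < 0 | connection > 1)) {
    stop("connection values must lie in [0, 1]")
  }
  structure(list(n_lakes = n_lakes, n_sea = n_sea,
                 founding_time = founding_time, founder_size = founder_size,
                 ancestral_size = ancestral_size,
                 migration_rate_base = migration_rate_base,
                 connection = connection, mutation_rate = mutation_rate,
                 generation_time = generation_time, seed = seed),
            class = "demography_config")
}

lake_names <- function(n) sprintf("Lake%02d", seq_len(n))
sea_names <- function(n) sprintf("Sea%02d", seq_len(n))

#' Simulate the lake metapopulation
#'
#' Runs the structured coalescent under the configured demography: each lake
#' exists at its bottlenecked `founder_size` since `founding_time` (in
#' generations, = years / generation_time), backward migration moves lake
#' lineages into their source sea at rate `migration_rate_base * c`, and at
#' the founding time every lake's lineages relocate to the sea source (the
#' founder event). Sea populations merge into a single ancestral source at
#' the same time, so every genealogy reaches a common ancestor even with
#' zero ongoing migration.
#'
#' @param config A [demography_config()].
#' @param sample_sizes Named integer vector of diploid sample sizes; names
#'   must be among the simulated populations (`Lake01..`, `Sea01..`).
#' @param n_loci Number of independent RAD loci.
#' @param locus_length Sites per locus.
#' @return Object of class `metapop_sim`: the `coalescent_sim` fields plus a
#'   `truth` list with exact per-population derived-allele frequencies per
#'   locus, pairwise Hudson FST across loci, and the configured Ne
#'   trajectories. With `mutation_rate = 0` all haplotypes are identical and
#'   `truth$fst` is `NA` (flagged monomorphic).
#' @export
simulate_metapopulation <- function(config, sample_sizes, n_loci = 200,
                                    locus_length = 144) {
  stopifnot(inherits(config, "demography_config"))
  lakes <- lake_names(config$n_lakes)
  seas <- sea_names(config$n_sea)
  pops <- c(seas, lakes)
  unknown <- setdiff(names(sample_sizes), pops)
  if (length(unknown)) stop("unknown population(s): ", paste(unknown, collapse = ", "))
  if (any(sample_sizes == 0)) {
    stop("zero sample size requested for population(s): ",
         paste(names(sample_sizes)[sample_sizes == 0], collapse = ", "))
  }
  sizes <- setNames(c(rep(config$ancestral_size, config$n_sea),
                      rep(config$founder_size, config$n_lakes)), pops)
  mig <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  source_sea <- seas[((seq_len(config$n_lakes) - 1L) %% config$n_sea) + 1L]
  for (i in seq_len(config$n_lakes)) {
    mig[lakes[i], source_sea[i]] <- config$migration_rate_base * config$connection[i]
  }
  if (config$n_sea > 1) { # seas exchange freely (c = 1)
    for (a in seas) for (b in seas) if (a != b) {
      mig[a, b] <- config$migration_rate_base / (config$n_sea - 1)
    }
  }
  t_found <- config$founding_time / config$generation_time
  events <- c(
    lapply(seq_len(config$n_lakes), function(i) {
      list(time = t_found, type = "move", from = lakes[i], to = source_sea[i])
    }),
    lapply(seas[-1], function(s) {
      list(time = t_found, type = "move", from = s, to = seas[1])
    })
  )
  sim <- simulate_coalescent(sample_sizes, sizes, mig, events, n_loci,
                             config$mutation_rate, locus_length, config$seed)
  pop_of <- sim$samples$population
  pops_present <- unique(pop_of)
  freqs <- lapply(sim$loci, function(l) {
    out <- matrix(numeric(0), nrow = length(pops_present), ncol = ncol(l$matrix),
                  dimnames = list(pops_present, NULL))
    for (p in pops_present) {
      out[p, ] <- colMeans(l$matrix[pop_of == p, , drop = FALSE])
    }
    out
  })
  if (any(vapply(freqs, ncol, 1L) > 0)) {
    fst <- hudson_fst_matrix(sim$loci, pop_of)
  } else {
    fst <- matrix(NA_real_, length(unique(pop_of)), length(unique(pop_of)),
                  dimnames = list(unique(pop_of), unique(pop_of)))
    attr(fst, "flag") <- "monomorphic: FST undefined"
  }
  ne <- rbind(
    data.frame(population = pops, time_from = 0,
               time_to = rep(c(Inf, t_found), c(config$n_sea, config$n_lakes)),
               Ne = as.numeric(sizes)),
    data.frame(population = lakes, time_from = t_found, time_to = Inf,
               Ne = config$ancestral_size)
  )
  sim$truth <- list(freqs = freqs, fst = fst, ne_trajectories = ne,
                    source_sea = setNames(source_sea, lakes))
  sim$config <- config
  class(sim) <- c("metapop_sim", class(sim))
  sim
}

# Hudson-style FST (ratio of averages over loci and sites) from realized
# haplotypes; the "true" differentiation of the realized sample.
hudson_fst_matrix <- function(loci, pop_of) {
  pops <- unique(pop_of)
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
    hw <- 0; hb <- 0
    na <- sum(pop_of == pops[a]); nb <- sum(pop_of == pops[b])
    for (l in loci) {
      if (ncol(l$matrix) == 0) next
      pa <- colMeans(l$matrix[pop_of == pops[a], , drop = FALSE])
      pb <- colMeans(l$matrix[pop_of == pops[b], , drop = FALSE])
      hw <- hw + sum(2 * pa * (1 - pa) * na / (na - 1) +
                     2 * pb * (1 - pb) * nb / (nb - 1)) / 2
      hb <- hb + sum(pa * (1 - pb) + pb * (1 - pa))
    }
    fst[a, b] <- fst[b, a] <- if (hb > 0) 1 - hw / hb else NA_real_
  }
  fst
}

#' Build a synthetic ddRAD reference genome
#'
#' Host loci are random sequences at `gc_host` GC content, each starting
#' with the SphI cut-site remnant (`CATGC`) and ending at an MluCI site
#' (`AATT`). Contaminant loci (emulating high-GC microbial symbiont
#' sequence) are generated strictly above 55% GC and host loci strictly
#' below, so the downstream GC screen has a known answer. Low-complexity
#' loci are dinucleotide repeats for the masking stage.
#'
#' @param n_host,n_contaminant,n_repeat Locus counts per class.
#' @param locus_length Total locus length in bases (>= 20).
#' @param gc_host,gc_contaminant Target GC fractions (host < 0.55 <
#'   contaminant enforced by construction).
#' @param seed Integer seed.
#' @return Object of class `synthetic_genome` with `loci` (named character),
#'   `contaminant_ids`, `repeat_ids`.
#' @export
synthetic_genome <- function(n_host, n_contaminant = 0, n_repeat = 0,
                             locus_length = 144, gc_host = 0.40,
                             gc_contaminant = 0.62, seed = 1) {
  stopifnot(locus_length >= 20, gc_host < 0.5, gc_contaminant > 0.58)
  core_len <- locus_length - nchar(SPHI_REMNANT) - nchar(MLUCI_SITE)
  rand_core <- function(gc, lo, hi) {
    repeat {
      s <- sample(DNA_BASES, core_len, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      seq <- paste0(SPHI_REMNANT, paste(s, collapse = ""), MLUCI_SITE)
      g <- gc_fraction(seq)
      if (g > lo && g < hi) return(seq)
    }
  }
  with_seed(seed, {
    host <- vapply(seq_len(n_host), function(i) rand_core(gc_host, 0, 0.53),
                   character(1))
    cont <- if (n_contaminant > 0) {
      vapply(seq_len(n_contaminant),
             function(i) rand_core(gc_contaminant, 0.57, 1), character(1))
    } else character(0)
    reps <- if (n_repeat > 0) {
      vapply(seq_len(n_repeat), function(i) {
        di <- sample(c("AT", "TA", "AC", "AG"), 1)
        paste0(SPHI_REMNANT,
               substr(strrep(di, ceiling(core_len / 2)), 1, core_len),
               MLUCI_SITE)
      }, character(1))
    } else character(0)
    loci <- c(host, cont, reps)
    names(loci) <- c(sprintf("host_%04d", seq_len(n_host)),
                     if (n_contaminant > 0) sprintf("contam_%04d", seq_len(n_contaminant)),
                     if (n_repeat > 0) sprintf("repeat_%04d", seq_len(n_repeat)))
    structure(list(loci = loci,
                   contaminant_ids = names(loci)[grepl("^contam_", names(loci))],
                   repeat_ids = names(loci)[grepl("^repeat_", names(loci))],
                   locus_length = locus_length, seed = seed),
              class = "synthetic_genome")
  })
}

# Apply the derived alleles of one haplotype to a reference locus sequence.
# `alleles`: data.frame(position, ancestral, derived); `carry`: 0/1 vector.
apply_variants <- function(ref_seq, positions, derived, carry) {
  if (!length(positions) || !any(carry == 1L)) return(ref_seq)
  s <- strsplit(ref_seq, "")[[1]]
  idx <- which(carry == 1L)
  s[positions[idx]] <- derived[idx]
  paste(s, collapse = "")
}

#' Generate barcoded ddRAD reads
#'
#' Builds per-individual haplotype sequences for every host locus (reference
#' sequence plus that haplotype's derived alleles), then emits single-end
#' reads of the form `barcode + SphI remnant + locus prefix` with
#' independent per-base errors at `error_rate` and negative-binomial
#' per-individual per-locus depth (mean `depth_mean`, dispersion
#' `depth_dispersion`; the overdispersion mirrors the wide 3-80x coverage
#' spread typical of ddRAD libraries). Contaminant and repeat loci are
#' sequenced invariantly for every individual. Quality strings encode the
#' error model: every base gets the Phred score of `error_rate`.
#'
#' @param genome A [synthetic_genome()]; host locus count must be at least
#'   the simulated locus count (extra host loci stay unsequenced).
#' @param sim A [simulate_metapopulation()]/[simulate_coalescent()] result.
#' @param barcodes Named character vector individual -> barcode; all
#'   barcodes must be the same length and pairwise > 2 mismatches apart.
#'   Default: auto-generated 6-mers.
#' @param depth_mean Mean reads per individual per locus.
#' @param depth_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); `Inf` gives Poisson, negative `depth_mean` is rejected.
#' @param error_rate Per-base sequencing error probability.
#' @param read_length Read length in bases (barcode included).
#' @param fixed_depth If `TRUE`, every individual/locus gets exactly
#'   `depth_mean` reads (useful for error-free oracle checks).
#' @param seed Integer seed.
#' @return Object of class `ddrad_reads`: `reads` data.frame (id, sequence,
#'   quality), `barcodes`, `truth` (read provenance: individual, locus,
#'   haplotype), `depth` table, and the variant truth table (locus,
#'   position, ancestral, derived).
#' @export
generate_ddrad_reads <- function(genome, sim, barcodes = NULL,
                                 depth_mean = 24, depth_dispersion = 2.5,
                                 error_rate = 0.005, read_length = 150,
                                 fixed_depth = FALSE, seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  inds <- unique(sim$samples$individual)
  if (is.null(barcodes)) barcodes <- default_barcodes(length(inds), inds)
  stopifnot(all(inds %in% names(barcodes)))
  bc_len <- unique(nchar(barcodes))
  if (length(bc_len) != 1) stop("barcodes must share one length")
  check_barcode_separation(barcodes, max_mismatch = 1)
  if (read_length < bc_len + nchar(SPHI_REMNANT) + 1) {
    stop("read_length shorter than barcode plus cut-site remnant")
  }
  host_ids <- setdiff(names(genome$loci),
                      c(genome$contaminant_ids, genome$repeat_ids))
  n_loci <- length(sim$loci)
  if (length(host_ids) < n_loci) stop("genome has fewer host loci than simulated loci")
  host_ids <- host_ids[seq_len(n_loci)]

  with_seed(seed, {
    # derived-allele truth table per simulated locus
    variants <- lapply(seq_len(n_loci), function(l) {
      pos <- sim$loci[[l]]$positions
      ref <- strsplit(genome$loci[[host_ids[l]]], "")[[1]]
      # never mutate the cut-site remnant (reads lacking it are discarded)
      keep <- pos > nchar(SPHI_REMNANT)
      pos <- pos[keep]
      anc <- ref[pos]
      der <- vapply(anc, function(a) sample(setdiff(DNA_BASES, a), 1), character(1))
      list(position = pos, ancestral = anc, derived = der, kept = keep)
    })
    draw_depth <- function(n) {
      if (fixed_depth) rep(as.integer(depth_mean), n)
      else if (is.infinite(depth_dispersion)) rpois(n, depth_mean)
      else rnbinom(n, size = depth_dispersion, mu = depth_mean)
    }
    qual_char <- rawToChar(as.raw(33L + min(40L, if (error_rate > 0)
      as.integer(round(-10 * log10(error_rate))) else 40L)))
    ids <- character(0); seqs <- character(0)
    prov <- list()
    depth_tab <- list()
    seq_ids <- c(host_ids, genome$contaminant_ids, genome$repeat_ids)
    for (ind_i in seq_along(inds)) {
      ind <- inds[ind_i]
      rows <- which(sim$samples$individual == ind)
      d <- draw_depth(length(seq_ids))
      depth_tab[[ind]] <- d
      ind_seqs <- character(0)
      for (li in seq_along(seq_ids)) {
        if (d[li] == 0) next
        lid <- seq_ids[li]
        if (li <= n_loci) {
          v <- variants[[li]]
          hap_choice <- sample(1:2, d[li], replace = TRUE)
          hapseq <- vapply(1:2, function(h) {
            carry <- sim$loci[[li]]$matrix[rows[h], v$kept]
            apply_variants(genome$loci[[lid]], v$position, v$derived,
                           as.integer(carry))
          }, character(1))
          tmpl <- hapseq[hap_choice]
        } else {
          hap_choice <- rep(0L, d[li])
          tmpl <- rep(genome$loci[[lid]], d[li])
        }
        rd <- substr(paste0(barcodes[[ind]], tmpl), 1, read_length)
        ind_seqs <- c(ind_seqs, rd)
        prov[[length(prov) + 1L]] <- data.frame(
          individual = ind, locus = lid, haplotype = hap_choice,
          stringsAsFactors = FALSE)
      }
      seqs <- c(seqs, ind_seqs)
    }
    # per-base errors: equivalent to iid per-base flips, but drawn as a
    # binomial error count per read with uniform positions, so memory stays
    # proportional to the reads that actually carry errors
    if (error_rate > 0 && length(seqs)) {
      lens <- nchar(seqs)
      n_err <- rbinom(length(seqs), lens, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(lens[i], n_err[i])
        for (p in pos) {
          old <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1)
        }
      }
    }
    prov <- do.call(rbind, prov)
    ids <- sprintf("read_%07d %s", seq_along(seqs), prov$individual)
    depth_mat <- do.call(rbind, depth_tab)
    colnames(depth_mat) <- seq_ids
    vtab <- do.call(rbind, lapply(seq_len(n_loci), function(l) {
      v <- variants[[l]]
      if (!length(v$position)) return(NULL)
      data.frame(locus = host_ids[l], position = v$position,
                 ancestral = v$ancestral, derived = v$derived,
                 stringsAsFactors = FALSE)
    }))
    structure(list(
      reads = data.frame(id = ids, sequence = seqs,
                         quality = strrep(qual_char, nchar(seqs)),
                         stringsAsFactors = FALSE),
      barcodes = barcodes, provenance = prov, depth = depth_mat,
      variants = vtab, host_ids = host_ids, error_rate = error_rate,
      read_length = read_length, seed = seed), class = "ddrad_reads")
  })
}

# Auto-generate well-separated fixed-length barcodes (pairwise >= 3
# mismatches, i.e. unambiguous at 1 allowed mismatch). Deterministic greedy
# scan over a seeded random stream of 6-mers.
default_barcodes <- function(n, ind_names, length_bp = 6) {
  chosen <- with_seed(20231, {
    acc <- character(0)
    tries <- 0L
    while (length(acc) < n && tries < 200000L) {
      b <- paste(sample(DNA_BASES, length_bp, replace = TRUE), collapse = "")
      tries <- tries + 1L
      if (all(vapply(acc, function(x) hamming(x, b) >= 3, logical(1)))) {
        acc <- c(acc, b)
      }
    }
    acc
  })
  if (length(chosen) < n) stop("cannot generate ", n, " separated barcodes")
  setNames(chosen, ind_names)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

check_barcode_separation <- function(barcodes, max_mismatch = 1) {
  bc <- unname(barcodes)
  n <- length(bc)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (hamming(bc[i], bc[j]) <= 2 * max_mismatch) {
      stop("ambiguous barcode table: '", bc[i], "' and '", bc[j],
           "' are within ", 2 * max_mismatch, " mismatches")
    }
  }
  invisible(TRUE)
}

#' Diploid genotype matrix from simulated haplotypes
#'
#' Sums the two haplotypes of each individual at every segregating site
#' across loci — the error-free genotypes the read-based pipeline estimates.
#'
#' @param sim A `coalescent_sim` / `metapop_sim`.
#' @return Integer matrix individuals x sites (0/1/2) with a `locus`
#'   attribute mapping sites to loci.
#' @export
genotype_matrix <- function(sim) {
  inds <- unique(sim$samples$individual)
  mats <- list(); locus_of <- list()
  for (l in seq_along(sim$loci)) {
    m <- sim$loci[[l]]$matrix
    if (ncol(m) == 0) next
    gm <- m[seq(1, nrow(m), by = 2), , drop = FALSE] +
      m[seq(2, nrow(m), by = 2), , drop = FALSE]
    mats[[length(mats) + 1L]] <- gm
    locus_of[[length(locus_of) + 1L]] <- rep(l, ncol(gm))
  }
  if (!length(mats)) {
    out <- matrix(0L, length(inds), 0, dimnames = list(inds, NULL))
    attr(out, "locus") <- integer(0)
    return(out)
  }
  out <- do.call(cbind, mats)
  rownames(out) <- inds
  attr(out, "locus") <- unlist(locus_of)
  out
}

#' Generate a synthetic lake-metadata table
#'
#' Draws lake profiles within the empirical ranges of the surveyed
#' Indo-Pacific systems: temperature 29-32.4 C, salinity 23.5-33.5 ppt,
#' tidal-amplitude fraction c in `[0.1, 0.8]`; sea/lagoon rows get c = NA and
#' category "open". The connection category is recomputed from c with the
#' standard thresholds (low <= 0.4, medium 0.5-0.7, high 0.8-1).
#'
#' @param n_lakes Number of lakes (>= 2).
#' @param seed Integer seed (fixed seed gives a byte-identical table).
#' @param n_sea Number of open lagoon rows appended.
#' @return data.frame with columns code, lat, lon, area_1000m2,
#'   temperature_c, salinity_ppt, tidal_fraction, category.
#' @export
generate_lake_metadata <- function(n_lakes, seed = 1, n_sea = 2) {
  stopifnot(n_lakes >= 2)
  with_seed(seed, {
    n <- n_lakes + n_sea
    code <- c(lake_names(n_lakes), sea_names(n_sea))
    lat <- round(runif(n, -9, 2), 4)
    lon <- round(runif(n, 112, 134), 4)
    temp <- round(runif(n, 29, 32.4), 1)
    sal <- round(runif(n, 23.5, 33.5), 1)
    area <- round(exp(runif(n, log(4), log(4900))), 1)
    c_frac <- c(round(runif(n_lakes, 0.1, 0.8), 1), rep(NA_real_, n_sea))
    category <- c(vapply(c_frac[seq_len(n_lakes)], categorize_connection,
                         character(1)), rep("open", n_sea))
    data.frame(code = code, lat = lat, lon = lon, area_1000m2 = area,
               temperature_c = temp, salinity_ppt = sal,
               tidal_fraction = c_frac, category = category,
               stringsAsFactors = FALSE)
  })
}
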