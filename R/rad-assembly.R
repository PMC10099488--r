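# De novo RAD locus assembly: demultiplex -> trim -> per-individual greedy
# clustering -> low-complexity masking and N filtering -> shared reference
# -> contaminant screen -> unique read assignment. Every read dropped at any
# stage is logged with a reason code so that reads in = assigned + discarded.

#' Demultiplex barcoded RAD reads
#'
#' Assigns each read to the unique barcode within `max_mismatch` mismatches
#' and requires the restriction cut-site remnant immediately after the
#' barcode (reads whose remnant is absent are discarded, as are barcode
#' failures). Barcode and remnant are stripped from the output sequences.
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @param barcode_map Named character vector individual -> barcode (equal
#'   lengths, pairwise more than `2 * max_mismatch` apart, enforced at load).
#' @param max_mismatch Maximum barcode mismatches (default 1).
#' @param cut_remnant Expected cut-site remnant after the barcode.
#' @return List: `assigned` (data.frame id/sequence/quality/individual),
#'   `discards` (data.frame id/reason).
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 1,
                        cut_remnant = SPHI_REMNANT) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence", "quality") %in% names(reads)))
  bc_len <- unique(nchar(barcode_map))
  if (length(bc_len) != 1) stop("barcodes must share one length")
  check_barcode_separation(barcode_map, max_mismatch)
  n <- nrow(reads)
  if (n == 0) {
    return(list(assigned = cbind(reads, individual = character(0)),
                discards = data.frame(id = character(0), reason = character(0))))
  }
  prefix <- substr(reads$sequence, 1, bc_len)
  pm <- do.call(rbind, strsplit(prefix, ""))
  mm <- sapply(barcode_map, function(b) {
    bb <- strsplit(b, "")[[1]]
    rowSums(pm != matrix(bb, n, bc_len, byrow = TRUE))
  })
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = n)
  best <- apply(mm, 1, which.min)
  best_mm <- mm[cbind(seq_len(n), best)]
  has_bc <- best_mm <= max_mismatch
  rem <- substr(reads$sequence, bc_len + 1, bc_len + nchar(cut_remnant))
  has_rem <- rem == cut_remnant
  ok <- has_bc & has_rem
  reason <- rep(NA_character_, n)
  reason[!has_bc] <- "barcode not found"
  reason[has_bc & !has_rem] <- "cut site not found"
  strip <- bc_len + nchar(cut_remnant)
  assigned <- data.frame(
    id = reads$id[ok],
    sequence = substr(reads$sequence[ok], strip + 1, nchar(reads$sequence[ok])),
    quality = substr(reads$quality[ok], strip + 1, nchar(reads$quality[ok])),
    individual = names(barcode_map)[best[ok]],
    stringsAsFactors = FALSE)
  list(assigned = assigned,
       discards = data.frame(id = reads$id[!ok], reason = reason[!ok],
                             stringsAsFactors = FALSE))
}

#' Trim adapters and low-quality tails
#'
#' A deliberately simple trimmer standing in for full adapter/quality
#' pipelines: removes the 3' adapter at its first exact occurrence (or a
#' terminal prefix of it, minimum 5 bases, at the read end), then trims
#' trailing bases below `min_quality`, and drops reads shorter than
#' `min_length` (logged).
#'
#' @param reads data.frame `id`/`sequence`/`quality` (+ optional columns,
#'   preserved).
#' @param adapter_seq Adapter sequence, `NULL` to skip adapter trimming.
#' @param min_quality Minimum Phred score kept at the 3' end.
#' @param min_length Minimum surviving read length.
#' @return List `reads` (trimmed) and `discards` (id/reason).
#' @export
trim_reads <- function(reads, adapter_seq = NULL, min_quality = 10,
                       min_length = 30) {
  seqs <- reads$sequence
  quals <- reads$quality
  if (!is.null(adapter_seq) && nzchar(adapter_seq)) {
    cut <- regexpr(adapter_seq, seqs, fixed = TRUE)
    at <- which(cut > 0)
    if (length(at)) {
      seqs[at] <- substr(seqs[at], 1, cut[at] - 1)
      quals[at] <- substr(quals[at], 1, cut[at] - 1)
    }
    # terminal partial adapter (prefix of adapter at read end, >= 5 bases)
    for (k in seq(nchar(adapter_seq) - 1, 5)) {
      ad <- substr(adapter_seq, 1, k)
      tailk <- substr(seqs, nchar(seqs) - k + 1, nchar(seqs))
      hit <- which(tailk == ad)
      if (length(hit)) {
        seqs[hit] <- substr(seqs[hit], 1, nchar(seqs[hit]) - k)
        quals[hit] <- substr(quals[hit], 1, nchar(quals[hit]) - k)
      }
    }
  }
  # 3' quality trim: drop trailing run of bases below min_quality
  keep_len <- vapply(quals, function(q) {
    if (!nchar(q)) return(0L)
    ph <- utf8ToInt(q) - 33L
    ok <- which(ph >= min_quality)
    if (!length(ok)) 0L else max(ok)
  }, integer(1), USE.NAMES = FALSE)
  seqs <- substr(seqs, 1, keep_len)
  quals <- substr(quals, 1, keep_len)
  long_enough <- nchar(seqs) >= min_length
  out <- reads
  out$sequence <- seqs
  out$quality <- quals
  list(reads = out[long_enough, , drop = FALSE],
       discards = data.frame(id = reads$id[!long_enough],
                             reason = rep("too short after trimming",
                                          sum(!long_enough)),
                             stringsAsFactors = FALSE))
}

# Deterministic greedy ordering: unique sequences by abundance (desc), then
# lexicographic. Makes clustering invariant to input read order.
order_for_clustering <- function(seqs) {
  tab <- table(seqs)
  u <- names(tab)
  cnt <- as.integer(tab)
  o <- order(-cnt, u, method = "radix")
  list(unique = u[o], count = cnt[o])
}

#' Greedy centroid clustering of one individual's reads
#'
#' Unique sequences are visited in abundance-then-lexicographic order; each
#' joins the first centroid with identity at or above `identity_threshold`
#' (identity = matching positions in the gapless overlap divided by the
#' longer length), otherwise it founds a new centroid. Clusters supported by
#' fewer than `min_support` reads are discarded. The representative is the
#' per-column majority consensus over the cluster's reads, with `N` on ties.
#'
#' @param sequences Character vector of trimmed reads for one individual.
#' @param identity_threshold Identity required to join a centroid.
#' @param min_support Minimum reads per retained cluster.
#' @return data.frame: `representative`, `support`; attribute `n_discarded`
#'   (reads in under-supported clusters).
#' @export
cluster_loci <- function(sequences, identity_threshold = 0.90, min_support = 3) {
  if (!length(sequences)) {
    out <- data.frame(representative = character(0), support = integer(0))
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  os <- order_for_clustering(sequences)
  cl <- .greedy_cluster_cpp(os$unique, identity_threshold)
  support <- vapply(seq_len(max(cl)), function(k) sum(os$count[cl == k]),
                    integer(1))
  keep <- which(support >= min_support)
  reps <- vapply(keep, function(k) {
    members <- rep(os$unique[cl == k], os$count[cl == k])
    consensus_sequence(members)
  }, character(1))
  out <- data.frame(representative = reps, support = support[keep],
                    stringsAsFactors = FALSE)
  o <- order(-out$support, out$representative, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(support[support < min_support])
  out
}

#' Majority consensus of a read stack
#' @param seqs Character vector of gaplessly aligned sequences.
#' @return Single consensus sequence; ties give `N`.
#' @export
consensus_sequence <- function(seqs) {
  if (length(seqs) == 1) return(seqs)
  cnt <- .base_counts_cpp(seqs)
  bases <- c(DNA_BASES, "N")
  apply_cons <- vapply(seq_len(ncol(cnt)), function(j) {
    col <- cnt[1:4, j]
    m <- max(col)
    if (m == 0 || sum(col == m) > 1) "N" else bases[which.max(col)]
  }, character(1))
  paste(apply_cons, collapse = "")
}

#' DUST-style low-complexity score
#'
#' Triplet-overrepresentation score of the classic DUST heuristic:
#' `sum(c_t * (c_t - 1) / 2) / (n_triplets - 1)` over the 3-mers of a
#' window. A homopolymer scores ~ (w-2)/2; random sequence scores ~ 0.5.
#'
#' @param seq DNA string (window).
#' @return Numeric score.
#' @export
dust_score <- function(seq) {
  n <- nchar(seq)
  if (n < 4) return(0)
  tri <- substring(seq, 1:(n - 2), 3:n)
  tri <- tri[!grepl("N", tri, fixed = TRUE)] # N positions carry no signal
  if (length(tri) < 2) return(0)
  ct <- table(tri)
  sum(ct * (ct - 1) / 2) / (length(tri) - 1)
}

#' Mask low-complexity runs and apply the N-fraction rule
#'
#' Windows (length `window`, stepped by half a window) whose DUST score
#' exceeds `complexity_threshold` are replaced by `N`; afterwards the locus
#' is flagged `high_N` if more than `max_N_fraction` of its bases are N, and
#' `low_complexity` if any window was masked.
#'
#' @param locus Locus sequence.
#' @param max_N_fraction Discard threshold on the N fraction (strictly
#'   greater-than, so exactly 60% N is retained under the 0.6 default).
#' @param complexity_threshold DUST score above which a window is masked.
#' @param window Window length in bases.
#' @return List: `sequence` (masked), `flags` (subset of
#'   `c("low_complexity", "high_N")`), `n_fraction`.
#' @export
mask_and_filter_locus <- function(locus, max_N_fraction = 0.6,
                                  complexity_threshold = 2.0, window = 64) {
  n <- nchar(locus)
  flags <- character(0)
  s0 <- strsplit(locus, "")[[1]] # windows scored on the unmasked sequence
  s <- s0
  starts <- unique(c(seq(1, max(1, n - window + 1), by = max(1, window %/% 2)),
                     max(1, n - window + 1)))
  for (st in starts) {
    en <- min(n, st + window - 1)
    w <- paste(s0[st:en], collapse = "")
    if (dust_score(w) > complexity_threshold) {
      s[st:en] <- "N"
      flags <- union(flags, "low_complexity")
    }
  }
  n_frac <- mean(s == "N")
  if (n_frac > max_N_fraction) flags <- union(flags, "high_N")
  list(sequence = paste(s, collapse = ""), flags = flags, n_fraction = n_frac)
}

#' Build the shared de novo reference
#'
#' Clusters all individuals' cluster representatives with the same greedy
#' rule and keeps a locus iff it is present in at least `min_share_fraction`
#' of the individuals (plain fraction, so 7/10 passes a 0.7 threshold).
#'
#' @param per_individual_catalogs Named list (one entry per individual) of
#'   [cluster_loci()] outputs.
#' @param min_share_fraction Minimum fraction of individuals sharing a locus.
#' @param identity_threshold Identity for cross-individual clustering.
#' @return List: `reference` (named character vector, `locus_0001`...),
#'   `locus_table` (data.frame locus_id, n_individuals, share, support),
#'   `n_candidates`.
#' @export
build_reference <- function(per_individual_catalogs, min_share_fraction = 0.7,
                            identity_threshold = 0.90) {
  n_ind <- length(per_individual_catalogs)
  if (n_ind < 2) stop("need catalogs from at least 2 individuals")
  if (all(vapply(per_individual_catalogs, nrow, 1L) == 0)) {
    stop("all per-individual catalogs are empty")
  }
  reps <- unlist(lapply(per_individual_catalogs, function(x) x$representative),
                 use.names = FALSE)
  sup <- unlist(lapply(per_individual_catalogs, function(x) x$support),
                use.names = FALSE)
  ind <- rep(names(per_individual_catalogs) %||% as.character(seq_len(n_ind)),
             vapply(per_individual_catalogs, nrow, 1L))
  # deterministic order: total support desc, then lexicographic
  agg <- rowsum(sup, reps)
  key <- data.frame(rep = reps, sup_tot = agg[reps, 1], stringsAsFactors = FALSE)
  o <- order(-key$sup_tot, key$rep, method = "radix")
  cl <- .greedy_cluster_cpp(reps[o], identity_threshold)
  cl_of <- integer(length(reps)); cl_of[o] <- cl
  n_cl <- max(cl)
  n_by_cl <- vapply(seq_len(n_cl), function(k) length(unique(ind[cl_of == k])),
                    integer(1))
  share <- n_by_cl / n_ind
  keep <- which(share >= min_share_fraction)
  refs <- vapply(keep, function(k) {
    consensus_sequence(reps[cl_of == k])
  }, character(1))
  o2 <- order(refs, method = "radix")
  refs <- refs[o2]; keep <- keep[o2]
  names(refs) <- sprintf("locus_%05d", seq_along(refs))
  list(reference = refs,
       locus_table = data.frame(
         locus_id = names(refs), n_individuals = n_by_cl[keep],
         share = share[keep],
         support = vapply(keep, function(k) sum(sup[cl_of == k]), numeric(1)),
         stringsAsFactors = FALSE),
       n_candidates = n_cl)
}

#' Screen reference loci for contamination
#'
#' Removes loci whose GC fraction exceeds `gc_max` (microbial symbionts run
#' GC-rich relative to the sponge host) and, optionally, loci sharing at
#' least `min_kmer_hits` k-mers with a user-supplied contaminant sequence
#' set. Running the screen twice equals running it once.
#'
#' @param reference Named character vector of locus sequences.
#' @param gc_max Maximum GC fraction retained (strictly greater is removed,
#'   so exactly 55% GC survives the 0.55 default).
#' @param contaminant_kmer_set Optional character vector of contaminant
#'   sequences (or precomputed k-mers of length `k`).
#' @param k K-mer length for the screen.
#' @param min_kmer_hits Shared k-mers required to call a locus contaminant.
#' @return List: `reference` (cleaned), `removed` (data.frame locus_id,
#'   reason, gc).
#' @export
screen_contaminants <- function(reference, gc_max = 0.55,
                                contaminant_kmer_set = NULL, k = 21,
                                min_kmer_hits = 1) {
  gc <- gc_fraction(reference)
  reason <- rep(NA_character_, length(reference))
  reason[!is.na(gc) & gc > gc_max] <- "gc_above_max"
  if (!is.null(contaminant_kmer_set) && length(contaminant_kmer_set)) {
    kmers <- function(x) {
      x <- toupper(x)
      unlist(lapply(x, function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        unique(substring(s, 1:(n - k + 1), k:n))
      }))
    }
    bad <- unique(kmers(contaminant_kmer_set))
    hits <- vapply(reference, function(s) sum(kmers(s) %in% bad), integer(1))
    reason[is.na(reason) & hits >= min_kmer_hits] <- "contaminant_kmer"
  }
  drop <- !is.na(reason)
  list(reference = reference[!drop],
       removed = data.frame(locus_id = names(reference)[drop],
                            reason = reason[drop], gc = gc[drop],
                            stringsAsFactors = FALSE))
}

#' Assign reads uniquely to reference loci
#'
#' Gapless assignment (read coordinate 0 aligns to locus coordinate 0): a
#' read is kept iff its best locus has at most `max_mismatches` mismatches
#' and is strictly better than the runner-up; ties are discarded as
#' multi-mapping, failures as unmapped, all logged.
#'
#' @param reads data.frame `id`/`sequence`/`individual` (demultiplexed,
#'   trimmed).
#' @param reference Named character vector of locus sequences.
#' @param max_mismatches Maximum mismatches for a valid assignment.
#' @return List: `stacks` (data.frame individual, locus_id, sequence),
#'   `discards` (id/reason), `log` (counts per outcome).
#' @export
assign_reads <- function(reads, reference, max_mismatches = 5) {
  if (!length(reference)) stop("reference is empty")
  hk <- min(16L, min(nchar(reference)))
  hint <- match(substr(reads$sequence, 1, hk), substr(reference, 1, hk))
  res <- .assign_reads_cpp(reads$sequence, reference, as.integer(hint))
  best <- res[, 1]; b1 <- res[, 2]; b2 <- res[, 3]
  ok <- !is.na(b1) & b1 <= max_mismatches & (is.na(b2) | b2 > b1)
  multi <- !is.na(b1) & b1 <= max_mismatches & !is.na(b2) & b2 == b1
  reason <- ifelse(multi, "multi-mapping", "no locus within max mismatches")
  stacks <- data.frame(individual = reads$individual[ok],
                       locus_id = names(reference)[best[ok]],
                       sequence = reads$sequence[ok],
                       stringsAsFactors = FALSE)
  list(stacks = stacks,
       discards = data.frame(id = reads$id[!ok], reason = reason[!ok],
                             stringsAsFactors = FALSE),
       log = c(assigned = sum(ok), multi_mapping = sum(multi),
               unmapped = sum(!ok & !multi)))
}

#' Run the full assembly pipeline
#'
#' Demultiplex, trim, cluster per individual, mask and N-filter the cluster
#' representatives, build the shared reference, screen contaminants, and
#' assign reads. Produces the per-stage filter report (counts in/out per
#' rule) the accounting invariant is checked against.
#'
#' @param reads Raw read data.frame (`id`, `sequence`, `quality`).
#' @param barcode_map Named character vector individual -> barcode.
#' @param identity_threshold,min_support,min_share,gc_max,max_mismatches
#'   Stage thresholds (defaults follow the study: support 3, sharing 0.7,
#'   GC 0.55).
#' @param adapter_seq,min_quality,min_length Trimming parameters.
#' @param complexity_threshold,max_N_fraction Masking parameters.
#' @param contaminant_kmer_set Optional contaminant sequences for the k-mer
#'   screen.
#' @return List of class `locus_catalog`: `reference`, `stacks`, `report`,
#'   `locus_table`, `discards`.
#' @export
assemble_loci <- function(reads, barcode_map, identity_threshold = 0.90,
                          min_support = 3, min_share = 0.7, gc_max = 0.55,
                          max_mismatches = 5, adapter_seq = NULL,
                          min_quality = 10, min_length = 30,
                          complexity_threshold = 2.0, max_N_fraction = 0.6,
                          contaminant_kmer_set = NULL) {
  dm <- demultiplex(reads, barcode_map)
  tr <- trim_reads(dm$assigned, adapter_seq, min_quality, min_length)
  by_ind <- split(tr$reads$sequence, tr$reads$individual)
  catalogs <- lapply(by_ind, cluster_loci, identity_threshold = identity_threshold,
                     min_support = min_support)
  # mask representatives; drop high-N representatives from each catalog
  masked_flags <- c(low_complexity = 0L, high_N = 0L)
  catalogs <- lapply(catalogs, function(cat) {
    if (!nrow(cat)) return(cat)
    m <- lapply(cat$representative, mask_and_filter_locus,
                max_N_fraction = max_N_fraction,
                complexity_threshold = complexity_threshold)
    flags <- lapply(m, `[[`, "flags")
    masked_flags["low_complexity"] <<- masked_flags["low_complexity"] +
      sum(vapply(flags, function(f) "low_complexity" %in% f, logical(1)))
    masked_flags["high_N"] <<- masked_flags["high_N"] +
      sum(vapply(flags, function(f) "high_N" %in% f, logical(1)))
    keep <- !vapply(flags, function(f) "high_N" %in% f, logical(1))
    cat$representative <- vapply(m, `[[`, character(1), "sequence")
    cat[keep, , drop = FALSE]
  })
  ref <- build_reference(catalogs, min_share_fraction = min_share,
                         identity_threshold = identity_threshold)
  scr <- screen_contaminants(ref$reference, gc_max = gc_max,
                             contaminant_kmer_set = contaminant_kmer_set)
  asg <- assign_reads(tr$reads, scr$reference, max_mismatches = max_mismatches)
  report <- list(
    reads_in = nrow(reads),
    demultiplexed = nrow(dm$assigned),
    demux_discards = table(dm$discards$reason),
    trimmed = nrow(tr$reads),
    trim_discards = nrow(tr$discards),
    clusters_per_individual = vapply(catalogs, nrow, 1L),
    representatives_flagged = masked_flags,
    reference_candidates = ref$n_candidates,
    reference_loci = length(ref$reference),
    contaminants_removed = table(scr$removed$reason),
    assignment = asg$log
  )
  discards <- rbind(dm$discards, tr$discards, asg$discards)
  structure(list(reference = scr$reference, stacks = asg$stacks,
                 locus_table = ref$locus_table, removed = scr$removed,
                 report = report, discards = discards),
            class = "locus_catalog")
}
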