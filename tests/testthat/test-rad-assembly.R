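mkreads <- function(seqs, quals = NULL) {
  data.frame(id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = quals %||% strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("demultiplexing honours the one-mismatch and cut-site rules", {
  bc <- c(ind1 = "AAAAAA", ind2 = "TTTTTT")
  body <- paste0("CATGC", strrep("ACGT", 20))
  reads <- mkreads(c(
    paste0("AAAAAA", body),            # exact barcode, correct remnant
    paste0("AAAAAC", body),            # one barcode mismatch
    paste0("AAAAAA", "GGGGG", strrep("ACGT", 20)), # remnant absent
    paste0("AACCAA", body)             # two mismatches from both barcodes
  ))
  dm <- demultiplex(reads, bc)
  expect_equal(dm$assigned$individual, c("ind1", "ind1"))
  # barcode and remnant are stripped
  expect_true(all(startsWith(dm$assigned$sequence, "ACGT")))
  expect_setequal(dm$discards$reason,
                  c("cut site not found", "barcode not found"))
  # ambiguous barcode tables are rejected at load
  expect_error(demultiplex(reads, c(a = "AAAAAA", b = "AAAAAT")), "ambiguous")
})

test_that("trimming removes adapters and low-quality tails", {
  clean <- paste0(strrep("ACGT", 20))
  adapter <- "AGATCGGAAGAGC"
  tr <- trim_reads(mkreads(clean), adapter, min_quality = 10, min_length = 30)
  expect_identical(tr$reads$sequence, clean) # untouched
  tr2 <- trim_reads(mkreads(paste0(clean, adapter)), adapter,
                    min_quality = 10, min_length = 30)
  expect_identical(tr2$reads$sequence, clean)
  # all-quality-2 read is dropped entirely
  junk <- mkreads(clean, quals = strrep("#", nchar(clean)))
  tr3 <- trim_reads(junk, adapter, min_quality = 10, min_length = 30)
  expect_equal(nrow(tr3$reads), 0)
  expect_equal(tr3$discards$reason, "too short after trimming")
})

test_that("greedy clustering enforces minimum support of three reads", {
  r <- strrep("ACGT", 30)
  expect_equal(nrow(cluster_loci(rep(r, 3))), 1)
  expect_equal(nrow(cluster_loci(rep(r, 2))), 0)
  cl <- cluster_loci(rep(r, 5))
  expect_equal(cl$support, 5)
  expect_identical(cl$representative, r)
})

test_that("clustering separates templates below the identity threshold", {
  set.seed(1)
  t1 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  s1 <- strsplit(t1, "")[[1]]
  flip <- sample(100, 20) # 20% divergence
  s2 <- s1
  s2[flip] <- vapply(s1[flip], function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  t2 <- paste(s2, collapse = "")
  # exhaustive pairwise-identity oracle: within-template identity 1,
  # between-template identity 0.8 < 0.9
  ident <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  expect_equal(ident(t1, t2), 0.8)
  cl <- cluster_loci(c(rep(t1, 5), rep(t2, 5)), identity_threshold = 0.9,
                     min_support = 3)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$representative, c(t1, t2))
})

test_that("DUST masking and the N-fraction rule use the stated boundaries", {
  # 61% N flagged, 60% retained ("> 60%" is strict)
  set.seed(77)
  tail39 <- paste(sample(c("A", "C", "G", "T"), 39, replace = TRUE),
                  collapse = "")
  tail40 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                  collapse = "")
  l61 <- paste0(strrep("N", 61), tail39)
  l60 <- paste0(strrep("N", 60), tail40)
  expect_true("high_N" %in% mask_and_filter_locus(l61)$flags)
  expect_false("high_N" %in% mask_and_filter_locus(l60)$flags)
  # poly-AT dinucleotide repeat: triplet-count oracle says score >> 2
  rep_locus <- strrep("AT", 50)
  tri <- substring(rep_locus, 1:(100 - 2), 3:100)
  ct <- table(tri)
  oracle_score <- sum(ct * (ct - 1) / 2) / (length(tri) - 1)
  expect_gt(oracle_score, 2)
  expect_equal(dust_score(rep_locus), oracle_score)
  m <- mask_and_filter_locus(rep_locus)
  expect_setequal(m$flags, c("low_complexity", "high_N"))
  expect_equal(m$sequence, strrep("N", 100))
  # random sequence is left alone
  set.seed(2)
  rand <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  expect_length(mask_and_filter_locus(rand)$flags, 0)
})

test_that("reference sharing threshold is a plain fraction (7/10 passes)", {
  mkcat <- function(seqs) data.frame(representative = seqs,
                                     support = rep(5L, length(seqs)),
                                     stringsAsFactors = FALSE)
  set.seed(3)
  shared7 <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                   collapse = "")
  shared6 <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                   collapse = "")
  everywhere <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                      collapse = "")
  cats <- lapply(1:10, function(i) {
    mkcat(c(everywhere, if (i <= 7) shared7, if (i <= 6) shared6))
  })
  names(cats) <- paste0("ind", 1:10)
  ref <- build_reference(cats, min_share_fraction = 0.7)
  expect_setequal(unname(ref$reference), c(everywhere, shared7))
  expect_error(build_reference(list(mkcat(character(0)),
                                    mkcat(character(0)))), "empty")
})

test_that("GC screen uses a strict 55% boundary and is idempotent", {
  gc56 <- paste0(strrep("G", 56), strrep("A", 44))
  gc55 <- paste0(strrep("G", 55), strrep("A", 45))
  ref <- setNames(c(gc56, gc55), c("l1", "l2"))
  scr <- screen_contaminants(ref)
  expect_identical(names(scr$reference), "l2")
  expect_equal(scr$removed$locus_id, "l1")
  expect_equal(scr$removed$reason, "gc_above_max")
  scr2 <- screen_contaminants(scr$reference)
  expect_identical(scr2$reference, scr$reference)
  expect_equal(nrow(scr2$removed), 0)
  # planted contaminants among hosts: exactly the planted ones removed
  g <- synthetic_genome(60, n_contaminant = 10, seed = 8)
  scr3 <- screen_contaminants(g$loci)
  expect_setequal(scr3$removed$locus_id, g$contaminant_ids)
  # k-mer screen against a user-supplied contaminant list
  scr4 <- screen_contaminants(ref["l2"], gc_max = 1,
                              contaminant_kmer_set = gc55, k = 21)
  expect_equal(scr4$removed$reason, "contaminant_kmer")
})

test_that("read assignment is unique-only and discards ties", {
  set.seed(4)
  l1 <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  l2 <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  ref <- c(locA = l1, locB = l2)
  # a read equidistant from both loci (1 mismatch to each)
  s1 <- strsplit(l1, "")[[1]]; s2 <- strsplit(l2, "")[[1]]
  diffpos <- which(s1 != s2)
  tie <- s1; tie[diffpos] <- s2[diffpos]
  tie[diffpos[1]] <- s1[diffpos[1]]
  # tie now matches l2 except at diffpos[1]; build a true midpoint instead:
  half <- diffpos[seq_len(floor(length(diffpos) / 2))]
  mid <- s1; mid[half] <- s2[half]
  reads <- data.frame(id = c("a", "b"),
                      sequence = c(l1, paste(mid, collapse = "")),
                      individual = "ind1", stringsAsFactors = FALSE)
  asg <- assign_reads(reads, ref, max_mismatches = 90)
  expect_equal(asg$stacks$locus_id, "locA")
  expect_equal(asg$discards$reason, "multi-mapping")
  expect_equal(sum(asg$log), 2)
})

test_that("error-free synthetic reads all assign to their source loci", {
  fx <- tiny_readset(seed = 13, n_loci = 30, error_rate = 0, depth_mean = 4)
  dm <- demultiplex(fx$reads$reads, fx$reads$barcodes)
  expect_equal(nrow(dm$discards), 0)
  ref_truth <- setNames(substr(fx$genome$loci, 6, nchar(fx$genome$loci)),
                        names(fx$genome$loci))
  asg <- assign_reads(dm$assigned, ref_truth)
  expect_equal(unname(asg$log["assigned"]), nrow(dm$assigned))
  expect_identical(asg$stacks$locus_id,
                   fx$reads$provenance$locus)
})

test_that("assembly is order-invariant and accounts for every read", {
  fx <- tiny_readset(seed = 17, n_loci = 25, error_rate = 0.003,
                     depth_mean = 8, fixed_depth = FALSE, n_contaminant = 3,
                     n_repeat = 2)
  cat1 <- assemble_loci(fx$reads$reads, fx$reads$barcodes)
  shuf <- fx$reads$reads[sample.int(nrow(fx$reads$reads)), ]
  cat2 <- assemble_loci(shuf, fx$reads$barcodes)
  expect_setequal(unname(cat1$reference), unname(cat2$reference))
  # accounting: reads in = reads assigned + reads discarded, with reasons
  expect_equal(nrow(fx$reads$reads),
               nrow(cat1$stacks) + nrow(cat1$discards))
  expect_false(any(is.na(cat1$discards$reason)))
})
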