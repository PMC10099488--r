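# File formats. FASTA goes through Biostrings; FASTQ uses a strict 4-line
# parser so malformed records are rejected with their line numbers; VCF is
# written as minimal text (GT:DP:GQ) and read back through vcfR.

#' Read a FASTQ file
#'
#' Strict 4-line-per-record parsing: the header must start with `@`, the
#' separator with `+`, and sequence and quality must have equal length —
#' violations raise an error naming the record and line. An empty file
#' yields an empty record set.
#'
#' @param path FASTQ path (plain text).
#' @return data.frame `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ: ", length(lines), " lines (not a multiple of 4) in ",
         path)
  }
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad_hdr <- which(!startsWith(ids, "@"))
  if (length(bad_hdr)) {
    stop("FASTQ record ", bad_hdr[1], " (line ", (bad_hdr[1] - 1) * 4 + 1,
         "): header does not start with '@'")
  }
  bad_sep <- which(!startsWith(plus, "+"))
  if (length(bad_sep)) {
    stop("FASTQ record ", bad_sep[1], " (line ", (bad_sep[1] - 1) * 4 + 3,
         "): separator does not start with '+'")
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len)) {
    stop("FASTQ record '", sub("^@", "", ids[bad_len[1]]), "' (line ",
         (bad_len[1] - 1) * 4 + 2, "): sequence and quality lengths differ (",
         nchar(seqs[bad_len[1]]), " vs ", nchar(quals[bad_len[1]]), ")")
  }
  data.frame(id = sub("^@", "", ids), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#' @param reads data.frame `id`, `sequence`, `quality`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  out <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read / write FASTA (via Biostrings)
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write genotype calls as a minimal VCF
#'
#' Emits a VCF 4.2 text file with GT, DP and GQ per genotype; locus ids
#' serve as chromosome names. Round-trips through [read_vcf()] preserving
#' GT and DP byte-wise.
#'
#' @param calls A `genotype_calls` object.
#' @param path Output path.
#' @export
write_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lakerad",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls$calls) %||%
              paste0("ind", seq_len(nrow(calls$calls)))), collapse = "\t")
  ), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(calls$calls))) {
    g <- calls$calls[, j]
    gq <- pmin(99L, as.integer(round(-10 * log10(pmax(1e-10, 1 - calls$posterior[, j])))))
    cell <- sprintf("%s:%d:%d",
                    ifelse(is.na(g), "./.", gt_code[as.character(g)]),
                    calls$depth[, j], gq)
    writeLines(paste(c(calls$sites$locus_id[j], calls$sites$position[j],
                       sprintf("site%d", j), calls$sites$ref[j],
                       calls$sites$alt[j], ".", "PASS", ".", "GT:DP:GQ",
                       cell), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF (via vcfR) into genotype matrix form
#' @param path VCF path.
#' @return List: `calls` (individuals x sites, 0/1/2/NA), `depth`, `sites`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  to012 <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  calls <- matrix(NA_integer_, ncol(gt), nrow(gt),
                  dimnames = list(colnames(gt), rownames(gt)))
  for (i in seq_len(ncol(gt))) calls[i, ] <- to012(gt[, i])
  sites <- data.frame(locus_id = vcfR::getCHROM(v), position = vcfR::getPOS(v),
                      ref = vcfR::getREF(v), alt = vcfR::getALT(v),
                      stringsAsFactors = FALSE)
  list(calls = calls, depth = t(dp), sites = sites)
}

#' Write a labeled symmetric matrix as TSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a JSON report
#' @param x List (coerced with auto-unboxing).
#' @param path Output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
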