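# The small-preset pipeline run is shared by several end-to-end checks;
# run it once per session and cache the result.
.preset_cache <- new.env(parent = emptyenv())

get_preset_run <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (is.null(.preset_cache[[key]])) {
    cfg <- preset_small(seed = seed)
    .preset_cache[[key]] <- suppressWarnings(run_pipeline(cfg))
  }
  .preset_cache[[key]]
}

# Eligible host loci: present with at least min_support reads in at least
# a `share` fraction of individuals (computed from the simulator's depth
# truth), i.e. the loci the assembly is expected to recover.
preset_recovery <- function(res, min_support = 3, share = 0.7) {
  depth_host <- res$reads$depth[, grepl("^host_", colnames(res$reads$depth)),
                                drop = FALSE]
  eligible <- colMeans(depth_host >= min_support) >= share
  truth_core <- substr(res$genome$loci, nchar("CATGC") + 1, 10000)
  host_cov <- substr(truth_core[grepl("^host_", names(truth_core))], 1, 139)
  m <- lakerad:::`.assign_reads_cpp`(unname(host_cov),
                                     unname(res$catalog$reference),
                                     rep(NA_integer_, length(host_cov)))
  recovered <- !is.na(m[, 2]) & m[, 2] <= 5
  cont_cov <- substr(truth_core[grepl("^contam_", names(truth_core))], 1, 139)
  mc <- lakerad:::`.assign_reads_cpp`(unname(cont_cov),
                                      unname(res$catalog$reference),
                                      rep(NA_integer_, length(cont_cov)))
  contaminants_present <- sum(!is.na(mc[, 2]) & mc[, 2] <= 5)
  list(n_eligible = sum(eligible),
       n_recovered = sum(recovered & eligible),
       recovery = sum(recovered & eligible) / sum(eligible),
       contaminants_present = contaminants_present,
       n_contaminants = length(cont_cov))
}
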