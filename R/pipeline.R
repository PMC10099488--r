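# End-to-end driver: simulate -> assemble -> genotype -> stats ->
# demography -> seascape, with per-stage seeds, write-once artifact
# directories, and a provenance manifest of thresholds and checksums.

#' Pipeline configuration
#'
#' Aggregates every stage's thresholds with the study defaults (min support
#' 3, sharing 0.7, GC 0.55, indel window 10, posterior 0.95, depth grid
#' {3, 10}, missingness grid {30%, 10%, 5%, 1%}) and one explicit seed per
#' randomised stage, derived deterministically from `seed`.
#'
#' @param demography A [demography_config()].
#' @param n_individuals Diploid samples per population.
#' @param n_loci Host RAD loci to simulate.
#' @param n_contaminants,n_repeats Planted contaminant / low-complexity loci.
#' @param depth_mean,error_rate Read simulation parameters.
#' @param stages Character vector of stages to run.
#' @param genotyping A [genotyping_config()].
#' @param min_support,min_share,gc_max,identity_threshold Assembly
#'   thresholds.
#' @param grid_depths,grid_missing Filter-grid axes.
#' @param n_perm_amova,n_perm_mantel,n_boot_network,n_boot_stairway
#'   Resampling counts.
#' @param out_dir Output directory (one subdirectory per stage).
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(demography = demography_config(),
                            n_individuals = 10, n_loci = 500,
                            n_contaminants = 10, n_repeats = 5,
                            depth_mean = 24, error_rate = 0.005,
                            stages = c("simulate", "assemble", "genotype",
                                       "stats", "demography", "seascape"),
                            genotyping = genotyping_config(),
                            min_support = 3, min_share = 0.7, gc_max = 0.55,
                            identity_threshold = 0.90,
                            grid_depths = c(3, 10),
                            grid_missing = c(0.30, 0.10, 0.05, 0.01),
                            n_perm_amova = 200, n_perm_mantel = 999,
                            n_boot_network = 100, n_boot_stairway = 0,
                            out_dir = tempfile("lakerad_run_"), seed = 1) {
  stage_seeds <- setNames(vapply(seq_along(stages), function(k)
    derive_seed(seed, k), integer(1)), stages)
  structure(list(demography = demography, n_individuals = n_individuals,
                 n_loci = n_loci, n_contaminants = n_contaminants,
                 n_repeats = n_repeats, depth_mean = depth_mean,
                 error_rate = error_rate, stages = stages,
                 genotyping = genotyping, min_support = min_support,
                 min_share = min_share, gc_max = gc_max,
                 identity_threshold = identity_threshold,
                 grid_depths = grid_depths, grid_missing = grid_missing,
                 n_perm_amova = n_perm_amova, n_perm_mantel = n_perm_mantel,
                 n_boot_network = n_boot_network,
                 n_boot_stairway = n_boot_stairway,
                 out_dir = out_dir, seed = seed, stage_seeds = stage_seeds),
            class = "pipeline_config")
}

#' The small demonstration preset
#'
#' 4 lakes + 1 sea source, 500 host loci plus planted contaminants and
#' low-complexity loci, 10 diploid individuals per population — the
#' configuration used throughout the package's end-to-end checks.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
preset_small <- function(seed = 1, out_dir = tempfile("lakerad_small_"), ...) {
  pipeline_config(
    demography = demography_config(n_lakes = 4, n_sea = 1, seed = derive_seed(seed, 99)),
    n_individuals = 10, n_loci = 500, n_contaminants = 10, n_repeats = 5,
    out_dir = out_dir, seed = seed, ...)
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  if (dir.exists(d)) {
    stop("stage directory already exists (write-once): ", d)
  }
  dir.create(d, recursive = TRUE)
  d
}

#' Run the full pipeline
#'
#' Executes the toggled stages in order, writing each stage's artifacts
#' into its own write-once subdirectory of `config$out_dir`, and returns
#' (and writes) a provenance manifest recording the package version, every
#' threshold and seed, and an MD5 checksum per artifact. Identical configs
#' produce identical manifests. A stage failure halts the run with the
#' completed stages' artifacts retained.
#'
#' @param config A [pipeline_config()].
#' @return List: `manifest`, plus the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  manifest <- list(
    package = "lakerad",
    version = as.character(utils::packageVersion("lakerad")),
    seed = config$seed, stage_seeds = as.list(config$stage_seeds),
    thresholds = list(
      min_support = config$min_support, min_share = config$min_share,
      gc_max = config$gc_max, identity = config$identity_threshold,
      posterior_min = config$genotyping$posterior_min,
      indel_window = config$genotyping$indel_window,
      grid_depths = config$grid_depths, grid_missing = config$grid_missing),
    stages = list())
  record <- function(stage, dir) {
    files <- list.files(dir, full.names = TRUE, recursive = TRUE)
    manifest$stages[[stage]] <<- list(
      dir = basename(dir),
      checksums = as.list(setNames(unname(tools::md5sum(files)),
                                   basename(files))))
  }
  on.exit({
    write_json_report(manifest, file.path(config$out_dir, "manifest.json"))
  })

  lakes <- lake_names(config$demography$n_lakes)
  seas <- sea_names(config$demography$n_sea)
  pops <- c(seas, lakes)

  if ("simulate" %in% config$stages) {
    d <- stage_dir(config, "simulate")
    sizes <- setNames(rep(config$n_individuals, length(pops)), pops)
    sim <- simulate_metapopulation(config$demography, sizes,
                                   n_loci = config$n_loci)
    genome <- synthetic_genome(config$n_loci, config$n_contaminants,
                               config$n_repeats,
                               seed = config$stage_seeds[["simulate"]])
    rd <- generate_ddrad_reads(genome, sim, depth_mean = config$depth_mean,
                               error_rate = config$error_rate,
                               seed = config$stage_seeds[["simulate"]])
    write_fastq(rd$reads, file.path(d, "reads.fastq"))
    write.table(data.frame(individual = names(rd$barcodes),
                           barcode = unname(rd$barcodes)),
                file.path(d, "barcodes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_fasta(genome$loci, file.path(d, "true_loci.fasta"))
    if (!is.null(rd$variants)) {
      write.table(rd$variants, file.path(d, "true_variants.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    res$sim <- sim; res$genome <- genome; res$reads <- rd
    record("simulate", d)
  }

  if ("assemble" %in% config$stages) {
    d <- stage_dir(config, "assemble")
    cat_ <- assemble_loci(res$reads$reads, res$reads$barcodes,
                          identity_threshold = config$identity_threshold,
                          min_support = config$min_support,
                          min_share = config$min_share, gc_max = config$gc_max)
    write_fasta(cat_$reference, file.path(d, "reference.fasta"))
    write.table(cat_$locus_table, file.path(d, "locus_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_json_report(cat_$report, file.path(d, "filter_report.json"))
    res$catalog <- cat_
    record("assemble", d)
  }

  if ("genotype" %in% config$stages) {
    d <- stage_dir(config, "genotype")
    gl <- genotype_likelihoods(res$catalog$stacks, res$catalog$reference,
                               error_rate = config$genotyping$error_rate)
    freqs <- estimate_allele_frequencies(gl)
    cfg <- config$genotyping
    cfg$seed <- config$stage_seeds[["genotype"]]
    calls <- call_genotypes(gl, freqs, cfg)
    filt <- filter_sites(calls, NULL, cfg)
    thin <- thin_one_snp_per_locus(filt, seed = cfg$seed)
    grid <- run_filter_grid(gl, freqs, NULL, config$grid_depths,
                            config$grid_missing, cfg)
    write_vcf(thin, file.path(d, "snps.vcf"))
    write.table(grid, file.path(d, "filter_grid.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res$gl <- gl; res$freqs <- freqs; res$calls <- thin; res$grid <- grid
    record("genotype", d)
  }

  pop_of_individual <- function() {
    ind <- rownames(res$calls$calls)
    sub("_ind\\d+$", "", ind)
  }

  if ("stats" %in% config$stages) {
    d <- stage_dir(config, "stats")
    pop <- pop_of_individual()
    div <- diversity(res$calls, pop, total_sites = config$n_loci *
                       nchar(res$genome$loci[[1]]))
    fst <- pairwise_fst(res$calls, pop, n_perm = 0)
    grp <- ifelse(pop %in% seas, "sea", "lake")
    am <- amova(res$calls, pop,
                groups = if (length(unique(grp)) > 1) grp else NULL,
                n_perm = config$n_perm_amova,
                seed = config$stage_seeds[["stats"]])
    pca <- pca_covariance(res$calls)
    net <- tryCatch(
      relative_migration_network(res$calls, pop,
                                 n_boot = config$n_boot_network,
                                 seed = config$stage_seeds[["stats"]]),
      error = function(e) NULL)
    write.table(div, file.path(d, "diversity.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_matrix_tsv(fst$fst, file.path(d, "fst.tsv"))
    write_matrix_tsv(fst$gst, file.path(d, "gst.tsv"))
    write_json_report(list(sigma = as.list(am$sigma),
                           percent = as.list(am$percent),
                           phi = as.list(am$phi),
                           p_value = as.list(am$p_value)),
                      file.path(d, "amova.json"))
    write.table(data.frame(individual = rownames(res$calls$calls),
                           population = pop,
                           round(pca$coordinates[, 1:4, drop = FALSE], 6)),
                file.path(d, "pca.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(net)) {
      write.table(net$edges, file.path(d, "migration_edges.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    res$diversity <- div; res$fst <- fst; res$amova <- am; res$pca <- pca
    res$network <- net
    record("stats", d)
  }

  if ("demography" %in% config$stages) {
    d <- stage_dir(config, "demography")
    pop <- pop_of_individual()
    total_sites <- config$n_loci * nchar(res$genome$loci[[1]])
    for (p in unique(pop)) {
      sfs <- folded_sfs(res$calls, pop, p, total_sites = total_sites)
      write.table(data.frame(minor_count = seq_along(sfs$bins),
                             n_sites = as.integer(sfs$bins)),
                  file.path(d, sprintf("sfs_%s.tsv", p)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (sum(sfs$bins) >= 50) {
        fit <- fit_stairway(sfs, mu = config$demography$mutation_rate,
                            generation_time = config$demography$generation_time,
                            n_boot = config$n_boot_stairway,
                            seed = config$stage_seeds[["demography"]])
        write.table(fit$trajectory, file.path(d, sprintf("stairway_%s.tsv", p)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        res$stairway[[p]] <- fit
      }
    }
    record("demography", d)
  }

  if ("seascape" %in% config$stages) {
    d <- stage_dir(config, "seascape")
    meta <- generate_lake_metadata(config$demography$n_lakes,
                                   seed = config$stage_seeds[["seascape"]],
                                   n_sea = config$demography$n_sea)
    meta$tidal_fraction[match(lakes, meta$code)] <- config$demography$connection
    meta$category[match(lakes, meta$code)] <-
      vapply(config$demography$connection, categorize_connection, character(1))
    keep <- meta$code %in% rownames(res$fst$fst)
    meta <- meta[keep, , drop = FALSE]
    meta <- meta[match(rownames(res$fst$fst), meta$code), , drop = FALSE]
    gen_d <- linearize_fst(res$fst$fst)
    geo_d <- geographic_distance_matrix(meta)
    env_d <- environment_distance_matrix(meta)
    con_d <- suppressWarnings(connection_distance_matrix(meta))
    mt <- list(
      geographic = mantel(gen_d, geo_d, n_perm = config$n_perm_mantel,
                          seed = config$stage_seeds[["seascape"]]),
      environment = mantel(gen_d, env_d, n_perm = config$n_perm_mantel,
                           seed = config$stage_seeds[["seascape"]]),
      connection = mantel(gen_d[rownames(con_d), rownames(con_d)], con_d,
                          n_perm = config$n_perm_mantel,
                          seed = config$stage_seeds[["seascape"]]))
    write.table(meta, file.path(d, "lake_metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_matrix_tsv(unclass(gen_d), file.path(d, "dist_genomic.tsv"))
    write_matrix_tsv(unclass(geo_d), file.path(d, "dist_geographic.tsv"))
    write_matrix_tsv(unclass(env_d), file.path(d, "dist_environment.tsv"))
    write_matrix_tsv(unclass(con_d), file.path(d, "dist_connection.tsv"))
    write_json_report(lapply(mt, function(x) list(r = x$r, p = x$p)),
                      file.path(d, "mantel.json"))
    res$mantel <- mt; res$metadata <- meta
    record("seascape", d)
  }

  res$manifest <- manifest
  res
}
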