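#!/usr/bin/env Rscript
# Step 5: demographic inference — folded SFS per population and
# stairway-style piecewise-constant Ne fits (mu = 1.1e-8 per site per
# generation, generation time 1 year, 12.5/87.5% bootstrap envelope), the
# lake populations carrying the founder-bottleneck signal.

suppressPackageStartupMessages(library(lakerad))
thin <- readRDS("results/03_genotype/calls.rds")
st <- readRDS("results/01_simulate/state.rds")
out <- "results/05_demography"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pop <- sub("_ind\\d+$", "", rownames(thin$calls))
total_sites <- 500 * nchar(st$genome$loci[[1]])

for (p in unique(pop)) {
  sfs <- folded_sfs(thin, pop, p, total_sites = total_sites)
  write.table(data.frame(minor_count = seq_along(sfs$bins),
                         n_sites = as.integer(sfs$bins)),
              file.path(out, sprintf("sfs_%s.tsv", p)), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (sum(sfs$bins) < 50) {
    cat(sprintf("%s: only %d segregating sites, skipping the fit\n",
                p, sum(sfs$bins)))
    next
  }
  fit <- suppressWarnings(
    fit_stairway(sfs, n_epochs = 4, mu = st$cfg$mutation_rate,
                 generation_time = st$cfg$generation_time, n_boot = 100,
                 seed = 5))
  write.table(fit$trajectory, file.path(out, sprintf("stairway_%s.tsv", p)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: S = %4d, recent Ne ~ %8.0f, ancestral Ne ~ %8.0f (true: lake %d, sea %d)\n",
              p, sum(sfs$bins), fit$model$Ne_per_epoch[1],
              tail(fit$model$Ne_per_epoch, 1), st$cfg$founder_size,
              st$cfg$ancestral_size))
}
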