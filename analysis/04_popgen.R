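#!/usr/bin/env Rscript
# Step 4: population structure and diversity of the simulated
# metapopulation — per-lake diversity (pi, He, Ho), pairwise normalised
# F'ST, nested AMOVA (sea vs lake grouping, 1000 permutations), covariance
# PCA, and the GST-based relative migration network (threshold 0.2).

suppressPackageStartupMessages(library(lakerad))
thin <- readRDS("results/03_genotype/calls.rds")
st <- readRDS("results/01_simulate/state.rds")
out <- "results/04_popgen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pop <- sub("_ind\\d+$", "", rownames(thin$calls))
total_sites <- 500 * nchar(st$genome$loci[[1]])

div <- diversity(thin, pop, total_sites = total_sites)
fst <- pairwise_fst(thin, pop, n_perm = 999, seed = 4)
grp <- ifelse(grepl("^Sea", pop), "sea", "lake")
am <- suppressWarnings(amova(thin, pop, grp, n_perm = 1000, seed = 4))
pca <- pca_covariance(thin)
net <- relative_migration_network(thin, pop, threshold = 0.2,
                                  n_boot = 1000, seed = 4)

write.table(div, file.path(out, "diversity.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_matrix_tsv(round(fst$fst, 4), file.path(out, "fst.tsv"))
write_matrix_tsv(round(fst$p_value, 4), file.path(out, "fst_pvalues.tsv"))
write_json_report(list(sigma = as.list(am$sigma),
                       percent = as.list(am$percent), phi = as.list(am$phi),
                       p_value = as.list(am$p_value)),
                  file.path(out, "amova.json"))
write.table(net$edges, file.path(out, "migration_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(individual = rownames(thin$calls), population = pop,
                       round(pca$coordinates[, 1:4], 5)),
            file.path(out, "pca.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Diversity per population:\n"); print(div, row.names = FALSE)
cat(sprintf("\nMean pairwise F'ST: %.2f (true Hudson FST from step 1: %.2f)\n",
            mean(fst$fst[upper.tri(fst$fst)], na.rm = TRUE),
            mean(st$sim$truth$fst[upper.tri(st$sim$truth$fst)])))
cat(sprintf("AMOVA: %.1f%% among groups, %.1f%% among populations, %.1f%% within (PhiST = %.2f, p = %.3f)\n",
            am$percent[1], am$percent[2], am$percent[3],
            am$phi["phi_st"], am$p_value["phi_st"]))
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance; %d migration edges >= 0.2\n",
            pca$percent_variance[1], pca$percent_variance[2],
            nrow(net$edges)))
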