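# lakerad

Population genomics of marine-lake sponges from ddRAD data.

Marine lakes — landlocked pockets of seawater connected to the adjacent sea
only through caves or porous rock — formed after the Last Glacial Maximum
(~8,000–10,000 years ago) and act as natural replicates of colonisation and
isolation. For the sponge *Suberites diversicolor*, which occurs in
Indo-Pacific marine lakes across 1–1,400 km, the question is what structures
its populations: geographic distance (isolation by distance), local
environment (temperature/salinity; isolation by environment), the
permeability of each lake's connection to the sea (isolation by
resistance), or founder events with subsequent drift and priority effects.

`lakerad` re-implements the complete analysis chain for that question as a
tested R package with an analysis workflow on top:

* **Synthetic data** (`simulate_metapopulation`, `generate_ddrad_reads`,
  `generate_lake_metadata`): a structured coalescent of a large sea source
  seeding bottlenecked lake populations at `founding_time`, migration scaled
  by each lake's tidal-amplitude fraction *c*, and barcoded 150 bp
  single-end ddRAD reads (SphI remnant `CATGC`, negative-binomial depth,
  per-base errors) with planted high-GC contaminant and low-complexity loci.
* **RAD assembly** (`assemble_loci` and its stages): demultiplexing (1
  barcode mismatch, cut-site required), trimming, greedy clustering with
  minimum support 3, DUST-style masking with a >60% N rule, a de novo
  reference from loci shared by ≥70% of individuals, a >55% GC contaminant
  screen plus optional k-mer screen, and unique gapless read assignment.
* **Genotyping** (`genotype_likelihoods`, `estimate_allele_frequencies`,
  `call_genotypes`, `filter_sites`, `thin_one_snp_per_locus`,
  `run_filter_grid`): symmetric-error genotype likelihoods, EM allele
  frequencies, 0.95-posterior calls, indel-window/depth-percentile/
  missingness filters, one random SNP per tag, and the {3×,10×} ×
  {30,10,5,1}% coverage-by-missingness sensitivity grid.
* **Population genomics** (`diversity`, `pairwise_fst`, `amova`,
  `pca_covariance`, `folded_sfs`, `relative_migration_network`): π, He, Ho;
  the normalised fixation index F′ST (Meirmans–Hedrick G″ST, with
  `F'ST/(1−F'ST)` linearisation); nested AMOVA with permutation tests;
  covariance PCA; folded site-frequency spectra; and the GST-based relative
  migration network (threshold 0.2, bootstrap support).
* **Demography** (`expected_sfs`, `fit_stairway`): exact expected SFS under
  piecewise-constant *Ne* via `E[ξ_i] = Σ_k k·E[T_k]·P(i|k)·μL`, and a
  stairway-style composite-likelihood fit (μ = 1.1 × 10⁻⁸ per site per
  generation, generation time 1 year, 12.5/87.5% bootstrap envelope).
* **Seascape tests** (`tidal_fraction`, `categorize_connection`, the
  distance-matrix builders, `mantel`, `spearman_diversity`,
  `summarize_profiles`): c = Lake_max/Sea_max with categories low (≤0.4),
  medium (0.5–0.7), high (0.8–1); haversine geographic distances;
  PCA-rotated environmental distances; a connection-resistance matrix
  `d(i,j) = ((1−c_i)+(1−c_j))/2`; Mantel tests with 10,000 permutations;
  and Spearman correlations (strong at |ρ| ≥ 0.5, α = 0.01).

The package ships the printed survey metadata of the eleven sampling sites
(nine marine lakes, two open lagoons) in
`inst/extdata/lake_profiles.tsv`, used by the seascape module.

## Worked example

```r
library(lakerad)

cfg <- demography_config(n_lakes = 2, n_sea = 1, seed = 5)
sim <- simulate_metapopulation(cfg, c(Sea01 = 4, Lake01 = 4, Lake02 = 4),
                               n_loci = 60)
genome <- synthetic_genome(60, n_contaminant = 4, n_repeat = 2, seed = 5)
rd  <- generate_ddrad_reads(genome, sim, depth_mean = 12, seed = 5)
cat_ <- assemble_loci(rd$reads, rd$barcodes)
cat_$report$contaminants_removed
#> gc_above_max
#>            4

gl    <- genotype_likelihoods(cat_$stacks, cat_$reference)
calls <- call_genotypes(gl, estimate_allele_frequencies(gl))
thin  <- thin_one_snp_per_locus(filter_sites(calls, NULL, genotyping_config()), 1)
pop   <- sub("_ind\\d+$", "", rownames(thin$calls))
round(pairwise_fst(thin, pop, n_perm = 49)$fst, 3)
#>        Lake01 Lake02 Sea01
#> Lake01  0.000  0.915 0.685
#> Lake02  0.915  0.000 0.428
#> Sea01   0.685  0.428 0.000
```

All four contaminant loci planted above 55% GC were removed by the screen,
and the two lakes — founded 9,000 generations ago at *Ne* = 500 with almost
no migration — are far more differentiated from each other (F′ST ≈ 0.92)
than either is from the sea source they were seeded from (F′ST 0.43–0.69),
the founder-bottleneck signature the workflow is built to detect.

The `analysis/` directory holds the numbered workflow
(`01_simulate.R` … `06_seascape.R`): each script is a thin narrative driver
over these functions that prints what it found and writes its tables under
`results/`.

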