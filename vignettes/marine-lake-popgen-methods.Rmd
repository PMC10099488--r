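---
title: "Methods: population genomics of marine-lake sponges from ddRAD data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of marine-lake sponges from ddRAD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakerad)
```

## The system and the questions

Marine lakes are landlocked bodies of seawater connected to the adjacent sea
only through caves or porous rock. They formed as sea levels rose after the
Last Glacial Maximum (roughly 8,000-10,000 years ago), so each lake is an
independently seeded replicate of the same colonisation experiment. For a
sessile, poorly dispersing benthic animal such as the sponge *Suberites
diversicolor*, three classical hypotheses compete to explain genetic
structure among lakes: isolation by geographic distance, isolation by
environment (temperature, salinity), and isolation by resistance — the
permeability of the connection to the sea, summarised by the tidal-amplitude
fraction `c` = (lake tidal range)/(sea tidal range). A fourth possibility is
that founder events and subsequent priority effects dominate, in which case
none of the three predictors explains the structure and every lake is
distinct simply because it was bottlenecked at colonisation and drifted.

`lakerad` implements the full analysis chain needed to pose these questions
to double-digest RAD (ddRAD) data — and, because the original sequence data
live in an external archive, a synthetic-data module that generates the
whole study design from scratch so that every downstream stage is testable
against a known truth.

## Synthetic data: what is emulated

`simulate_metapopulation()` runs a structured coalescent (time in
generations, backwards from the present) over one or more large sea source
populations and a set of small lake populations:

* each lake exists at its bottlenecked effective size (`founder_size`,
  default 500 diploids) from the present back to `founding_time` (default
  9,000 years; generation time 1 year), at which point all of its lineages
  relocate into the sea source — the founder event;
* backward migration from a lake into the sea occurs at
  `migration_rate_base * c`, the isolation-by-resistance hypothesis encoded
  as a simple multiplicative scaling (c = 1 for open sea);
* the sea source has `ancestral_size` (default 50,000) diploids, and
  multiple sea populations merge at the founding time so every genealogy
  reaches a common ancestor even with zero ongoing migration;
* mutations are dropped on branches under the infinite-sites model at
  `mutation_rate` per site per generation, default 1.1e-8 — the rate used
  for the sponge's 300 Mb genome throughout, with generation time 1 year.

`generate_ddrad_reads()` then emulates the library structure: each read is
`barcode + SphI remnant (CATGC) + locus prefix`, 150 bp single-end, with
independent per-base errors (default 0.5%) and negative-binomial
per-individual per-locus depth. The defaults (mean 24x, dispersion 2.5)
reproduce the empirical coverage profile of the study this package
re-implements: mean ~24x with a 1st-99th percentile span of roughly 2-75x,
matching the reported 3.1-82.2x range. The genome generator plants
contaminant loci strictly above 55% GC (emulating microbial symbiont
sequence) and low-complexity dinucleotide repeats, so the contaminant
screen and the masking stage each have a known right answer.

What the generator deliberately does not emulate: PCR duplicates,
paired-end structure, indel-rich loci (at most a single declared indel per
locus, to exercise the masking window), base-quality variation within reads,
and allele-specific amplification bias. Passing tests therefore demonstrate
correctness of the analysis chain under idealised-but-overdispersed
sequencing, not robustness to every real-library artefact.

## Assembly and filtering rules

The assembly follows the custom-pipeline order: demultiplex (one barcode
mismatch allowed; reads without the expected cut-site remnant directly after
the barcode are discarded), trim, cluster each individual's reads by greedy
centroid clustering, mask, build a shared reference, screen contaminants,
and assign reads uniquely. The thresholds are the study's: minimum cluster
support 3 reads; loci discarded if more than 60% N after masking; reference
built from loci shared by at least 70% of individuals (a plain fraction, so
7/10 passes); loci above 55% GC removed; only uniquely best-matching reads
kept (gapless, at most 5 mismatches, strictly better than the runner-up).

Choices the source pipeline left open, fixed here and configurable:

* greedy clustering identity threshold 0.90, with a deterministic
  abundance-then-lexicographic visiting order so results are invariant to
  input read order;
* cluster representative = per-column majority consensus, `N` on ties;
* the low-complexity stage is a DUST-style triplet-overrepresentation score
  (window 64, threshold 2.0, N-containing triplets ignored) standing in for
  a repeat-database masker, which would require taxon-specific libraries;
* read assignment is gapless; reads from indel-bearing haplotypes fail the
  mismatch cap and drop out, and indel neighbourhoods are masked downstream
  from declared indel positions (simulator truth or a user file).

## Genotype likelihoods and calling

Genotype likelihoods use the standard symmetric-error model: for read base
`b` and genotype `g` alt copies, `P(b|g) = (g/2) p_alt + (1-g/2) p_ref`,
`p_x = 1-eps` if `b = x` else `eps/3`, with fixed `eps = 0.01`. Only the
relative posteriors matter at the calling threshold, so the error parameter
is not re-estimated per run. Site nomination requires the pooled alt count
to reach `max(2, 0.5% of pooled depth)` — the proportional floor keeps
sequencing errors from nominating sites at deep coverage; sites with two
such non-reference alleles are dropped as multi-allelic. Allele frequencies
come from an EM fixed point of the likelihood-weighted Hardy-Weinberg model
(tolerance 1e-8, at most 100 iterations), using one global frequency per
site in the reference-panel-free spirit of likelihood-based callers. A
genotype is emitted only when its posterior (likelihood times HWE prior)
reaches 0.95 and the cell depth reaches the grid's minimum (3 or 10);
everything else is missing. Site filters: 10 bp around declared indels;
pooled site depth outside the nearest-rank 1st-99th percentiles; missing
fraction above the grid cap (30/10/5/1%). One random SNP per RAD tag is
retained, so the grid's SNP count equals the number of tags retaining a
polymorphic site — which makes the count provably non-increasing along both
grid axes.

## Differentiation, AMOVA, networks

The "normalised fixation index" is implemented as Meirmans & Hedrick's
G''ST computed pairwise (k = 2) from Nei & Chesser's small-sample-corrected
HS and HT, averaged over sites before forming ratios. Negative estimates
are clamped to zero (flagged); monomorphic pairs are `NA` (flagged).
Linearisation for distance-based tests is `F'ST/(1-F'ST)`.

AMOVA decomposes sums of squared Euclidean distances on 0/1/2 allele counts
(missing loci excluded pairwise, the sum rescaled to the full locus count)
with the standard unequal-sample-size coefficients; permutation schemes are
the conventional ones per level (individuals among populations; individuals
among populations within groups; whole populations among groups). Reported
components are truncated at zero, but the permutation p-values compare
untruncated statistics — truncation creates ties at zero that would make
null p-values non-uniform, and the suite checks calibration by KS test.

The relative migration network follows the hypothetical-migrant-pool
construction: for the ordered pair (A -> B), pool frequencies are the
unweighted mean of A and B; the directional estimate is Wright's
`Nm = (1/GST - 1)/4` between the *recipient* B and the pool (strong A -> B
flow leaves B resembling the pool); all directed values are divided by the
global maximum, edges below 0.2 are removed, and bootstrap over loci gives
per-edge support. The inner differentiation measure is plain Nei GST, per
the method's usual GST variant.

## Demographic inference from the folded SFS

`expected_sfs()` computes `E[xi_i] = sum_k k E[T_k] P(i|k) mu L` with
`P(i|k) = C(n-i-1, k-2)/C(n-1, k-1)` and `E[T_k]` obtained exactly by
epoch-wise integration of the lineage-count pure-death chain (matrix
exponentials of the bidiagonal generator; occupancy via
`A^{-1}(e^{A tau} - I)`). Under constant Ne this reproduces `theta/i` to
floating-point accuracy, which the suite asserts at 1e-6.

`fit_stairway()` maximises the multinomial (conditional-on-S) composite
likelihood of the folded bins over per-epoch Ne on the log scale, with
breakpoints fixed at geometric quantiles of the expected tree depth under a
constant-Ne Watterson pilot — recent epochs get the resolution because that
is where the SFS carries information. The multinomial constrains only the
spectrum *shape* (under constant Ne it is exactly scale-free), so the Ne
scale is set afterwards by matching the expected number of segregating
sites to the observed count; on exact constant-Ne input this recovers the
true Ne in every epoch to better than 1%. Folded spectra are used
throughout because de novo RAD loci have no ancestral-state information.
The default of 4 epochs reflects the identifiability limit of folded
spectra from 10-20 sampled alleles; the bootstrap envelope (site
resampling, or locus resampling when a per-locus bin matrix is supplied)
reports the 12.5/87.5 percentiles and is clamped to bracket the point
estimate. Known limitation: the most ancient epoch is weakly identified
and tends to overshoot; inference about the *drop* (recent vs ancient
ratio) is what the package's checks rely on, at the 5-fold level on
20-fold simulated bottlenecks.

## Seascape statistics

The tidal fraction is `max(lake)/max(sea)` on baseline-corrected
water-level series; categories are low (c <= 0.4), medium (0.5-0.7), high
(0.8-1), "open" for sea sites, with the scheme's (0.4, 0.5) gap assigned to
medium with a message. Geographic distances are haversine on a 6,371 km
sphere; environmental distances are Euclidean on all PCA axes of
standardised temperature and salinity (with all axes retained this equals
the z-score distance — the PCA is kept for parity with the published
workflow); the connection-resistance distance is
`d(i,j) = ((1-c_i) + (1-c_j))/2`, the mean isolation of the pair. The exact
equation of the original resistance matrix lives in prior work and is not
reproduced here; this documented stand-in honours the published ordering
contract (isolated-isolated pairs most distant, open-open pairs at zero,
mixed pairs strictly between, monotone in each partner's connection).
Lakes with no measured tidal fraction are excluded from the connection
matrix with a warning.

Mantel tests correlate upper-triangle entries under simultaneous
row/column permutation (one-sided, add-one estimator, 10,000 permutations
by default, explicit seed; an exact mode enumerates all permutations for
small systems). Spearman correlations of diversity against lake predictors
use tie-corrected ranks, flagging |rho| >= 0.5 as strong and p < 0.01 as
significant.

## Problem sizes and numerical choices

The package's end-to-end checks run on a "small" preset — 4 lakes + 1 sea
source, 500 host loci plus 10 contaminant and 5 low-complexity loci, 10
diploids per population, mean depth 24x — chosen as the smallest system
that exercises every filter with comfortable margins (sharing, support,
GC, depth grid). Statistical calibration uses 500 replicates at toy sizes;
oracle-equivalence checks use exact 1e-10 tolerances on toy inputs;
Monte-Carlo comparisons state their tolerance in standard errors computed
from the replicates themselves. Coalescent simulations are exact
(event-driven, no time discretisation); the only numerical tolerances in
the package are the EM fixed point (1e-8), the L-BFGS-B stairway fit
(bounded log-Ne, 300 iterations), and the matrix exponentials (Higham
scaling-and-squaring via the Matrix package).

## Known limitations

* Gapless assignment means indel polymorphism is handled by exclusion and
  masking, not by alignment; loci with common indels lose coverage.
* Nucleotide diversity computed from one-SNP-per-tag calls understates
  per-site diversity relative to estimators that use all sites; the
  package reports the estimator's inputs (`total_sites`, variable-site
  counts) so the two conventions can be reconciled.
* The migration network inherits the known caveats of the
  migrant-pool construction: it is relative, not absolute, and
  undifferentiated pairs saturate at the maximum.
* The stairway fit's ancient epochs are weakly constrained by folded
  spectra at small n; confidence envelopes there are wide and the
  package's own checks only rely on recent-vs-ancient contrasts.
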