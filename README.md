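# microdivr

Microdiversity, persistence and ecotype analysis of amplicon sequence
variants (ASVs) nested inside 97%-identity OTUs, built for
root-associated soil surveys sampled along the bulk soil (BS) → loosely
bound soil (LS) → tightly bound soil (TS, the rhizosphere) gradient.

Species-level OTUs hide fine-scale variation: the exact sequence
variants inside one OTU can prefer different soil compartments and
respond oppositely to soil chemistry — they behave as distinct
**ecotypes**.  `microdivr` quantifies that hidden variation and asks
whether it stabilises the OTU: are OTUs carrying several effective
variants more persistent and less volatile across samples than
single-variant OTUs?

The package is aimed at microbial ecologists working with denoised
amplicon data (an ASV table, representative sequences, a rooted
phylogeny, sample metadata) and provides the full analysis chain plus a
ground-truth synthetic-community generator for validating every stage.

## The core statistics

For an OTU whose member ASVs have pooled relative abundances
*q₁, …, q_k* (counts summed over all samples, normalised within the
OTU), **microdiversity** is the effective number of ASVs

> D = exp(−Σᵢ qᵢ ln qᵢ),

the Hill number of order 1, with 1 ≤ D ≤ k.  **Persistence** is the
fraction of samples with at least one read of the OTU (rarefied table);
**variability** is the coefficient of variation (sd/mean) of its
per-sample relative abundance.  A *persistent OTU* has
persistence > 0.75 and variability < 2 (strict).  Habitat preference of
each ASV is read from z-scores of its per-sample relative abundance
(positive where the compartment mean z exceeds 0), and ecotypes are
classed positive/negative by the sign of their significant
(BH-corrected Spearman) correlation with SOC, pH, NO₃⁻–N, NH₄⁺–N or TN.

Around these sit the standard machinery: OptiClust de-novo clustering at
97% identity (MCC-maximising single-sequence reassignment), rarefaction,
alpha diversity (Shannon, Chao1, Pielou, Simpson dominance, Faith PD),
unweighted UniFrac + PCoA at ASV and OTU level, ANOSIM / PERMANOVA /
Mantel / Procrustes permutation tests, SIMPER, Duncan multiple-range
letters and Wilcoxon rank-sum tests.

## A worked example

```r
library(microdivr)

sim <- simulate_community(paper_like_scenario(seed = 1))
cl  <- opticlust(pairwise_distance(sim$seqs),
                 abundance = colSums(sim$table))
cl
#> OptiClust partition: 94 sequences -> 50 OTUs at cutoff 0.03
#> pair-classification MCC = 1 (2 sweeps)

ar  <- rarefy(sim$table, 11000, seed = 1)
rec <- microdiversity_records(ar, cl)
rec
#> microdiversity records for 50 OTUs: 27 multi-ASV, 40 persistent
#>    otu_id n_asvs microdiversity persistence variability persistent ...
#> 1   OTU-1      1          1.000           1      1.3608       TRUE
#> 2   OTU-2      3          1.899           1      0.9236       TRUE
#> 3   OTU-3      4          2.867           1      0.6411       TRUE
#> ...

st <- stability_vs_microdiversity(rec, n_perm = 999, seed = 1)
st$persistence_test
#> Wilcoxon W = 887, p = 1.063e-05 (normal approximation)
st$variability_test
#> Wilcoxon W = 380, p = 1.016e-09 (normal approximation)
```

Reading the output: the clusterer recovered all 50 planted OTUs
perfectly (pair-classification MCC = 1).  Multi-ASV OTUs rank
significantly higher in persistence (one-sided Wilcoxon, p ≈ 1e-05) and
lower in variability (p ≈ 1e-09) than single-ASV OTUs, and
microdiversity correlates positively with persistence (Spearman
ρ ≈ 0.64, permutation p = 0.001) — the planted stability pattern.

`run_pipeline(pipeline_config(scenario = paper_like_scenario(seed = 1)))`
chains every stage (clustering → rarefaction → alpha/beta diversity →
ordination concordance → community tests → microdiversity → ecotypes)
into one machine-readable report; `inst/scripts/microdiv-pipeline.R` is
a thin command-line wrapper around it.

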