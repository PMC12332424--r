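# popconnect

Population structure and connectivity analysis for abyssal invertebrates
sampled across ocean basins, combining three independent data tracks in
one tested R pipeline:

1. **Mitochondrial mitotyping.** Deep-sea bivalves with doubly
   uniparental inheritance (DUI) carry two deeply diverged mitochondrial
   lineages — the maternally transmitted F-type and the paternally
   transmitted M-type — inside a single panmictic species. Naive
   barcoding then mistakes heteroplasmy for cryptic species. The package
   computes pairwise substitution counts and Kimura-2-parameter
   distances, `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with transition
   proportion `P` and transversion proportion `Q`, delimits mitotype
   clusters by single-linkage at a configurable K2P threshold (default
   0.05), transfers labels between markers (COI to 16S), and draws
   minimum-spanning haplotype networks with inferred intermediate
   haplotypes.
2. **Genome-wide SNP structure.** Starting from a biallelic VCF:
   missingness filters (individuals > 75%, loci > 20%), singleton and
   monomorphism removal, LD pruning (`r² > 0.2` within a 50-locus
   window), mode imputation, and admixture inference by sparse
   nonnegative matrix factorization `X ~ Q (2F)` with simplex-projected
   ancestry rows and masked cross-entropy model choice across K.
   Replicate runs are label-aligned, summarised with 95% CIs, and
   checked with Gelman–Rubin PSRF and effective-sample-size diagnostics.
   Differentiation uses Nei's standard distance and the Nei–Chesser
   sample-size-corrected G_ST (`1 - mean(Hs)/mean(Ht)`, ratio of
   averages), followed by Ward clustering and DAPC.
3. **MALDI-TOF proteomic fingerprinting.** Full spectral chain — mass
   trim to 2000–20000 m/z, square-root transform, Savitzky–Golay
   smoothing, SNIP baseline subtraction, TIC normalisation, SNR-8 peak
   detection, strict 0.002 relative-tolerance binning, noise-floor
   filtering, Hellinger transform — then hierarchical clustering,
   k-means/BIC group finding and random-forest classification with
   mean-decrease-accuracy peak ranking.

Synthetic-data generators with known truth (`simulate_heteroplasmic_sequences()`,
`simulate_admixed_genotypes()`, `simulate_spectra()`) emulate the
statistical structure of each track so the whole pipeline is testable
without downloads.

## Worked example

```r
library(popconnect)

# --- mitochondrial track on synthetic DUI sequences ---
sim <- simulate_heteroplasmic_sequences(n_specimens = 30, seed = 7)
d   <- k2p_matrix(sim$alignment)
mt  <- delimit_mitotypes(d, threshold = 0.05)
glance(mt)
#> # A tibble: 1 x 4
#>   n_specimens n_mitotypes largest threshold
#>         <int>       <int>   <int>     <dbl>
#> 1          30           2      19      0.05
mitotype_distance_summary(d, mt)
#> # A tibble: 3 x 6
#>   mitotype_a mitotype_b type        min    max label
#>   <chr>      <chr>      <chr>     <dbl>  <dbl> <chr>
#> 1 MT1        MT1        within  0.00653 0.0367 0.01-0.04
#> 2 MT2        MT1        between 0.246   0.283  0.25-0.28
#> 3 MT2        MT2        within  0.00817 0.0214 0.01-0.02
```

Two mitotypes emerge: within-lineage K2P distances stay below 0.04
while the F/M split sits at 0.25–0.28 — the heteroplasmy signature, not
two species.

```r
# --- SNP track: filters, admixture, differentiation ---
g   <- simulate_admixed_genotypes(n_individuals = 60, n_loci = 400,
                                  fst = 0.3, seed = 11)
X   <- impute_missing(prune_ld(filter_genotypes(g$genotypes)))
ens <- admixture_ensemble(X, K_range = 1:3, reps = 4, seed = 42)
glance(ens)
#> # A tibble: 3 x 6
#>       K  reps mean_cross_entropy sd_cross_entropy max_psrf  min_ess
#>   <int> <int>              <dbl>            <dbl>    <dbl>    <dbl>
#> 1     1     4              0.450           0.0308     1    2.40e 2
#> 2     2     4              0.427           0.0187     1.00 1.08e18
#> 3     3     4              0.445           0.0166     1.01 1.29e 3
recommend_k(ens)    # lowest masked cross-entropy: K = 2 (user decides)
autoplot(ens, K = 2)  # stacked ancestry bars
```

The masked cross-entropy dips at the planted K = 2; PSRF near 1 shows
replicate runs agree after label alignment.

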