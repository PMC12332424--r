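---
title: "Models and methods behind popconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popconnect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popconnect implements a three-track analysis of population structure for
deep-sea invertebrates: mitochondrial lineage typing, genome-wide SNP
admixture and differentiation, and MALDI-TOF proteomic fingerprinting.
This vignette explains the models, the parameters that matter, the
synthetic-data generators used for validation, and the design choices
made where the design was genuinely open.

## Mitochondrial track

### Distances

Pairwise distances between aligned sequences use pairwise deletion: any
site with `N` or a gap in either sequence of a pair is excluded, and the
per-pair effective site count is recorded. The Kimura-2-parameter
distance is

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q),$$

with $P$ and $Q$ the transition and transversion proportions over the
effective sites. When a logarithm argument is non-positive the pair is
saturated; it is flagged undefined and reported, never silently dropped.
By Jensen's inequality $d \ge P + Q$ on every defined pair, and
$d \to P + Q$ as divergence vanishes — both are asserted in the tests.

### Mitotype delimitation

Mitotypes — clusters of mitochondrial haplotypes separated by large
substitution gaps — are delimited by single-linkage clustering of the
K2P matrix cut at a threshold, default **0.05** on the defining marker
(COI). The default reflects the empirical gap structure of DUI bivalve
data: within-lineage diversity rarely exceeds K2P 0.04–0.05 while the
smallest between-lineage distances start near 0.06. Because the rule is
a plain threshold, borderline sub-lineages (rare single-specimen
haplotype groups) emerge naturally as small clusters; there is no
special-casing, and users studying them should vary the threshold.
Labels are assigned by descending cluster size (`MT1` largest), ties
broken by the lexically smallest member id, so the labelling is
deterministic and order-invariant.

Undefined distances are treated as above-threshold: a saturated pair is
never evidence that two sequences belong together.

### Haplotype networks

The network is a **minimum spanning network**: every edge that belongs
to at least one minimum spanning tree of the substitution-count graph is
retained (Kruskal over ascending weight classes with the cycle
property), so equal-weight alternative connections survive. An edge of
$k$ steps is expanded through $k-1$ inferred intermediate nodes — the
"missing haplotype" filled circles of classic network figures. The
statistical-parsimony connection limit of the TCS algorithm is *not*
implemented: cluster delimitation is already handled by the threshold
rule above, and for well-separated clusters the minimum spanning network
reproduces the same topology class.

## SNP track

### Filtering

Filters run in a fixed order — individuals with more than 75% missing
calls, then loci with more than 20% missingness among retained
individuals, then monomorphic loci, then singletons (minor allele
observed exactly once) — and every step logs removed/retained counts
that must reconcile with the input. LD pruning is a greedy scan in locus
order with a positional window (default 50 loci, $r^2 > 0.2$ drops the
later locus): RAD-style tags have no genome coordinates, so position in
the table is the only meaningful neighbourhood, and the greedy rule is
deterministic and idempotent. Imputation fills each missing call with
the per-locus modal dosage (ties to the lower dosage): deterministic and
auditable, deliberately *not* model-based so that the admixture model is
not fitted to its own extrapolations.

### Admixture model

The dosage matrix $X$ (individuals × loci, entries 0/1/2) is factorised
as $X \approx Q\,(2F)$ with ancestry rows $Q_i$ on the probability
simplex and ancestral frequencies $F \in [0,1]^{K \times L}$, by
alternating least squares: a clipped solve for $F$, a ridge solve for
$Q$ followed by exact Euclidean projection of each row onto the simplex
(the sort-based algorithm), until the relative loss change falls below
$10^{-6}$ or 500 sweeps.

**Ridge penalty `alpha` (default 1).** The penalty
$\alpha\lVert Q\rVert^2$ competes with the *differential* eigenvalue of
the locus-summed normal equations — the part of the signal that
distinguishes ancestries — which is small when differentiation is weak.
At a few thousand loci a heavy ridge (e.g. 10) visibly shrinks all
ancestries toward $1/K$ and biases per-individual estimates by
$\sim 0.2$; a mild ridge keeps the solves well-conditioned without
measurable bias, which is what the parameter-recovery tests require.
Users can raise it for very noisy data.

**Masked cross-entropy.** Before fitting, 5% of cells are hidden and
replaced by their locus mean; after fitting, the hidden cells are scored
with $-\mathrm{mean}\left[\frac{x}{2}\log\hat p + (1-\frac{x}{2})
\log(1-\hat p)\right]$, $\hat p = \mathrm{clamp}(QF, 10^{-6},
1-10^{-6})$. This out-of-sample criterion is reported as a full curve
across K; the package never auto-selects K — `recommend_k()` points at
the minimum but a flat curve (common under weak structure) is a finding,
not an error, and the final K is the analyst's call.

### Replicate ensembles and diagnostics

Per K, replicate runs from derived seeds are aligned to the lowest-loss
run by assignment matching on column correlations of $Q$ (exhaustive
over permutations for $K \le 8$, greedy with pairwise-swap refinement
beyond), undoing label switching. Summaries are per-individual means
with percentile 2.5/97.5% intervals across runs.

Two convergence-style diagnostics treat the runs as chains of
per-individual ancestries:

* **PSRF** is the pooled/within variance ratio
  $\sqrt{(W + (1+1/m)\,B/n)/W}$. The classic $(n-1)/n$ shrinkage term is
  deliberately omitted so that *identical chains give exactly 1*; large
  values still flag disagreement between replicate runs.
* **ESS** is the autocorrelation-based estimate
  $n/(1 + 2\sum\rho_k)$ with Geyer's initial-positive-sequence
  truncation on paired autocorrelations, summed over runs. On white
  noise it centres on the chain length with a chain-to-chain spread of
  roughly 10%; tests therefore check the centre, not single draws.

### Differentiation

Nei's standard distance
$D = -\ln\!\left(J_{xy}/\sqrt{J_x J_y}\right)$ accumulates gene
identities over both alleles of all loci typed in both members of a pair
(pairwise-complete by default; whether to use imputed data instead is a
user switch, since either convention is defensible). Pairwise $F_{ST}$
uses the Nei–Chesser sample-size-corrected gene diversities with
harmonic-mean sample size and the **ratio of averages**
$1 - \overline{H_S}/\overline{H_T}$ across loci, the standard multilocus
form for this estimator; small negative estimates are retained as
legitimate outcomes of the correction. Ward clustering ("ward.D" update
on the distance matrix as given) cut at three clusters feeds a DAPC:
PCA of centred dosages, LDA of the top 10 PC scores, two discriminant
axes — all three counts configurable.

## Proteomic track

The processing chain is fixed in order: trim to 2000–20000 m/z → square
root (variance stabilisation) → Savitzky–Golay smoothing (half-window 10
grid points, polynomial order 3 — the standard order for peak-shaped
signals; the half-window is interpreted in grid points) → SNIP baseline
with 15 clipping passes and window schedule $w = \min(i, 15)$ (the
simplest published schedule consistent with a 15-iteration budget; the
baseline is pointwise ≤ the signal by construction) → subtraction with
negative clipping → TIC normalisation. The per-spectrum noise level is
the scaled MAD (×1.4826) of the final corrected intensities, so the
SNR-8 peak threshold lives on the same scale as the spectrum it is
applied to.

Peaks are local maxima of a ±20-point window above 8× noise. Binning
pools all peaks, sorts by m/z and recursively bisects at the largest
relative gap until every bin is within 0.002 relative tolerance of its
mean *and* contains at most one peak per specimen (the strict rule);
the pass repeats until the bin count is stable, making the output a
fixed point of re-binning. The noise floor zeroes matrix cells below
1.75× the mean per-spectrum noise (a per-spectrum variant is available).
The Hellinger transform $h_{ij} = \sqrt{x_{ij}/\sum_j x_{ij}}$ gives
unit-sum-of-squares rows, so Euclidean distances on the transformed
matrix equal Hellinger distances on the raw proportions.

Group finding uses hierarchical clustering (complete linkage by default;
the choice is not critical for well-separated groups and is exposed) and
k-means over all PC scores with the BIC
$n\ln(\mathrm{WSS}_k/n) + k\ln n$. This BIC is the field's usual
k-means criterion but it is dimension-naive: on isotropic
low-dimensional data with many samples it oversplits, while in the
spectra-like regime (tens of specimens, many correlated features) it
behaves well — which is why the validation exercises it in that regime.
Classification uses a random forest (10000 trees, 22 variables per
split) with *unscaled* permutation importances (mean decrease in
out-of-bag accuracy), and the reported top peaks are those above an
importance cutoff of 0.0006, capped at 13.

## Synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* **Sequences.** One ancestral sequence is mutated under a uniform
  (Jukes–Cantor) substitution process into F- and M-type roots at a
  target K2P divergence (default 0.25, the scale of F/M divergence in
  DUI bivalves); each specimen adds star-shaped within-lineage variation
  (default pairwise 0.02) and emits F or M per a configured fraction
  (default 0.25, male-biased as DUI predicts). The `divergence`
  parameter targets the root-to-root distance; realised tip-to-tip
  divergence adds the two tip branches (~0.02), staying inside the
  ±0.03 realisation band. Uniform substitution is deliberate: K2P
  estimation remains valid, and lineage separability — not substitution
  bias — is what the downstream tests need.
* **Genotypes.** Balding–Nichols frequencies around Uniform(0.1, 0.9)
  ancestral values. The `fst` argument is calibrated to mean *measured*
  differentiation: $K$ sources drawn with Beta parameter $f$ have
  expected among-source $G_{ST}$ of $f(1-1/K)/(1-f/K)$, so the draw uses
  $f = K\,\mathrm{fst}/(K-1+\mathrm{fst})$. Without this inversion a
  nominal 0.10 would be estimated near 0.053 and every recovery check
  would be comparing different quantities. Admixed individuals (default
  30%) draw Beta(2,2) ancestry; unadmixed individuals split evenly
  between sources; basins are attached so ancestry is basin-structured
  (northern/southern/mixed). Missingness is injected completely at
  random, plus an optional high-missingness block to exercise the
  filters.
* **Spectra.** A shared set of 40 Gaussian peaks at log-spaced m/z with
  mass-proportional widths on a uniform 1-Da grid; 13 informative peaks
  are amplitude-scaled ×3 in group B — groups differ in relative
  intensity, never in peak presence. An exponentially decaying baseline,
  Gaussian detector noise, and per-replicate multiplicative and
  sub-tolerance mass jitter complete the model. The 3× shift is
  calibrated only to reproduce a qualitative two-group separation; no
  quantitative effect size is claimed for real data.

Every generator is a pure function of its seed (byte-identical outputs).

What the generators do *not* emulate: substitution-model heterogeneity
and saturation, real LD blocks and kinship, locus dropout that
correlates with genotype, isotope envelopes, mass-calibration drift
larger than the binning tolerance, and batch effects. Passing tests
therefore demonstrate algorithmic correctness and calibration under the
assumed models, not robustness to every artefact of field data.

## Validation scale and numerical choices

The test suite and the acceptance script run the tracks at: 100
specimens × 615 bp (mtDNA), 100 individuals × 1000–2000 loci with a
10-replicate K = 2 ensemble (SNP), and 120 specimens × 3 replicates ×
40 peaks (spectra) — sizes chosen to match the scale of a typical
abyssal sampling campaign while keeping a full validation run in the
minutes range. Smaller fixtures back the unit tests.

Numerical conventions: ties in mode imputation go to the lower dosage;
ties in peak plateaus go to the lower m/z; cluster labels order by size
then lexical member id; undefined distances propagate as flags, never as
silent drops; the simplex projection is exact, so ancestry rows sum to 1
to machine precision after every sweep.

## Known limitations

* The mitotype threshold is a single global cut; gradual divergence
  gradients (rather than clean gaps) will make it sensitive near the
  threshold, which is why the distance summary table reports the full
  within/between ranges.
* The NMF is a least-squares model of dosages, not a likelihood model of
  genotypes; its cross-entropy is a model-choice heuristic, and weakly
  structured data legitimately produce flat curves.
* PSRF/ESS applied to replicate optimisation runs measure run-to-run
  stability, not MCMC convergence in the strict sense.
* The strict binning rule can place two bins closer than the tolerance
  when a specimen yields twin peaks; this mirrors the strictness of the
  rule, and such twin bins are visible in the bin table.
* Random-forest importances on Hellinger-normalised rows spread signal
  across features (closure effect); ranking sharpness should be judged
  on the raw intensity matrix when that matters.
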