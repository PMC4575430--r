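---
title: "Dose-responsive signatures, connectivity mapping and pathway perturbation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-responsive signatures, connectivity mapping and pathway perturbation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosesig)
```

# The inference chain

`dosesig` implements the transcriptomic chain of evidence by which the
active component of a complex treatment (for instance a crude botanical
extract) can be identified from dose-response expression data alone:

1. **Preprocessing** turns probe-level intensities into a genes x doses
   matrix of log2 treated/vehicle ratios.
2. **Dose-pattern mining** finds the genes whose expression tracks dose
   monotonically, up or down, and attaches permutation-based
   significance to each candidate profile.
3. **Signature selection** reduces the response to ordered up- and
   down-tag lists by fold-change thresholds at the highest dose.
4. **Connectivity scoring** compares that signature against a compendium
   of rank-ordered reference treatments with a two-sided
   Kolmogorov–Smirnov statistic; compounds that mimic the query rise to
   the top, reversers sink to the bottom.
5. **Over-representation analysis**, **signed pathway activity** and
   **topology-aware pathway impact analysis** characterize what the up-
   and down-regulated programs do.
6. **Markov clustering** of a functional-interaction network decomposes
   the dose-responsive genes into coherent modules.

Every stage is exercised end to end on synthetic data with planted
ground truth, so the whole chain is testable without any external
database. The central biological motif being emulated is *reciprocal
regulation*: a dose-monotone down-regulated ("metabolism-like") block
and a dose-monotone up-regulated ("signaling-like") block on a null
background.

# Synthetic data: what is planted and what is not

`generate_dose_series()` draws a universe of `n_genes` genes and plants
two blocks: up-genes with expected log2 ratio `+effect_size * d` at dose
`d`, down-genes with the negated trend, null genes at 0, plus i.i.d.
Gaussian noise. The defaults (1000 genes, 3 doses beyond vehicle, 20 %
up / 30 % down, effect size 1, noise 0.1) mirror a three-dose design
with a strong transcriptional response; the 2:3 up:down ratio follows
the reciprocal structure described above (824 vs 1,093 genes at full
scale). Each generator takes an explicit seed and restores the caller's
RNG state, so identical configurations are bit-reproducible.

The simulator plants *pooled* single arrays per dose (one column per
dose), not replicate-level arrays, and generates values directly on the
log-ratio scale. A separate emitter, `generate_raw_intensities()`,
exponentiates the planted matrix into probe-level intensities with
duplicate spots, a vehicle channel, a local-background channel and a
deliberately low-signal probe fraction, purely to exercise the
preprocessing path. What is *not* emulated: dye effects, spatial
artifacts, probe-level feature extraction, batch structure, and any
dependence between genes beyond the planted blocks. Passing tests
therefore demonstrate algorithmic correctness and statistical
calibration on idealized inputs, not robustness to real-array
pathologies.

`generate_reference_compendium()` builds each mimic instance by sorting
`planted signature value + N(0, rank_noise_sd)`; at `rank_noise_sd = 0`
retrieval is perfect by construction and it degrades smoothly toward
random as the noise grows (0.25 by default, which still separates
mimics cleanly). Decoys are uniform permutations; an
`inversion_fraction` of the mimics is emitted sign-flipped to exercise
negative connectivity.

`generate_interaction_network()` carves each expression block into
sub-modules of about 30 genes connected at probability 0.9 inside a
module and 0.01 elsewhere. Modules never straddle the two reciprocal
blocks, so their members are co-expressed by construction — the
property the module filter later screens for.

# Preprocessing choices

* The background filter keeps probes whose signal is at least
  `factor x background` (default 1.4, inclusive) in **every** sample;
  the per-sample-vs-any-sample alternative is not configurable because
  the all-samples rule is the only deterministic reading.
* Quantile normalization (delegated to `limma::normalizeQuantiles`,
  ties averaged) equalizes the column distributions exactly. Note that
  this presumes most genes unchanged: if a large fraction of the
  transcriptome shifts with dose, normalization compresses genuine
  signal. The raw-intensity round-trip test therefore plants only 10 %
  responsive genes.
* Ratios use log base 2 and an intensity floor of 1.0 before division.
* Display clustering is UPGMA (`stats::hclust(method = "average")`),
  default distance 1 − Pearson correlation; constant rows are an error
  naming the offending genes. Tie-breaking follows `hclust`'s
  deterministic agglomeration order.

# Dose-pattern mining

Candidate profiles are all integer level sequences of length `n_doses`
starting implicitly at level 0 (vehicle) with per-step changes bounded
by `c`; the all-zero profile is excluded, giving `(2c+1)^n_doses - 1`
profiles. Genes are assigned to the profile with the highest Pearson
correlation computed over the *vehicle-anchored* vectors (a leading 0
prepended to both), which keeps constant-level profiles usable and
anchors the shape comparison at the control. Correlation is invariant
under positive rescaling of a profile, so exactly proportional profiles
tie; correlations are rounded to 10 decimals and ties break to the
lowest profile id, deterministically.

`c` defaults to 1. A larger bound enumerates many near-proportional
shapes (for three doses, (2,5,8) is nearly collinear with (1,2,3))
which compete for the same genes and dilute the per-profile counts
without adding distinguishable shapes; with `c = 1` the strictly
monotone full-range profiles still exist and planted blocks concentrate
on them.

Significance: each of `n_perm` (default 1000) permutations shuffles
every gene's dose labels independently and re-assigns all genes; `E` is
the mean permuted count per profile. Two statistics are reported. The
naive ratio `E/O` is informative but floor-limited: with `d` doses the
identity shuffle occurs with probability `1/d!`, so `E/O` can never
fall below about 1/6 at three doses no matter how strong the signal.
Profile *calls* therefore use the binomial tail `P(X >= O)` with
`X ~ Bin(n_genes, E/n_genes)` — the observed count against the
permutation expectation — adjusted by Benjamini–Hochberg across
profiles and thresholded at 0.001 by default. Significant profiles pool
by the sign of their final level into the up and down patterns.

Tag signatures take genes with linear ratio strictly above `fold_up`
(default 4) or strictly below `fold_down` (default 0.25) at the highest
dose — the dose with maximal signal — ordered by |log ratio|.

# Connectivity scoring

For a tag list at ascending ranks `V(1..t)` in a universe of `n`, the
enrichment score is `a = max_j (j/t − V(j)/n)` if `a > b`, else `−b`
with `b = max_j (V(j)/n − (j−1)/t)`: the signed maximal deviation of
the tag distribution from uniformity. The raw connectivity score is 0
when the up- and down-tag enrichments share a sign (an incoherent
match) and `ES_up − ES_down` otherwise; positive scores are scaled by
the compendium's maximum positive score, negative by the maximum
|negative|, so results span exactly [−1, 1] whenever both signs occur.

Permutation p-values draw `n_perm` random disjoint tag sets of the
query's sizes uniformly from the universe and compare |s|. Because the
null tags are uniform, the null distribution depends only on `(n,
t_up, t_down)` — not on which permutation an instance carries — so one
null sample serves the whole query. A discrete antisymmetry detail:
reversing a ranking maps `a` to `b − 1/n` and `b` to `a + 1/n`, so
reversal negates the score only up to one rank-grid step; the tests
assert this exact relation rather than naive negation.

# Enrichment

The "modified Fisher's exact" test is implemented as the EASE score:
the hypergeometric upper tail with the overlap decremented by one,
which penalizes single-gene overlaps (plain Fisher is selectable).
The background defaults to the measured universe, not the genome.
Benjamini–Hochberg adjustment is `stats::p.adjust`; tests cross-check
it against an explicit step-up construction. Per-module enrichment
applies the same test within each module's own BH family — a node-set
stand-in for edge-based network-ontology statistics.

# Pathway activity

Activity of pathway `P` in sample `s` is
`A_P(s) = (1/|P∩measured|) Σ_g w_g x_g(s)` with `w_g = −1` for
repressors, so repression accumulates instead of cancelling. Repressor
labels derive from the pathway topology (a gene whose outgoing edges
are majority-repressive gets −1), with explicit overrides possible.
Significance permutes the matrix's gene labels `n_perm` times; the
per-pathway statistic is the per-profile maximum of |A| across samples
(one decision per pathway, not per sample), with the add-one estimator
`(k+1)/(n_perm+1)` and BH across pathways.

# Pathway impact analysis

Each topology is a signed directed graph; the propagation matrix is
`B[v,u] = sign(u→v)/N_ds(u)` and the perturbation factors solve
`PF = ΔE + B·PF`. Net accumulation is `Acc = PF − ΔE`, totalled as
`tA`. Because `tA` is linear in `ΔE` (`tA = 1'(M⁻¹−I)ΔE`), the
bootstrap reuses the solved coefficients: each of `n_boot` (default
3000) replicates re-assigns the pathway's DE count of log fold-changes
(resampled from the DE pool) to random pathway genes; the evidence is
the two-sided, median-centered tail probability. Over-representation
evidence is the plain hypergeometric tail, and the two combine as
`P_G = c − c·ln c` with `c = P_NDE·P_PERT` (Fisher's product for two
uniforms), BH-adjusted across pathways and flagged at 0.01/0.05. A
near-singular system (`rcond < 1e−10`) is an error at solve time; the
random-topology generator redraws and, as a last resort, damps edge
weights by 0.99 with a warning. The DE input to the full run is the
union of the merged dose patterns with the highest-dose log2 ratio as
`ΔE`.

# Network modules

The Markov clustering loop operates on the column-stochastic adjacency
with unit self-loops: expand (matrix power 2), inflate (elementwise
power, default 5.0, then column normalization), prune entries below
`prune_threshold` (default 1e−5) *after* normalization so the
threshold is a column fraction and uniform attractor columns are never
emptied, until the maximum entry change falls below 1e−8. Clusters are
the connected components of the converged non-zero structure, which
for doubly idempotent limits coincides with the attractor-row reading;
nodes attracted by overlapping supports follow their largest-mass
attractor.

Inflation controls granularity. At 5.0 the clustering is deliberately
fine: clean cliques and disconnected components are recovered exactly,
but looser planted blocks (within-block density 0.8) typically shatter
into pure fragments — a property of the algorithm, reproduced
identically by an independently written reference implementation, and
the reason the planted interaction network uses dense (0.9) modules.
Clusters never merge across connected components, and at high
inflation fragments refine the planted blocks without straddling them.

Modules are retained when they have at least `min_size = 7` members
(inclusive) and mean *pairwise* Pearson correlation of dose profiles at
least `min_corr = 0.8` (pairwise, not gene-to-centroid, is the fixed
reading); with three-point profiles this correlation is fragile, so
constant-profile members contribute only non-degenerate pairs and are
reported. Survivors are renumbered 0..m−1 by decreasing size.

# Orchestration and problem sizes

`run_pipeline()` simulates every input from one seed (per-stage
sub-seeds are derived from it), runs the seven analysis stages in
order — patterns, tags, connectivity, enrichment, activity, impact
analysis, modules — writes each output as TSV in a write-once run
directory, and records a JSON manifest with parameters, seed, input
checksums and per-stage record counts; identical configurations yield
byte-identical manifests. There is no shell entry point: the package
functions and this vignette are the interface, and
`scripts/acceptance.R` is a worked orchestration example.

The default study scale — 1000 genes, 3 doses, a 50-instance
compendium with 10 mimics (20 % inverted), 30 gene sets (3 enriched per
direction), 10 twenty-gene topologies with one planted activation
cascade on the up block, 1000 permutations for pattern/activity/
connectivity significance and 3000 bootstraps for the impact analysis —
runs in well under a minute and is the size the tests and the
acceptance script use throughout.

# Known limitations

* Per-gene dose vectors are short (3 points by default); all
  correlation-based steps (profile assignment, module coherence) are
  correspondingly coarse.
* The permutation FDR floor discussed above means the naive `E/O`
  ratio is descriptive only; calls rest on the binomial tail.
* Quantile normalization distorts planted signal when the responsive
  fraction is large; the analysis path is calibrated for log-ratio
  input, with the raw-intensity path provided for completeness.
* The compendium model plants a single shared signature; real
  reference collections contain correlated families of compounds,
  batch structure and dose/cell-line heterogeneity that the retrieval
  tests do not probe.
* Per-compound aggregation of instances is a best-instance roll-up,
  documented as an approximation of service-side enrichment
  aggregation.
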