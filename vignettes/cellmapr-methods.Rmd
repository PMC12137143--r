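---
title: "Building multiscale cell maps from multimodal protein data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building multiscale cell maps from multimodal protein data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmapr)
```

## The problem

Subcellular organisation spans four orders of magnitude, from heterodimers
of a few nanometres to organelles of micrometres. Two proteome-scale
measurements see different slices of this organisation: affinity
purification–mass spectrometry (AP–MS) captures direct biophysical
interactions, while immunofluorescence (IF) confocal imaging captures
spatial co-distribution. `cellmapr` fuses the two into a single hierarchy
of protein assemblies — complexes, condensates, compartments — and attaches
the statistics used to validate and interpret such a map.

The package operates on precomputed per-protein feature vectors. For the
interaction modality it authored its own biased-random-walk embedding
(`embed_network()`): second-order walks with return parameter p = 2 and
in–out parameter q = 1, walk length 80 and 10 walks per node, followed by
skip-gram with negative sampling (window 10, 5 negatives, 5 epochs, the
cited embedding method's published defaults — the source description does
not fix the skip-gram end, so these are package choices exposed as
arguments). Image features are consumed as a numeric table (in the original
setting, 1,024-dimensional convolutional-network descriptors of confocal
images; replicate images of a protein are averaged).

## The multimodal co-embedding

Each modality is encoded by a branch of
dropout → linear → batch-norm → ELU → dropout → linear → batch-norm → tanh,
giving bounded 128-d vectors $a_i$ (interactions) and $b_i$ (images). A
joint encoder (dropout → linear → batch-norm → L2-normalisation over the
concatenation) produces the unit-norm joint embedding $z_i$. Decoding goes
through latent read-outs $c_i = w_x z_i$, $d_i = w_y z_i$ and three-layer
decoders (linear, ELU, linear, tanh, linear) back to the input spaces.

Training minimises

$$L = R + \lambda_{\mathrm{triplet}} (T_x + T_y), \qquad
R = \tfrac1n\sum_i \lVert x_i-\hat x_i\rVert^2
  + \tfrac1n\sum_i \lVert y_i-\hat y_i\rVert^2
  + \lambda_{\mathrm{reg}} (\lVert w_x\rVert_F + \lVert w_y\rVert_F),$$

with a cluster-driven triplet loss per modality: with $S(i,j)=1$ when
Louvain clustering puts $i,j$ in the same cluster,

$$T = \frac1m \sum_{i}\sum_{j\ne i}\sum_{k\ne i,j}
  S(i,j)\,(1-S(i,k))\,\max\!\big(D(z_i,z_j)-D(z_i,z_k)+\epsilon,\,0\big),$$

where $D$ is cosine distance and $m$ counts the strictly positive hinge
terms ($T=0$ when $m=0$). Defaults: $\epsilon = 0.10$, dropout 0.25,
$\lambda_{\mathrm{reg}} = \lambda_{\mathrm{triplet}} = 5$, batch 64, Adam
at $10^{-4}$, and a three-phase schedule — 200 epochs of $R$ only, 200
epochs of $L$ with clusters from the raw inputs, then 500 epochs with
clusters from the branch outputs $(a, b)$, refreshed every 200 epochs.

Design choices the architecture description leaves open, decided here:

* **Hidden widths** — branch encoders 1024→512→128 and decoders
  128→512→512→1024 (`coembed_config()` exposes both).
* **Triplet scope** — the printed sum ranges over all protein triples,
  which is infeasible; it is evaluated within each minibatch using the
  current global cluster labels, the standard minibatch treatment, with
  $m$ counted per batch. The formula itself is unchanged.
* **Cluster graph** — Louvain runs on a cosine k-nearest-neighbour graph
  (k = 15, negative similarities dropped); the source text clusters
  "vectors" without fixing a graph construction.
* **Phase-3 refreshes** — labels recomputed at the start of phase 3 and
  every `cluster_refresh_epochs` thereafter ("updated every 200 epochs"
  admits two readings; this one is configurable).
* **Emission** — final embeddings are computed in evaluation mode
  (dropout off, frozen batch-norm statistics), so they are deterministic
  given the trained weights.

The network is implemented with explicit forward and backward passes in
base R matrix code (single-threaded, seed-deterministic), with Adam and
per-layer batch-norm running statistics; the skip-gram inner loop of the
walk embedding is C++ for speed with its own deterministic generator.

## From embedding to map

Pairwise cosine similarities (dot products of unit-norm rows) are
thresholded into ten nested proximity networks keeping the top 0.2, 0.3,
0.4, 0.5, 1, 2, 3, 4, 5 and 10% of pairs (`round(f·P)` with banker's
rounding, minimum one edge, ties broken by lexicographic pair id so the
networks are reproducible). In each network, modularity communities are
detected across a log-spaced resolution grid (40 points, 0.01 to
maxres = 80) and kept when they recur — Jaccard ≥ 0.75 to a running
representative — at ≥ 10 grid points (persistence). The representative is
the member set at the median resolution of its run. How the published
pan-resolution tool merges its per-network results is not described;
here representatives are pooled across the ten networks, deduplicated at
Jaccard ≥ 0.9 keeping the most persistent, and assembled once into a
single DAG: a root equal to the universe, containment edges (child →
minimal strictly-larger parents with containment index ≥ 75%, transitive
edges removed), and children with Jaccard ≥ 90% to a parent merged into
it. Because parents are strictly larger, the graph is acyclic by
construction; the invariants are still asserted in tests. Minimum assembly
size is 3, matching the smallest assemblies such maps discuss.

Physical sizes come from ordinary least squares of log10 diameter (nm) on
log10 protein count over a user-supplied calibration table of assemblies
with literature-documented diameters; `predict_diameter()` attaches the
textbook prediction interval
$\hat y \pm t_{1-\alpha/2,\,n-2}\, s_e \sqrt{1 + 1/n + (x-\bar x)^2/S_{xx}}$
back-transformed to nanometres. The calibration table is input data, not a
constant of the package.

## Validation statistics

* **Jackknife robustness** — drop 10% of proteins, rerun embedding +
  detection with identical parameters, and ask whether each original
  assembly has a match (Jaccard ≥ 40% and BH-adjusted hypergeometric
  p < 0.001, universe = the jackknifed map's proteins, since dropped
  proteins cannot contribute overlap). Robustness is the matched fraction
  over resamplings; modality dependence replaces one modality's features
  with standard-normal vectors first.
* **SEC–MS co-elution** — pairwise Pearson correlations of elution
  profiles, averaged over the replicates in which both proteins are
  detected (proteins must appear in ≥ 2 replicates; zero-variance
  profiles skip that replicate for the pair). Each assembly's
  within-assembly similarities are compared to root-only pairs (proteins
  sharing no assembly below the root) by a one-sided rank-sum test, BH
  across assemblies, validated at FDR < 5%. "Unexpected" members —
  absent from an assembly's best-matching reference components — are
  tested individually the same way for assemblies under 50 proteins. The
  quadratic null is subsampled (default cap 10^6 pairs, seeded).
* **Annotation** — hypergeometric overlap of each assembly with each
  component of reference catalogs (GMT), BH within catalog, records kept
  at Jaccard ≥ 10% and FDR < 1%; categories from the best Jaccard:
  ≥ 50% high overlap, 20–50% substantial variation, otherwise novel.
* **Condensate-style flags** — per-protein booleans (disorder: a run of
  more than 30 residues each above 50% disorder probability;
  phase-separation propensity above 60%; curated membership), tested per
  assembly by uncorrected hypergeometric p < 0.01, candidate if
  significant for any flag.
* **Conservation** — within-assembly cosine similarities computed in two
  cell lines' interaction-feature spaces, compared two-sidedly and
  summarised by Cliff's delta (≥ 0.5 called line-specific; negative
  values floored at 0 for display only).
* **Structure pairs** — per pair, the median over five models of
  0.8·ipTM + 0.2·pTM; the empirical FDR at threshold s is
  (fraction of null non-co-assembly pair scores ≥ s)/(fraction of
  observed ≥ s), capped at 1 — the source states only that a null
  distribution "was used to calculate an FDR", so this standard
  estimator is the package's decision. Interface-confidence flags
  (any residue within 10 Å of the partner with per-residue confidence
  > 80, from the top-ranked model) are consumed, not computed.
* **Mutation convergence** — per-gene corrected load
  $M_g=\log_2(\max(N_{g,\mathrm{obs}}-N_{g,\mathrm{exp}},0)+1)$ with
  cohort-proportional scaling of the expected counts; lasso regression of
  $M$ on assembly-indicator columns plus per-gene singleton columns
  (so single-gene signal is not credited to assemblies); an assembly's
  selection score is the largest penalty at which its coefficient enters
  the path (50 log-spaced penalties from the first-entry penalty down to
  10^-3 of it). Significance by permutation of gene labels —
  $p = (1+\#\{\text{perm} \ge \text{obs}\})/(n_{\mathrm{perm}}+1)$,
  per-assembly by default with a pooled option — BH, selection at FDR
  ≤ 0.4. The lasso path is solved by glmnet with `intercept = FALSE`,
  `standardize = FALSE`, which makes the first-entry penalty exactly
  $\max_j |x_j^\top y|/n$ and lets tests verify it against an independent
  coordinate-descent oracle; the load is non-negative and mostly zero, so
  an intercept would be ≈ 0 anyway. Driver validation fits Gaussian
  kernel densities (Scott's rule) to mutagenesis-screen counts of
  putative drivers versus other map genes and reports
  FDR(x) = AreaFP/(AreaFP + AreaTP) from trapezoidal tail areas —
  unweighted by class prevalence, the literal reading of the formula,
  with a weighted option.

## The synthetic-data generator

`make_synthetic_bundle()` plants one ground truth — a balanced hierarchy
whose leaves partition the protein universe (an `overlap` switch
duplicates a fraction of proteins into a second leaf to exercise
multi-localization) — and emulates every modality from it: a
stochastic-block interaction network (within-leaf edge probability 0.8,
background 0.01, 30% baits), Gaussian hierarchical image features,
Gaussian elution peaks shared within leaves (40 fractions, 3 replicates,
peak width 1.5 fractions, per-replicate jitter 0.5), per-gene Bernoulli
mutations (base rate 0.005 per patient, selected assemblies at a
multiplier), and corrupted reference catalogs with controlled Jaccard.
Expected mutation counts are emitted exactly (`n_patients × base_rate`);
the background mutation model is consumed as input in the real pipeline
too, so no background estimation is emulated.

Two deliberate departures from realism: feature dimension defaults to 256
rather than 1,024 — the planted covariance structure has intrinsic
dimension equal to the number of hierarchy levels, so added dimensions
contribute only isotropic noise and nothing to the geometry (`dim = 1024`
remains available) — and noise is isotropic Gaussian with no
missing-not-at-random structure, batch effects, or intensity-dependent
variance. Passing the recovery tests therefore demonstrates correctness
of the machinery on data whose signal matches the model's assumptions; it
does not certify performance on real AP–MS/IF data, where feature
distributions are heavier-tailed and modality disagreement is informative
rather than noise.

All generators draw from per-operation seeded streams derived from one
bundle seed by fixed offsets, so adding a component never perturbs the
others and identical seeds give byte-identical artifacts.

## Problem sizes and numerical choices

The bundled end-to-end checks run the full pipeline on 300 proteins in 20
leaves under 4 compartments with a reduced 50/50/100-epoch schedule and a
256-d embedding of the simulated network — large enough that community
detection faces ~45,000 pairs and small enough for routine reruns; the
paper-scale schedule (200/200/500 at 1,024 dimensions) is the package
default for real data. Rank-test calibration is checked on 200 random
five-protein assemblies over 300 proteins with structure-free profiles
(random per-protein peaks), where assembly pairs cover a minority of pair
space so the raw one-sided test's size can be read from the rejection
rate; mutation recovery uses 50 assemblies of 10 genes, 3 planted at 8×
the base rate in 200 patients, 1,000 permutations.

Degenerate inputs are handled explicitly: all-identical vectors cluster
into one community; zero-variance elution profiles skip that replicate;
assemblies with fewer than two covered proteins are untestable and leave
the BH family; all-true or all-false flags give p = 1; an all-zero
mutation load short-circuits to scores 0, p = 1. Coefficients below 1e-7
on the lasso path are treated as zero (boundary-penalty numerical noise).
Ties in the similarity ranking are broken lexicographically; banker's
rounding sets threshold-network edge counts.

## Known limitations

* Equivalence with the published pan-resolution detection tool is
  structural, not bit-identical: its cross-network merging and
  persistence bookkeeping are unpublished, so only the stated parameters
  (persistence 10, maxres 80, containment 75%, redundancy 90%) are
  matched.
* The walk-embedding and autoencoder are deterministic only
  single-threaded; a multi-threaded BLAS may reorder reductions.
* Louvain/Leiden community labels depend on igraph's RNG; determinism is
  guaranteed under a fixed seed and igraph version.
* The triplet loss treats cluster labels as fixed within a phase;
  no gradient flows through the clustering.
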