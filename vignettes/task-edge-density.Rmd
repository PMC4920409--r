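---
title: "Task-related edge density: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-related edge density: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Block-design task fMRI experiments repeat short stimulation trials of two
conditions, A and B. Classical voxel-wise activation analysis asks where the
BOLD amplitude differs between conditions; it cannot see a *network* effect in
which two remote voxels start to fluctuate in lockstep when the task demands
it. `tedfmri` detects such task-related network formation at full voxel
resolution: it scores every voxel pair (every *edge*) for a condition
difference in trial-locked synchronisation, and then asks whether
high-scoring edges arrive in spatially dense packs.

The method needs no haemodynamic response model and no parcellation; its null
distribution comes from permuting the task labels of whole trials, so the
spatial correlation structure of fMRI noise is preserved under the null.

## The statistic, step by step

**Trial assembly.** Each run is drift-corrected by regressing out a basis of
slow signals — a constant, a linear trend, and all discrete-cosine functions
with frequency below the cutoff (default 1/90 Hz). We include the linear term
explicitly because a scanner drift ramp has slowly decaying projections on
*all* cosine terms; with the ramp in the basis the projection is exact and the
operation remains idempotent. The run is then cut into K trials of T volumes
per condition, and each (voxel, trial) series is normalised to mean 0, sd 1
(divisor T-1), so amplitude and offset differences between trials do not
masquerade as synchronisation.

**Effect-size series.** For voxel i and within-trial time t,

  mu_i(t) = mean over trials,  sigma_i(t) = sd over trials (divisor K-1),
  s_i(t) = mu_i(t) / sigma_i(t).

The division by the across-trial sd is the heart of the method: a voxel whose
response flips or jitters across trials has a large sigma and a flat s, even
if each single trial correlates beautifully with some other voxel. Cells with
sigma = 0 get s = 0 and are flagged; a voxel with no inter-trial variance
carries no evidence of task-locked behaviour.

**Synchronisation and differential synchronisation.** For each pair (i, j),
r is the Pearson correlation of s_i and s_j over within-trial time, and

  theta_{i,j} = atanh(r) for r > 0, else 0;   z_{i,j} = theta^A - theta^B.

Negative correlations are clamped to zero on purpose: a pair that is strongly
*anti*-correlated in B but silent in A would otherwise produce a large
positive z and read as task-positive coupling in A. r is clamped at 1 - 1e-7
because the Fisher transform diverges at 1. Pairs with a constant effect
series get theta = 0 (no evidence, not infinite evidence).

**Rank-Gaussianisation.** The z triangle is remapped onto exact normal
scores: the value of ascending rank r (average ranks for ties) becomes
`qnorm((r - 0.5)/N)`. Global confounds (arousal, motion, respiration) distort
the marginal distribution of z but largely spare the *ranking*; the transform
discards the former and keeps the latter. Because the same transform is
re-applied inside every permutation replicate, null and observed triangles
have identical marginals by construction — any difference that remains is
spatial arrangement, which is exactly what the next step measures. A fixed
retained fraction (top 1%) then corresponds to the fixed threshold
z_t = qnorm(0.99) = 2.33.

**Local edge density.** For a suprathreshold edge (i, j) whose endpoints are
at least 15 mm apart, take the closed 26-neighbourhoods N[i] and N[j]
(27 voxels each in the interior) and count suprathreshold pairs crossing
between them:

  D_e = #{(p, q) : p in N[i], q in N[j], z_{p,q} > z_t} / (|N[i]| |N[j]|).

The edge itself crosses, so a lone suprathreshold edge has D_e = 1/729 on
full neighbourhoods. At mask boundaries the denominator is the product of the
actual in-mask neighbourhood sizes, so D_e stays a fraction in [0, 1] rather
than being systematically deflated at the brain edge. The 15 mm rule (with
3 mm voxels) keeps the neighbourhoods disjoint with at least three voxels of
clearance; crossing pairs are counted regardless of their own length, because
the distance rule selects which edges *get* a density, not which pairs count.

**Inference.** The null is built by swapping the A/B labels of each trial
with probability 1/2 (one Bernoulli vector per run per replicate, the same
vector for all voxels) and re-running the entire statistic pipeline,
including the Gaussianisation. Pooled null densities give F0, the observed
densities give Fz, both as cumulative histogram counts on a grid of 1,000
bins on [0, 1] (bin width 0.001 resolves every attainable density, since
denominators are at most 729). The empirical false-discovery rate is

  Fdr(c) = pi0 (1 - F0(c)) / (1 - Fz(c)),  with pi0 = 1,

clamped to [0, 1], with the last finite value carried into an exhausted
observed tail. The significance cutoff is the smallest grid value with
Fdr < alpha; edges above it are declared significant. Sub-threshold edges
(D_e defined as 0) are excluded from both cdfs: the rank normalisation fixes
the suprathreshold count per replicate, so the comparison is fair, and the
shared point mass at zero would only dilute both distributions identically.

**Outputs.** Significant edges are projected onto a hubness map (per voxel,
the number of significant edges ending there; the total is twice the edge
count), exportable as NIfTI together with a TSV edge table and a JSON
manifest recording every parameter and seed. Reverse contrasts (B-A) re-run
the pipeline with the condition roles swapped rather than negating z, which
would break the positive-correlation clamp.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `top_fraction` | 0.01 | fraction of edges above the initial threshold; implies z_t = 2.33 |
| `min_distance_mm` | 15 | short-edge exclusion; keeps neighbourhoods disjoint |
| `adjacency` | 26 | neighbourhood scheme (6/18/26); results are fairly insensitive |
| `highpass_hz` | 1/90 | drift cutoff in Hz; must be below Nyquist |
| `permutations` | 1000 | null replicates; ~100 already give a stable cutoff at scale |
| `alpha` | 0.05 | Fdr level for the significance cutoff |
| `pi0` | 1 | prior null probability; 1 is the conservative choice |

The initial threshold is the influential one: more permissive thresholds
admit more (weaker) edges into the density computation. The adjacency scheme
mostly rescales denominators.

## What the generator emulates — and what it does not

`simulation_spec()` builds a full-mask lattice (default 10x10x10 voxels of
3 mm, K = 20 trials of T = 16 volumes at TR 0.72 s, matching a typical
fast-TR block design) with unit Gaussian noise. Clusters of voxels respond
with a boxcar convolved with a canonical double-gamma shape, amplitude `a`
(so `a/noise_sd` is the per-sample effect size; default 2), and per-trial
sign `g_k = +1` with probability `(1 + c)/2`. Consistency `c = 1` gives
trial-locked responses; `c = 0` flips signs at random, leaving each single
trial's correlation structure intact while destroying inter-trial
consistency — the scenario that separates this statistic from plain
correlation differences. Sign flips are shared by clusters of the same
condition so that cross-cluster per-trial correlations stay matched across
consistency levels. `amplitude = 0` yields exchangeable null data. The two
default clusters are 3x3x3 blocks 15 mm apart, so all 729 cross-cluster
pairs are legitimate long-range edges.

The generator does **not** emulate physiological drift spectra, spatial
autocorrelation of the noise, motion artefacts, or inter-subject variability.
A green test therefore establishes correctness of the algorithm and its
calibration under exchangeability — not robustness to every real-world
confound the normalisation step is designed to absorb.

## Numerical choices and edge cases

- Correlation clamp 1e-7 before the Fisher transform; identical series map to
  atanh(1 - 1e-7), about 8.41, rather than infinity.
- Undefined correlations (constant series) give theta = 0.
- Ties in the Gaussianisation get average ranks, keeping the map
  order-invariant and deterministic.
- The threshold comparison is strict (`z > z_t`), and the 15 mm rule excludes
  only distances strictly below 15 mm.
- `D_e` uses mask-truncated denominators; overlapping neighbourhoods are an
  error, not a silent miscount.
- Where the observed tail 1 - Fz reaches zero, the Fdr carries its last
  finite value forward; the curve is clamped to [0, 1].
- All matrices live on the upper triangle over voxel ids assigned in
  ascending (x, y, z) lexicographic order; pair (i, j) sits at index
  (j-1)(j-2)/2 + i.
- Permutation seeds are derived once from the user seed and recorded in the
  run manifest, making every export byte-reproducible.

## Known limitations

- Memory and time grow quadratically with the voxel count; the pure-R
  implementation is comfortable up to a few thousand voxels (the matrix
  stages are BLAS/sparse-algebra bound). Whole-brain analyses at tens of
  thousands of voxels require block-wise storage and were out of scope here.
- The statistic requires two conditions with a common trial structure; it is
  not applicable to resting-state data, and a one-sample design leaves no
  labels to permute.
- Negative-correlation effects are invisible by design.
- With few permutation replicates the far tail of F0 is estimated from few
  effectively independent replicates, and the resulting Fdr cutoff retains a
  small upward drift as P grows (visible when comparing P = 100 against
  P = 200 on small lattices); at realistic problem sizes the pooled null is
  far larger and the cutoff stabilises around P = 100.
- Trials are assumed exchangeable within condition; slow habituation or
  learning inflates the across-trial sigma and costs power, though not
  validity.
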