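---
title: "Methods: unsupervised filtering of tumor-level CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised filtering of tumor-level CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A clinical CT examination yields tens to hundreds of axial slices per
patient, of which only a contiguous handful intersect the tumor. For a
downstream diagnostic classifier the remaining slices are label noise: they
inherit the patient-level diagnosis while containing no disease signal.
Manual screening removes them reliably but slowly; manual contour
annotation is slower still.

This package automates the triage step as a composite of three stages:

1. **Ingestion** — DICOM series or NIfTI volumes are read, direct
   identifiers are stripped, stored intensities are mapped to Hounsfield
   units via the rescale slope/intercept, and each volume is split into
   axial slices windowed linearly to $[0,1]$.
2. **Embedding** — each slice is mapped to a fixed-length feature vector by
   a pluggable extractor (a frozen pre-trained CNN in production; a
   deterministic 64-dimensional hand-crafted descriptor as the built-in,
   dependency-free reference).
3. **Clustering** — K-means with $k = 2$ partitions the embedded slices by
   minimizing the within-cluster sum of squared distances
   $$E = \sum_{i=1}^{k} \sum_{x \in C_i} \lVert x - \mu_i \rVert_2^2,
     \qquad \mu_i = \frac{1}{|C_i|} \sum_{x \in C_i} x,$$
   after which an explicit rule decides which of the two clusters is the
   "tumor-level" (relevant) one.

The contribution exercised here is the composite filtering pipeline, not
the CNN internals: any frozen embedding satisfying the adapter contract
(image in, finite fixed-length vector out, deterministic) can be plugged in
via `register_cnn_adapter()`.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `window_center`, `window_width` | 40, 400 | HU | Standard abdominal soft-tissue window; the source workflow never states its window, so the common clinical default is used and both are config-exposed. |
| `k` | 2 | — | Relevant vs irrelevant is a binary split by design. |
| `n_restarts` | 10 | — | Best-of-restarts by final $E$. |
| `tol` | 1e-6 | $E$ units | Absolute objective-change stop. |
| `scope` | per-series | — | Slice relevance is a within-volume notion; pooled mode (one model for the cohort) is exposed because the source description is ambiguous. Pooled clustering on heterogeneous volumes tends to split by patient rather than by relevance. |
| `normalize` | TRUE | — | K-means is scale-sensitive; columns are z-scored with the *population* sd (so two observations map to exactly $\pm 1$; constant columns become 0). |
| `min_centroid_separation` | 0.5 | normalized feature units | Below this between-centroid distance the series is flagged: both clusters may be irrelevant (no tumor in the volume). A cluster is still mapped relevant — the flag, not the mapping, carries the warning. |

## Numerical choices in the clustering core

- **Distance** is squared Euclidean exactly as in the objective; no
  alternative metrics.
- **Initialization.** The default restart schedule is *mixed*: k-means++
  seeding on odd restarts, plain random-row seeding on even ones. Pure
  k-means++ concentrates initial centers on spread-out points and, on small
  adversarial instances, all ten restarts can fall into the same non-optimal
  basin (observed on 3/200 random instances with $n \le 8$); the random
  restarts buy basin diversity. Both pure modes remain selectable.
- **Polish.** Each Lloyd fixed point is refined by deterministic
  first-improvement single-point relocations (Hartigan-style moves): a point
  is moved from cluster $A$ to $B$ when
  $\frac{|B|}{|B|+1}\lVert x-\mu_B\rVert^2 <
   \frac{|A|}{|A|-1}\lVert x-\mu_A\rVert^2$,
  with exact incremental mean updates. This optimizes the same objective
  $E$ and removes the one-point-flip local optima that Lloyd alone cannot
  escape; with it, best-of-10 matches the exhaustive-enumeration oracle on
  all 200 acceptance instances.
- **Ties** in nearest-centroid assignment go to the lowest cluster index.
- **Empty clusters** are reseeded at the point farthest from its current
  centroid (donor clusters with one member are protected), so $k$ clusters
  survive to convergence.
- **Convergence** is an assignment fixed point, or $|\Delta E| \le$ `tol`,
  or `max_iter`; converged models satisfy the centroid-equals-cluster-mean
  fixed point to 1e-8, and the recorded objective trace is non-increasing.
  Both are asserted on every fit in the test suite.
- **Determinism.** Every stochastic component consumes a local RNG stream
  derived from an explicit seed and restores the caller's RNG state.

## The cluster-to-relevance mapping

The clustering itself is symmetric in its two labels; which cluster is
"tumor-level" is decided by an explicit rule (the loosest part of the
original description, so three rules are provided rather than one hidden
heuristic):

- **foreground-mass** (default): the cluster whose slices have the higher
  mean foreground score — global intensity variance + mean absolute
  gradient + fraction of pixels above the window midpoint, computed from
  the raw (unnormalized) reference coordinates 61, 63 and 64, or from
  caller-supplied per-slice scores for other extractors. A bright lesion
  adds mass above mid-window and edge energy at its rim.
- **exemplar**: the cluster holding the majority of user-supplied
  known-relevant slice keys; equal counts raise an explicit
  "ambiguous mapping" error rather than guessing.
- **majority-size**: the larger cluster, kept only for completeness and
  warned about — in a typical stack *most* slices are irrelevant.

## What the phantom generator emulates — and what it does not

Each synthetic patient is an axial stack in HU: a smooth in-plane
low-frequency cosine texture (amplitude 10–25 HU around a 40 HU base,
standing in for anatomy), iid Gaussian noise (sd 20 HU, typical soft-tissue
CT noise), and, on a contiguous run of slices, an elliptical lesion with a
sigmoid-feathered edge. Lesion contrast is `separation * noise_sd`; its
internal speckle texture (the learnable difference between the two patient
classes) also scales with `separation`. Cohort defaults: 20 patients of 40
slices at 64×64 voxels, a 10-slice tumor run, patients alternating between
the two classes. Volumes are written as NIfTI or DICOM with deliberately
planted private header fields so anonymization is exercised end to end.

Two generator choices are deliberate and load-bearing:

- the background is **constant along z** within a volume. Real anatomy
  drifts through-plane, and that drift is signal a clustering filter can
  legitimately exploit — but it also means a zero-contrast lesion would no
  longer be a true null (measured: with drift, "recovery" at separation 0
  reaches 0.8 purely from z-band structure). With a z-constant background,
  separation is the *only* relevance signal, so the separation-0 cohort is
  an exact chance baseline;
- at `separation = 0` literally nothing is added to tumor-run slices
  (amplitude and speckle both scale with s), making tumor and background
  slices exchangeable by construction.

A green filtering test therefore establishes that the pipeline finds a
contrast/texture signal of the stated size under stationary backgrounds; it
does not establish performance on real CT, where anatomy drift, scanner
artifacts and lesion variability all exist. Likewise the bundled reference
extractor is a stand-in: it separates the phantom classes well, but makes
no claim of CNN-grade invariances.

Chance-level at separation 0 is asserted in a bias-aware way: the exemplar
rule is told 3 true tumor slices per series, which mechanically inflates
raw recovery above 0.5 even under the null, so the null check is that
*non-exemplar* tumor slices are selected at the same rate as background
slices (difference within ±0.1), with raw recovery additionally confined to
a wide [0.35, 0.75] band far below the 0.95 signal regime.

## The downstream demo

The diagnostic stand-in is a multinomial logistic (softmax) classifier
trained by mini-batch SGD with the clinical model's stated hyperparameters
(learning rate 0.1, batch size 32, cross-entropy), zero-initialized and
seed-deterministic. A linear model replaces the deep backbone deliberately:
the comparison under test — unfiltered vs oracle-screened vs
pipeline-filtered training data — concerns data refinement, not model
capacity, and must run on one CPU in seconds. Slice labels inherit the
patient class; test metrics are computed on held-out patients (patient-level
split, never slice-level), both per slice and per patient by majority vote.
Only the *direction* of the effect is asserted (screened arms train at
least as well; the pipeline arm within 0.05 accuracy of the oracle arm);
the original headline accuracies depend on an unavailable hospital cohort
and are not reproduced.

## Degenerate inputs and edge policies

- Windowing requires `window_width > 0`; values at or beyond the window
  edges clip to 0/1 exactly.
- PNG output quantizes with round-half-up to 8 bits; read-back reproduces
  the quantized grid exactly, so windowed values survive a write/read cycle
  to within 1/255. 16-bit output is intentionally not offered — the
  downstream extractors consume 8-bit data.
- All-identical feature rows: z-scoring zeroes constant columns; k-means
  still returns $k$ non-empty clusters (empty-cluster repair) with $E = 0$.
- Ratios with zero denominators in the evaluation indexes are reported as
  `NA` sentinels, never silently 0.
- Series that fail ingestion are skipped with a recorded per-series error;
  a run only fails when *no* series ingests.

## Known limitations

- The DICOM reader supports single-frame, uncompressed, explicit-VR
  little-endian files only (the subset the generator writes); the NIfTI
  reader handles single 3-D/4-D images with axis-aligned orientation. Both
  exist because no medical-image I/O package is available in the target
  environment; on systems with mature readers, ingestion should be swapped
  out behind the same `volume_record` contract.
- Per-slice windowing is per-volume (one window for the whole stack);
  per-slice normalization is not implemented.
- No model selection over $k$; no soft clustering; no resampling or
  registration.
- The exemplar rule needs at least one known-relevant slice per clustering
  scope, which is supervision — cheap (three clicks per volume) but not
  zero.
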