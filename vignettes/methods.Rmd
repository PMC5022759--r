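---
title: "Seeded region growing with GA-selected seeds: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded region growing with GA-selected seeds: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growseg)
```

## The segmentation model

T1-weighted brain MRI shows the three tissues of interest at distinct mean
intensities (CSF < GM < WM), but with substantial Gaussian-like acquisition
noise and, on many scanners, a smooth multiplicative intensity
non-uniformity. Pure intensity thresholding fails under that
non-uniformity; region growing instead makes membership a *local* decision
anchored to a spatially coherent region.

Each class grows breadth-first from one seed pixel. With $N$ accepted
pixels the region carries a running mean $\mu_N$ and dispersion; a frontier
pixel $p$ is accepted iff

$$|I_p - \mu_N| \le \max(k_\sigma \,\sigma_N,\; t_{\min}).$$

The mean is updated incrementally, $\mu_N = ((N-1)\mu_{N-1} + I_N)/N$, and
the dispersion by Welford's recurrence
($M_N = M_{N-1} + (I_N - \mu_{N-1})(I_N - \mu_N)$, $\sigma_N^2 = M_N/N$),
so at every step $\mu_N$ and $\sigma_N$ equal the batch mean and population
standard deviation of the accepted intensities to machine precision — the
test suite asserts agreement to $10^{-9}$ relative on random sequences. A
single-pixel region starts at $\sigma = 0$. A raw alternative recurrence
for the dispersion, $V_N = ((N-2)V_{N-1} + I_N)/N$, is retained behind
`variance_update = "printed"` for comparison; it mixes intensity and
intensity-squared units and is not a variance, so it is never the default.

### Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `k_sigma` | — | 2.5 | accepts ~99% of in-class pixels under Gaussian noise once $\sigma_N$ has stabilized near the true class noise |
| `t_min` | intensity (0–255 scale) | 10 | releases the $\sigma=0$ cold start: about one noise-sd at typical phantom noise, and far below the ≥60-unit inter-class contrast |
| `neighborhood` | — | `eight` | the full 8-neighborhood; `four` and `diagonal-four` are selectable subsets |
| `class_order` | — | csf, gm, wm | classes grow sequentially; earlier classes claim contested pixels first (no re-assignment pass) |

The frontier is a FIFO queue; an accepted pixel's neighbors are enqueued in
row-major order over its 3×3 window and each pixel is tested at most once.
This makes every run deterministic. Membership is tested against the *live*
statistics, as the incremental formulation implies; a `frozen` mode tests
against fixed mean/sd instead, in which case the grown region provably
equals the flood fill of the thresholded image — the suite checks that
equivalence against an independent brute-force flood fill.

Two documented edge behaviors: with `k_sigma = 0, t_min = 0` the region
degenerates to the connected set of pixels exactly equal to the seed
intensity; and if a later class's seed was already claimed by an
earlier-grown class, that class grows an empty region rather than erroring
(`grow_region()` itself still rejects an ineligible seed). The latter keeps
GA fitness evaluation total on noisy images where regions occasionally
swallow another class's candidate pixel.

## Seed selection by genetic algorithm

The result of region growing depends strongly on seed placement — a seed in
a noise spike or near a boundary biases $\mu$ from the start. Seed selection
is cast as optimization: candidate pixels per class come from disjoint
intensity windows (by default, windows split at the midpoints between class
means), and a GA searches over one-seed-per-class chromosomes. Fitness of a
chromosome is the cost of the segmentation grown from it against a
reference: per class, the binary class maps are compared pixelwise and the
squared differences summed — on 0/1 maps, the mismatch count. This is a
supervised calibration step by construction: the cost needs reference class
maps, such as a labeled atlas slice or a phantom's ground truth; seeds
calibrated there transfer to sibling images of the same contrast.

GA operators were left open by the problem statement and are engineering
choices: tournament selection (size 3, drawn with replacement), per-class
uniform crossover (each class's coordinate swapped between children with
probability 0.5, which keeps every gene a valid in-window coordinate),
mutation that resamples a class's seed uniformly from its candidate mask,
and elitism (2 of a population of 30 by default) — which guarantees the
best-cost history is non-increasing, an invariant asserted inside
`ga_optimize()` after every generation. Termination: a fixed generation
budget (50), a zero-cost early exit, or `stall_generations` (10) without
improvement. Fitness values are memoized per chromosome, and the whole run
is reproducible from `rng_seed`. Because the candidate windows are disjoint,
the three seeds of any chromosome are distinct by construction.

## Evaluation metrics

The headline error is the root-mean-square difference
$\sqrt{\tfrac1N\sum_i (P_i - G_i)^2}$ computed on each class's binary map
and averaged over the three classes; on binary maps $\text{RMS}^2 N$ is the
Hamming distance, so the measure is a mismatch *fraction* and is invariant
to image size at a fixed mismatch rate. The RMS over the integer label maps
is reported alongside but weighs label-id differences quadratically, which
is why the binary-per-class form is the headline. Dice coefficients per
class (defined as 1 when both masks are empty) complete the report.

## The phantom generator

`generate_phantom()` emulates what a simulated-MRI database provides: an
intensity image plus exact per-tissue ground truth. Geometry is either
nested ellipses — a CSF ring outside a GM ring outside a WM core, a crude
cortical topology whose per-class pixel counts are independently checkable
by a point-in-ellipse scan — or Voronoi blobs for irregular shapes. Class
means default to 0/60/120/200 (background/CSF/GM/WM) on a 0–255 scale,
matching T1-weighted ordering. Noise is i.i.d. additive Gaussian; the bias
field is a fixed low-order polynomial surface rescaled to span
$1 \pm$ `bias_amplitude`, multiplying the class raster before noise is
added. Everything is deterministic given the spec and its `rng_seed`.

What the phantom does *not* emulate: partial-volume voxels, spatially
correlated (Rician) MRI noise, anatomical detail, or 3-D continuity. Tests
passing on phantoms therefore demonstrate the algorithmic contract —
correct statistics, connectivity, determinism, and that optimized seeding
beats naive seeding under noise — not clinical-grade accuracy on real
scans.

### Study conditions used by the tests and the acceptance script

Perfect-recovery checks run on clean 128×128 nested-ellipse phantoms, where
midpoint candidate windows make every candidate mask exactly the true class
mask and any chromosome yields cost 0. The manual-vs-GA comparison uses 20
paired phantoms at noise $\sigma = 10$ (128×128), GA population 24 for 30
generations; the manual baseline takes the first in-window pixel per class
in array scan order — a plausible blind pick, which under noise often lands
on an isolated out-of-class pixel whose intensity strayed into the window,
exactly the failure mode seed optimization exists to remove. GA-vs-
exhaustive equivalence is checked on 8×8 toys whose candidate sets are
small enough to enumerate completely.

## Known limitations

- One seed per class; growing a class from several seeds is not
  implemented.
- 2-D processing; NIfTI volumes are read but a slice must be selected —
  no volumetric 6/18/26-neighborhood growth.
- The cost requires a reference; there is no unsupervised seeding beyond
  the thresholded candidate masks and the naive baseline.
- No topology preservation, hole filling, or split-and-merge
  post-processing.
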