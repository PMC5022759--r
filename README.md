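# growseg

Brain-MRI tissue segmentation by **seeded region growing** with seed points
chosen by a **genetic algorithm**. The package targets the standard
three-tissue problem — gray matter (GM), white matter (WM) and cerebrospinal
fluid (CSF) — and ships a BrainWeb-style synthetic phantom generator with
exact ground truth, so the whole pipeline is testable without downloading
imaging data.

## The method

**Region growing.** Each tissue class grows from a single seed pixel. The
region keeps a running mean and standard deviation of its accepted
intensities, updated incrementally as pixels join: with *N* pixels accepted,

    mu_N = ((N-1) * mu_{N-1} + I_N) / N

and the dispersion follows Welford's numerically stable recurrence, so the
standard deviation always equals the population standard deviation of the
accepted intensities (a single-pixel region starts at sd = 0). A frontier
pixel *p* (an 8-, 4- or diagonal-4-neighbor of the region) is accepted iff

    |I_p - mu| <= max(k_sigma * sd, t_min)

where `t_min` is a floor tolerance that releases the sd = 0 cold start.
Classes grow sequentially; a pixel belongs to whichever class reached it
first, and pixels never accepted remain background.

**Seed selection.** The quality of a region-grown segmentation depends
heavily on where the seeds sit. Candidate seeds are first thresholded per
class (intensity windows), then a genetic algorithm — chromosomes are one
`(row, col)` seed per class, tournament selection, per-class uniform
crossover, candidate-constrained mutation, elitism — minimizes the cost of
the segmentation grown from each chromosome against a reference
segmentation:

    Cost = sum_c sum_pixels (pred_c - ref_c)^2     (binary class maps)

which on 0/1 maps is the per-class mismatch count. Seed optimization is
therefore a supervised/calibration step: you need one reference-bearing
image (e.g. a labeled atlas slice or a phantom); the seeds found there can
be applied to sibling images.

**Evaluation.** RMS error `sqrt(mean((P - G)^2))` on per-class binary maps
(averaged across classes, the headline number) and on the integer label
map, plus the Dice coefficient per class.

## Worked example

```r
library(growseg)
spec  <- phantom_spec(shape = c(128, 128), noise_sigma = 10, rng_seed = 42)
ph    <- generate_phantom(spec)
cands <- candidate_seeds(ph$image, default_windows())
res   <- ga_optimize(ph$image, ph$reference, cands,
                     grow_config(), ga_config(rng_seed = 42))
res$best_cost
#> [1] 190
labels <- segment_image(ph$image, res$best_seeds)
evaluate_segmentation(labels, ph$reference)
#> segmentation evaluation: rms=0.0618 (label rms=0.2150)
#>   csf rms=0.0681 dice=0.9898
#>   gm  rms=0.0649 dice=0.9914
#>   wm  rms=0.0524 dice=0.9913
```

The GA found seeds whose grown segmentation mislabels 190 of the 3 x 16384
class-map pixels on this noisy phantom (per-class binary RMS 0.062, Dice
about 0.99 per tissue). The naive manual baseline — taking the first
in-window pixel per class, `naive_seeds()` — yields RMS 0.348 on the same
image: optimized seeding cuts the error several-fold, the ordering the
method is built to deliver.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/exec/growseg`): subcommands `simulate`, `segment`, `optimize`,
`evaluate`, `compare`, all honoring `--seed` for bit-identical reruns, with
exit codes 0 (success), 1 (data error), 2 (configuration error). For
example:

```sh
Rscript inst/exec/growseg simulate --out-dir ph --noise-sigma 10 --seed 42
Rscript inst/exec/growseg optimize --image ph/image.png \
  --ref-csf ph/csf.png --ref-gm ph/gm.png --ref-wm ph/wm.png \
  --out-dir opt --seed 42
```

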