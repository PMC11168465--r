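# telotrack

Quantitative image analysis of telomeric RNA localization and telomerase
dynamics in human cells, for researchers studying how the long noncoding
RNA TERRA and the telomerase RNA subunit (hTR) distribute over chromosome
ends. The package turns multi-channel 3D fluorescence microscopy — RNA
FISH plus telomere-marker immunofluorescence, and two-color live-cell
movies — into the quantities such studies report:

- **3D focus detection** per channel (matched-filter threshold at
  background median + k·MAD, 26-connected components, peak splitting),
  with per-object **integrated density** (the telomere-length proxy),
  volume and centroid, nucleus segmentation and per-cell assignment, and
  singlet/doublet scoring of partially overlapping telomere signals.
- **Object-based colocalization**: two foci colocalize when their voxel
  sets share at least one voxel. Significance comes from a **shuffle
  null**: the test channel's objects are randomly re-placed (rigid
  translation) inside the nuclear mask 100 times, and the observed
  nearest-neighbor distance CDF is compared with the mean ± 95% envelope
  of the shuffled CDFs. Triple partitions split RNA–RNA pairs into
  telomeric vs extratelomeric and count "TERRA-free" telomeric hTR.
- **Particle tracking** of live movies: photobleaching correction,
  nearest-neighbor linking with gap closing, frame-wise telomere
  colocalization events (an event of k consecutive frames at interval Δ
  lasts k·Δ seconds; events ≥ 10 s are *stable*), and cis/trans
  classification of particles relative to their telomere of origin
  (overlap < 0.3 µm, proximity < 0.6 µm, same z slice).
- **Dwell-time kinetics**: survival (1-CDF) curves; constrained two-phase
  exponential decay fits S(t) = A_f·e^(−K_fast·t) + A_s·e^(−K_slow·t)
  (plateau 0, K_slow > 0, 1/Y² relative weighting) giving residence times
  τ = 1/K and half-lives ln2·τ per phase; Kaplan–Meier curves of
  cumulative dwell per telomere; two-group log-rank tests.
- A **synthetic-data generator** that renders fixed-seed FISH scenes and
  live movies with full ground truth, so every stage above is validated
  against known answers.

## Worked example

Fixed-image pipeline on the default synthetic scene (4 nuclei, 25
telomeres each, two RNA channels, SNR 10), with the shuffle null:

```r
library(telotrack)
rep <- run_fish_pipeline(config = scene_config(seed = 7),
                         n_shuffles = 100, seed = 7)
rep
#> <run_report>
#> List of 10
#>  $ n_cells            : int 4
#>  $ n_telomere_foci    : int 98
#>  $ n_rna_a            : int 20
#>  $ n_rna_b            : int 20
#>  $ n_pairs            : int 8
#>  $ n_telomeric_pairs  : int 3
#>  $ pct_cells_with_pair: num 100
#>  $ telomeric_fraction : num 37.5
#>  $ shuffle_decision   : chr "significant"
#>  $ seed               : num 7
rep$shuffle
#> <shuffle_envelope> 100 shuffles, global rule: significant (p=0.0198)
```

98 telomere foci are detected for 105 planted emitters (the missing ones
are sub-resolution pairs), the 20 + 20 RNA spots yield 8 voxel-overlap
colocalizations of which 3 lie on telomeres (37.5%), and the observed
proximity beats 100 random re-placements (Monte-Carlo p ≈ 0.02).

Dwell-time kinetics: draw 1000 bound durations from the two-phase world
(60% fast τ=8 s, 40% slow τ=40 s, censored at the 300-s movie end), build
the survival curve and fit the constrained two-phase decay:

```r
d   <- sample_dwell_times(1000, p_fast = 0.6, tau_fast = 8, tau_slow = 40,
                          censor_at = 300, seed = 42)
fit <- fit_biexponential(survival_from_dwells(d$duration, d$censored))
fit
#> <biexp_fit> tau_fast=8.04s tau_slow=40.2s A_fast=0.62 A_slow=0.38 R2=0.9992
derive_half_life(fit)
#>      fast      slow
#>  5.574593 27.854123
```

Both residence times are recovered within 1% here; half-lives are
ln2 × τ.

## Command line

```sh
Rscript -e 'telotrack::telotrack_cli()' simulate --seed 3 --out out/
Rscript -e 'telotrack::telotrack_cli()' fish --seed 3 --shuffles 100 --out out/
Rscript -e 'telotrack::telotrack_cli()' live --seed 3 --out out/
Rscript -e 'telotrack::telotrack_cli()' benchmark --out out/
```

`--config <file>` takes a JSON (or YAML) file with `scene:` and
`kinetics:` sections mirroring `scene_config()` / `kinetics_config()`
arguments. Image I/O is plain text (long-format voxel CSV, truth/track
CSV tables); stacks are first-class in-memory arrays.

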