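# ndrms

Electrode-density analysis of epicortical (ECoG) recordings with the
**normalized differential root mean square (ndRMS)** — a pairwise statistic
that quantifies how much information two electrodes do *not* share, as a
function of their distance, their contact size, and the frequency band.

## The problem and who this is for

High-density (HD, 3 mm pitch / 1 mm contacts) and ultra-high-density (UHD,
0.9 mm pitch / 0.2 mm contacts) subdural grids raise a practical question
for electrophysiologists designing recording arrays: at what electrode
spacing do neighbouring contacts stop contributing unique signal?
Correlation between electrode pairs is the traditional yardstick, but it is
not a calibrated measure of *non-shared* information. The ndRMS is: both
signals of a pair are z-normalized per trial,

```
trial_norm(n) = (trial(n) - mu_trial) / sigma_trial ,
```

the normalized signals are subtracted, and the RMS of the difference is
taken:

```
ndRMS = sqrt( (1/N) * sum_n ( z_x(n) - z_y(n) )^2 )  =  sqrt( 2 (1 - r) ) ,
```

where `r` is the Pearson correlation of the pair. The statistic is
dimensionless and bounded: **0** for identical signals, **sqrt(2)** for
independent white noise, and **2** for oscillations in antiphase — values
between sqrt(2) and 2 therefore indicate out-of-phase oscillatory activity.
Normalization removes the amplitude effects of electrode size and the
power-law amplitude differences between frequency bands, making pairs
comparable across grids and bands.

Because intraoperative patient recordings cannot be redistributed, the
package includes a forward simulator of epicortical potentials (traveling
oscillations with cortical conduction speeds, 1/f^2 broadband activity
mixed through an exponential volume-conduction kernel, disc-averaging
electrodes, sensor noise) so that every analysis stage can be exercised,
tested and calibrated on data with known ground truth.

## What is in the package

- grid geometry: square/hexagonal layouts, pairwise distances, equidistant
  (0.1 mm) IED bins with the >= 10 pairs inclusion rule, matched-bin
  pairing between grids (`make_square_layout`, `make_hex_layout`,
  `pair_distance_table`, `bin_equidistant`, `matched_ied_bins`)
- forward simulation: `sim_config`, `simulate_source_field`,
  `sample_electrodes`, `generate_dataset`
- preprocessing: `detect_bad_channels`, harmonic `notch_filter` (50 Hz and
  24 Hz with harmonics), `common_median_reference`, per-band
  `bandpass_filter` (Butterworth 3rd/4th order, zero-phase),
  `morlet_band_power`, `segment_trials`
- the statistic: `znormalize`, `ndrms_pair`, `ndrms_oracle`,
  `ndrms_per_pair` (median over rest trials, or single-stream for
  anesthesia recordings)
- spatial statistics: `ndrms_by_ied`, `average_levels`,
  `correlation_by_ied`, `compare_grids` (exact Wilcoxon rank-sum at
  matched IEDs, Bonferroni-corrected)
- task mapping: `trial_band_power` (64–128 Hz), `signed_r2_map`
- I/O and orchestration: BIDS-style `_electrodes.tsv` / `_events.tsv`,
  a lossless raw+JSON recording container, `analysis_config`,
  `run_pipeline`, and a thin CLI (`exec/ndrms`, subcommands `simulate`
  and `run`)

## Worked example

Simulate an HD grid recording under the default study conditions and
compute the distance-resolved ndRMS:

```r
library(ndrms)

layout <- default_hd_layout()          # 8 x 12, 3 mm pitch, 1 mm contacts
cfg    <- sim_config(seed = 1)         # 8 s @ 2000 Hz, defaults documented
field  <- simulate_source_field(cfg, layout)
rec    <- sample_electrodes(field, layout, cfg)

pairs  <- pair_distance_table(layout)
bins   <- bin_equidistant(pairs)       # 0.1 mm bins, >= 10 pairs
pv     <- ndrms_per_pair(rec, pairs)   # stream mode: one value per pair
rows   <- ndrms_by_ied(pv, bins, pairs)
head(rows[, c("ied_mm", "value", "n")], 4)
```

```
  ied_mm     value   n
1    3.0 0.6806192 172
2    4.2 0.7561721 154
3    6.0 0.8325651 152
4    6.7 0.8543863 272
```

The mean ndRMS rises from 0.68 at the 3 mm lattice spacing towards the
white-noise bound sqrt(2) ~ 1.41 as electrode separation grows (Spearman
rank correlation across the 52 bins: 0.94) — close electrodes share signal
through volume conduction and oscillation phase alignment, distant ones do
not. `n` is the number of equidistant pairs in each bin; the 3.0 mm bin
holds the 172 lattice-adjacent pairs of an 8 x 12 grid.

Comparing two grids at their shared distances uses the rank-sum machinery;
with nine per-band values per grid and complete separation,

```r
rank_sum_test(1:9, 11:19)
#> $statistic 45      # sum of ranks of the lower sample
#> $p_value   4.114e-05
```

## Documentation

The methods vignette (`vignettes/ndrms-methods.Rmd`) describes the model,
the simulator's design and its limits, all tunable parameters with their
defaults, and the numerical choices. Every exported function carries
roxygen documentation.
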