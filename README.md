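# pnpmrf

Plug-and-play magnetic resonance fingerprinting (PnP-MRF) with heterogeneous
radio-frequency transmit fields, at desk scale.

## The problem

Quantitative MRI wants voxel-wise maps of proton density (PD), the relaxation
times T1 and T2, and — at high field or near implants — the transmit field
amplitude B1+ itself, because B1+ heterogeneity changes the flip angle a
voxel actually experiences and biases every quantitative method that assumes
a nominal flip. Where B1+ collapses into a void, no amount of calibration
recovers the signal.

PnP-MRF embraces the heterogeneity instead of fighting it: two complementary
coil configurations (for example the centre-bright CP mode and the
centre-null gradient mode of a ring array) are interleaved into one
fingerprinting pulse train. As long as their B1+ voids do not overlap, every
voxel is substantially excited at regular intervals, and the matching process
recovers PD, T1, T2 *and* the per-channel B1+ amplitudes from a single
measurement.

This package implements the full computational chain on synthetic digital
phantoms:

- **Sequence schedule** — 4 segments x 120 excitations, 4.8–8 ms apart.
  Segments 1/3: RF-spoiled gradient echoes alternating echo-to-echo between
  the two transmit channels (B1+ and T1 encoding). Segments 2/4: one
  dedicated channel each, 0/180 phase cycling, gradient spoilers only, larger
  drives, so stimulated echoes add T2 weighting. Recovery delays between
  segments strengthen T1 encoding.
- **EPG simulation** — extended-phase-graph recursion over configuration
  states (F+_k, F-_k, Z_k), validated against a brute-force isochromat Bloch
  ensemble to machine precision; optional slice-profile integration from the
  Fourier transform of the RF pulse.
- **Dictionary** — 4-D grid (T1: 150–4564 ms and T2: 15–456 ms in 5% steps;
  B1+ per channel: 0–15 uT in 0.2 uT steps; over 10^7 entries at full size),
  compressed by view sharing: each run of 15 consecutive same-coil complex
  echoes is summed and projected to its modulus, turning 480 complex samples
  into 32 reals (30-fold storage reduction).
- **Radial encoding** — N spokes per time point, rotated by 14 x 6/N degrees
  between excitations (acceleration factor R = round(pi M / (2N))); exact
  non-uniform DFT forward model and density-compensated adjoint
  reconstruction; receive-sensitivity estimation from central k-space and
  matched-filter combination.
- **Matching** — exhaustive cosine-similarity search over unit-normalized
  compressed atoms; PD as the least-squares ratio of the measured to the
  un-normalized simulated fingerprint.
- **Transmit fields** — analytic ring-source models with orthogonal drive
  modes, approximate-CP calibration by central phase alignment, and
  magnitude-least-squares (variable exchange) RF shimming.
- **Phantom pipeline** — digital phantoms, seeded synthetic acquisition with
  complex Gaussian noise, end-to-end recovery reports.

## Worked example

```r
library(pnpmrf)

# four-segment interleaved schedule and its view-sharing compression plan
schedule <- build_default_schedule()
plan <- compression_plan(coil_sequence(schedule))

# published radial acceleration factors
acceleration_factor(160, 9)   # 28
acceleration_factor(336, 12)  # 44

# desk-scale dictionary (true sub-grid of the full 2.9e7-entry grid)
dict <- build_dictionary(reduced_parameter_grid(), schedule)

# end-to-end synthetic experiment: R ~ 28-equivalent radial undersampling
scenario <- scenario_config(M = 64, N = 4, noise_sd = 0.02, seed = 7)
res <- run_pipeline(scenario, dict, schedule)
print(res$report)
```

Output (about 30 s on one CPU):

```
schedule: 480 excitations, 32 compression bins of 15 samples
R(160, 9) = 28 | R(160, 3) = 84 | R(336, 12) = 44
dictionary: 2304 atoms x 32 points (64 degenerate)
PnP-MRF recovery report (R = 25, 2253 in-mask voxels)
  exact (T1,T2,B1) recovery : 80.6%
  T1 within one grid step   : 97.1%
  T2 within one grid step   : 100.0%
  B1 within 0.2 uT          : 97.2%
  T1/T2 RMSE                : 231.5 / 5.6 ms
  mean match correlation    : 0.9958
```

The report says: with 25-fold undersampling and 2% complex noise, 97% of the
phantom's voxels land on (or one grid cell away from) their true T1 and T2
dictionary entries, and the per-channel B1+ amplitudes are recovered to
within 0.2 uT for 97% of voxels — the self-calibrating property that makes
the interleaved acquisition work. In the noiseless fully sampled limit
(`scenario_config(M = 64, noise_sd = 0, encoding = "cartesian")`) recovery
is exact for 100% of voxels.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/pnpmrf.R build-dict --out dict/ --reduced
Rscript inst/cli/pnpmrf.R run --out maps/ --matrix 64 --spokes 4 --noise 0.02 --seed 7 --dict dict/
```

## Further reading

The methods vignette (`vignettes/pnpmrf-methods.Rmd`) documents the signal
model, the numerical conventions, what the synthetic world does and does not
emulate, and the package's design decisions.
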