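---
title: "PnP-MRF at desk scale: model, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PnP-MRF at desk scale: model, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
signal model and its assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic data generator emulates and
what it deliberately does not, the numerical conventions, and the places
where the design was genuinely open and a choice had to be made. Every
quantitative statement here is one the test suite or the acceptance script
computes itself.

## 1. Signal model

### Extended phase graphs

A voxel's magnetization under a long pulse train with gradient spoilers is
simulated with the extended-phase-graph (EPG) formalism: the transverse and
longitudinal magnetization are decomposed into Fourier dephasing orders
`F+_k`, `F-_k`, `Z_k` (with `F-_k` the conjugate of `F+` at order `-k`). An
RF pulse of flip `a` and phase `p` mixes the three states order by order
with the standard rotation matrix; free evolution over `tau` multiplies
transverse orders by `exp(-tau/T2)` and longitudinal orders by
`exp(-tau/T1)` with `Z_0` regrowing toward the equilibrium magnetization
`m0`; each gradient spoiler shifts the transverse ladder up one order, with
the usual `F- -> F+` wrap through zero. The echo is `F+_0` after transverse
decay over TE, demodulated by the transmit RF phase of that excitation, so a
fingerprint is strictly linear in `m0` — which is what lets proton density
be read off as a least-squares scale at the very end.

Phase convention: a 90-degree, phase-0 pulse on equilibrium yields
`F+_0 = -1i * m0`. Tests quote magnitudes or compare against the oracle, so
the convention is internal.

The model excludes off-resonance/B0 evolution, magnetization transfer,
multi-compartment relaxation and diffusion damping of high EPG orders; these
are out of scope throughout.

### The isochromat oracle

Every EPG claim is checked against an independent brute-force route: an
ensemble of spins with *deterministic, uniformly spaced* intra-voxel
dephasing angles rotated explicitly in 3-D (`isochromat_fingerprint()`). A
uniform grid of `n` spins reproduces every configuration order below `n`
exactly, so the comparison is limited only by floating-point rounding — the
acceptance criterion demands 1e-6 relative l2 agreement over 50 random
cases and the observed agreement is at machine precision. The deterministic
(rather than random) dephasing grid makes the oracle comparison itself
deterministic.

### Maximum order and truncation

One spoiler shift happens per repetition interval *and* one per
inter-segment recovery delay, so a 480-excitation train with three delays
touches order 483. The default retained order is therefore
`n_excitations + n_delays + 1`; population pushed past the top while still
above 1e-14 in magnitude raises a truncation warning. This matters in
practice because the dictionary keeps the full Cartesian parameter product —
including `T2 > T1` corners where high transverse orders survive
unusually long.

## 2. The four-segment schedule

The schedule structure is fixed: 4 segments x 120 excitations, repetition
intervals within 4.8–8 ms (default 4.8 ms, TE 2.3 ms), a 2 ms sinc pulse
with time-bandwidth product 3. Segments 1 and 3 alternate the two transmit
channels echo-to-echo under quadratic RF spoiling (default increment 117
degrees, the common literature value); segments 2 and 4 each dedicate one
channel, cycle the RF phase 0/180, keep the gradient spoilers, and drive
larger flips so stimulated echoes contribute T2 weighting. A 3 s recovery
delay separates segments; most tissues cannot fully relax in that time, so
the four segments form one connected fingerprint.

Two elements of the published design are not public (the exact per-excitation
drive voltages and phase increments), so the package declares stand-ins and
makes them configurable:

- **Drive train**: smooth half-sine ramps per segment, peaking at 25 degrees
  (segments 1/3) and 60 degrees (segments 2/4) at the reference B1.
- **Flip calibration**: achieved flip = `relative_drive x |B1| / reference_b1
  x reference_flip`. The reference B1 default is **6 uT**. An earlier
  candidate (60 degrees at 12 uT) was rejected after a margin analysis of
  the compressed dictionary: with peak flips of only 15–30 degrees at 3–6 uT,
  atoms two T1 grid steps apart correlated above 0.9999, so any percent-level
  perturbation (noise, aliasing) collapsed T1 discrimination exactly in the
  field range the method is supposed to serve. Anchoring 60 degrees at 6 uT
  puts the declared 3–12 uT operating range at 30–120 degree peak refocusing
  flips and multiplies the worst-case inter-atom margin by about four.

Which dedicated coil serves segment 2 versus 4 is unstated in the source
design; the package assigns channel 0 to segment 2 and channel 1 to
segment 4.

Schedules serialize to a flat text container (`# key=value` header plus one
CSV row per excitation, `%.17g` precision) that round-trips bit-exactly, and
a 32-bit FNV-1a hash of that canonical form binds every dictionary to the
schedule it was simulated under — matching with the wrong dictionary is a
hard error, not a silent wrong answer.

## 3. Dictionary and compression

Relaxation axes grow multiplicatively from the minimum in 5% steps
(constant relative accuracy): 71 T1 values from 150 ms and 71 T2 values from
15 ms, whose final values print as 4564 and 456 ms at their published
precision; this resolves the generate-from-min-or-max ambiguity in favour of
the minimum, which reproduces both printed endpoints. B1 axes are arithmetic,
0–15 uT in 0.2 uT steps (76 values), one per transmit channel: over 2.9e7
entries at full size. No `T2 <= T1` pruning is applied. Desk-scale work uses
`reduced_parameter_grid()` (default 8 x 8 x 6 x 6 = 2304 entries), an exact
sub-grid: shared tuples produce bitwise-identical atoms, and the build is
chunk-order independent.

Compression is k-space view sharing transplanted to the fingerprint
dimension: every run of 15 consecutive *same-coil* complex echoes
("consecutive" counts every other echo in the alternating segments) is
summed and the modulus taken — 480 complex points become 32 non-negative
reals, a 30-fold storage reduction (2 for complex-to-real, 15 for the
binning). The modulus makes the representation invariant to any phase that
is constant within a bin — in particular the per-coil transmit phase, which
is why the dictionary can be simulated with real-valued B1.

Atoms are stored unit-l2-normalized with the pre-normalization norm kept
separately; the all-zero entries at `B1 = (0, 0)` are flagged invalid and
excluded from matching rather than deleted, so entry indexing stays
congruent with the grid.

## 4. Radial encoding

Each time point is sampled with N evenly distributed spokes spanning the
k-space diameter, rotated by `14 x 6/N` degrees between excitations. The
rotation-to-spacing ratio is `(84/N) / (180/N) = 7/15`: fifteen consecutive
same-coil echoes — exactly one compression bin — tile the angle gap
uniformly, so each compressed frame sees a 15-fold denser composite spoke
set. The acceleration factor is `R = round(pi M / (2N))`, the fully sampled
radial count over the acquired count; the implementation reproduces all four
published (M, N, R) triples exactly.

Conventions, fixed and documented: spokes span 180 degrees with angles in
`[0, pi)` measured from the kx axis; `samples_per_spoke = 2M` (two-fold
read-out oversampling), k in cycles/FOV, pixel coordinates
`(i - M/2)/M`. The forward model and adjoint are *exact* non-uniform DFTs
(no gridding approximation): the uniform radial sample spacing turns the
per-spoke exponential into a geometric recurrence per pixel, which makes the
exact transform affordable at M = 64 and keeps the operator pair's
inner-product test and the brute-force DFT comparison at machine precision.
A gridding NUFFT would only become necessary at full scale (M >= 160),
which stays outside the test suite.

Density compensation is the standard radial ramp: per-sample weight
`|k| dk (pi/N)` with the centre sample at one quarter of the first ring's
weight, scaled by `1/M^2` for the inverse-DFT normalization. Two accuracy
facts shape the tests:

- At full sampling the ramp-compensated adjoint reconstructs a smooth test
  image to within a few percent relative l2 — but a *binary* disk keeps
  about 5.5% of its spectral energy outside the `|k| <= M/2` circle that
  radial spokes can observe at all, so the self-consistency test compares
  against the circularly band-limited disk.
- The residual point-spread-function error concentrates at parameter
  discontinuities. This is why the end-to-end *exactness* oracle (below)
  uses Cartesian full sampling.

Receive sensitivities are estimated from the data themselves: the spokes of
the first compression bin are reconstructed with a Hann apodization confined
to the central k-space region, and the per-channel low-resolution images are
divided by their root sum of squares. Combination is the matched filter
`sum(conj(s) x) / sum(|s|^2)`. Because one sensitivity estimate serves all
time points, estimation error acts as a per-voxel complex constant — which
correlation matching is invariant to.

## 5. Matching

The matcher is a deliberate exhaustive search (no tree or fast index):
cosine similarity between the measured compressed fingerprint and every
valid unit atom, ties broken toward the lowest entry index, deterministic
across chunk sizes. PD is `<measured, best_atom> / atom_norm(best)` — the
least-squares scale between measured and un-normalized simulated
fingerprints — optionally divided by the root sum of squares of supplied
receive maps.

The support mask thresholds the l2 norm of the whole compressed fingerprint
at 5% of its 95th percentile. An earlier candidate — thresholding the first
bin only — was rejected because the first bin holds coil-0 echoes
exclusively, so it silently masked out every voxel inside the coil-0 B1+
void: precisely the voxels the complementary illumination exists to save,
and the complementarity demonstration became unsatisfiable by construction.

## 6. Synthetic transmit fields

Full-wave electrodynamic field simulation is replaced by an analytic ring
model: element k on a ring just outside the field of view radiates
`A exp(-r/decay) exp(-i 2 pi r / lambda)`, times the element's azimuthal
orientation phase `exp(-i alpha k)`. That last factor is the physics that
makes the circularly polarized mode work: the B1+ field of a rotated element
acquires the rotation phase, so driving element k with phase `alpha k`
(mode 1) adds constructively at the centre, while mode 2 nulls there — and
it is exactly why the approximate gradient mode can be *derived* from the
calibrated CP mode by incrementing phases with the azimuthal angle.

Short wavelengths (default 0.14 m, roughly tissue at ultra-high field)
produce interference voids. The two presets — CP/gradient modes of an
8-element ring, and the cosine/sine "linear" drive pair — are scaled so the
95th percentile of the brighter field is 12 uT, the upper end of the
declared 3–12 uT operating window, and are *designed* so that their voids do
not overlap: over the object region each illumination alone dips below 10%
of the peak somewhere, while the pointwise maximum of the two never falls
below 15% of the peak (both properties are asserted by tests). The published
coefficient-of-variation percentages of the electrodynamically simulated
fields are *not* reproduction targets; only these qualitative structures
are.

RF shimming is the magnitude-least-squares variable-exchange iteration:
alternately solve the complex least-squares fit to `m * exp(i arg(S b))` and
update the phase. The objective is provably non-increasing; initialization
defaults to the CP mode for reproducibility, with seeded random restarts
available. Rank-deficient systems fall back to a pseudo-inverse with a
warning. The coefficient of variation (population SD over mean of |B1+|)
is the uniformity metric. The central region for approximate-CP phase
alignment defaults to a block of about 5% of the mask area at its centroid
— unstated in the source design, declared here.

## 7. The synthetic world, and what a green test establishes

`simulate_acquisition()` produces, per foreground voxel, an EPG fingerprint
under that voxel's per-channel B1, modulated by smooth synthetic receive
sensitivities, sampled by the encoding operator, plus i.i.d. complex
Gaussian k-space noise whose per-sample standard deviation is
`noise_sd x` the 95th percentile of the noiseless k-space magnitude —
seeded, and bitwise reproducible.

Two worlds are distinguished deliberately:

- **Grid-aligned** (`grid_aligned = TRUE`): tissue T1/T2 and per-voxel |B1|
  snapped to the dictionary axes *and* zero relative transmit phase —
  the voxel's drive lies exactly in the dictionary's span. This makes
  "exact recovery" well-defined, and it is the world of the exactness and
  undersampling criteria.
- **Honest physics** (`grid_aligned = FALSE`): off-grid tissues and the true
  complex B1. The relative transmit phase then entangles mildly across
  segments through surviving coherences — an effect the interleaved design
  suppresses but EPG faithfully retains — perturbing fingerprints at the
  0.1–0.5% level, which is comparable to the spacing between neighbouring
  atoms of a coarse grid.

Likewise two encodings: rotating radial spokes (default; carries the
undersampling and complementarity experiments) and distortion-free Cartesian
full sampling (`encoding = "cartesian"`), the idealized fully sampled limit.
The end-to-end exactness oracle runs Cartesian because the radial adjoint's
residual PSF error, though within its own few-percent contract, mixes
fingerprints across tissue boundaries and B1-snap contours where adjacent
atoms correlate above 0.999 — with radial encoding at full sampling roughly
a tenth of in-mask voxels (all on such discontinuities) match a neighbouring
cell instead. A green exactness test therefore establishes that the
fingerprint model, compression, sensitivity handling and matcher are
mutually consistent and invertible — not that a density-compensated adjoint
is distortionless, which it is not and which the undersampled criterion
covers at its artifact-level thresholds instead.

What the generator does not emulate: B0 off-resonance, slice-profile effects
in the pipeline (available in the dictionary, off by default at desk scale),
motion, receiver-chain nonlinearity, multi-compartment tissue, and real coil
electrodynamics (SAR, electric fields are out of scope entirely).

## 8. Numerical choices, in one place

- EPG order cap `n_excitations + n_delays + 1`; truncation tolerance 1e-14.
- Isochromat oracle: uniform deterministic dephasing grid; 512 spins for the
  short random cases, 2048 for full-length trains (both exceed the highest
  reachable order).
- Ramp density compensation with quarter-weight centre; `1/M^2`
  normalization.
- Mask threshold 5% of the 95th percentile of compressed-fingerprint norm.
- Matching ties break toward the lowest entry index; degenerate zero-B1
  atoms masked, never matched; all-zero voxels return correlation 0 rather
  than erroring.
- MLS shim: CP initialization, monotone variable exchange; planted-solution
  tests run a few hundred iterations because variable exchange converges
  linearly.
- Axis endpoint rule: count chosen by rounding `log(max/min)/log(ratio)`,
  endpoints reproduced at printed precision, never clamped.
- Schedule text serialization at `%.17g` so round trips are bit-exact; the
  FNV-1a schedule hash feeds the dictionary-compatibility guard.

## 9. Known limitations

- Desk scale only by default: the full 2.9e7-entry dictionary is guarded by
  a resource error (the guard is configurable); full-size M = 160 encoding
  works but is not exercised by the tests.
- The drive/phase trains are declared stand-ins; absolute recovered-map
  quality is therefore a property of this package's sequence, not a
  reproduction of the published in vivo numbers (test-retest precision,
  B1 correlation with saturation mapping, scan times), which are explicitly
  out of scope.
- The adjoint reconstruction is intentionally simple; no parallel-imaging or
  iterative reconstruction is provided, matching the design's position that
  matching filters most aliasing.
- Proton density is relative: with estimated (unit root-sum-of-squares)
  sensitivities the receive shading is not removed from PD unless true
  magnitude maps are supplied.
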