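---
title: "SWIM-encoded two-dimensional mass spectrometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SWIM-encoded two-dimensional mass spectrometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swim2dms)
```

## The measurement principle

Two-dimensional mass spectrometry (2DMS) correlates every product ion with
its precursor without chromatographic separation or quadrupole isolation.
On a quadrupole time-of-flight instrument this is achieved with stored
waveform ion radius modulation (SWIM): ions are trapped in the RF-only
quadrupole, and a sequence of broadband dipolar excitation pulses modulates
the orbital radius of every trapped species. The per-frequency amplitude of
pulse $n$ is

$$M(f, n) = \tfrac{1}{2}\left(1 + \sin\!\left(n\pi\,
  \frac{f - f_{min}}{f_{max} - f_{min}} - \frac{\pi}{2}\right)\right),$$

so, as $n$ increments, the drive amplitude at any fixed frequency follows a
sampled sinusoid. An ion whose secular frequency is $f_s$ therefore has its
radius — and through a radius-dependent fragmentation step, its intensity
and its fragments' intensities — modulated at the *encoding frequency*

$$f_e = \frac{f_s - f_{min}}{2\,(f_{max} - f_{min})} \in [0, 0.5]
\ \text{cycles/index}.$$

A Fourier transform along the SWIM-index dimension of every time-of-flight
m/z bin then recovers, for each product ion, the encoding frequency — and
hence the precursor m/z — it belongs to.

The package implements the five stages of this experiment as composable
modules: pulse synthesis (`synthesize_pulse`, `pulse_sequence`), the
secular-frequency calculus (`mathieu_q`, `mathieu_beta`,
`encoding_frequency`, `mz_from_encoding`, `fit_calibration`), a
signal-level forward simulator (`generate_cube`), a Monte Carlo trajectory
simulator (`run_pulse_sequence`), and the decoding pipeline
(`transform_cube` through `pick_peaks` and the slicing functions).

## Pulse synthesis

The frequency-domain prescription $P_M(f,n) = M(f,n)\,e^{i\varphi(f)}$ is
laid out on the DFT grid of the pulse window (magnitudes exactly zero
outside $[f_{min}, f_{max}]$), inverse-transformed, and the real part taken.
The quadratic phase $\varphi$ spreads the pulse in time to reduce the DAC
peak-voltage demand. Its textbook form $T (f-f_{min})^2/(f_{max}-f_{min})$
is dimensionally a time-bandwidth product, so the package adopts the
convention

$$\varphi(f) = \pi T\,\frac{(f-f_{min})^2}{f_{max}-f_{min}},$$

under which the group delay $(1/2\pi)\,d\varphi/df$ runs linearly from 0 at
$f_{min}$ to $T$ at $f_{max}$ — i.e. the chirp occupies the first $T$
seconds of the window, matching the observed localization of the
acquisition-scale pulse within roughly half of its 20 ms window at
$T = 10$ ms. The bare quadratic remains available via
`quadratic_phase(..., literal = TRUE)` for cross-checks.

Two defaults deserve a note:

* **Amplitude scale.** Only the outcome ("about 1 V zero-to-peak") is
  physically prescribed. The natural normalization target — the index with
  the largest band-mean $M$ — is degenerate, because the band-mean of
  $M(f,n)$ is exactly $1/2$ for every $n \ge 1$. The scale is therefore
  fixed so that the $n = 1$ pulse peaks at `cfg$amplitude` volts (default
  1 V); all other pulses share the same volts-per-unit scale.
* **Windowing.** No apodization is applied before the inverse transform;
  energy confinement comes entirely from the quadratic phase.

## Secular-frequency calculus

For an RF-only quadrupole the stability parameter is
$q = z e V_{trap} / (\pi^2 m r_0^2 f_{trap}^2)$ ($V_{trap}$ zero-to-peak)
and the secular frequency is $f_s = \beta f_{trap}/2$. Three routes from
$q$ to $\beta$ are provided:

* `dehmelt`: $\beta = q/\sqrt 2$, valid for $q < 0.4$;
* `koizumi`: the closed form
  $\cos(\pi\beta) = 1 - \frac{\pi^2}{4} q^2 + \frac{\pi^4}{1120} q^4$,
  equivalently
  $q^2 = \frac{4}{\pi^2}\bigl(35 - \sqrt{1225 - 70\,(1 - \cos \pi\beta)}\bigr)$,
  accurate to 0.2% for $q \le 0.5$ and 0.7% over the whole first stability
  region;
* `exact`: the standard continued-fraction characteristic exponent,
  truncated when terms fall below $10^{-12}$, which serves as the oracle
  for both approximations in the test suite.

The constant in the closed form is normalized so its low-$q$ limit agrees
exactly with the Dehmelt/continued-fraction limit; its radicand satisfies
$1225 - 70(1-\cos\pi\beta) \ge 1085$ for every stable $\beta$, so the
inversion from encoding frequency to m/z never leaves its domain.

Because the Dehmelt route linearizes in $z/m$, it inverts to the reciprocal
law $m/z = k_1/(f_e + k_0)$ with $k_0 = f_{min}/2(f_{max}-f_{min})$
(`encoding_constants`). This reciprocal form shows curvature below about
m/z 400, where $q$ is no longer small; the Koizumi route is the recommended
first-pass axis (`first_pass_axis(..., method = "eq6")`).

**The field radius $r_0$** is not measurable on most instruments and enters
every absolute frequency prediction. The default, 2.8954 mm, is a synthetic
fixture value back-solved once so that the reciprocal-law prediction for an
m/z 449.92 precursor is 0.102 cycles/index under the default trap settings
(1 MHz, 120 V zero-to-peak); it is a convention of this package, not a
measured constant.

**Calibration.** Peaks on the autocorrelation line are intact precursors,
so their accurately known product-axis m/z recalibrates the precursor axis.
`fit_calibration` fits a least-squares polynomial (order 1-3) in the
*first-pass mass* $m_1 = k_1/(f_e+k_0)$ rather than in $f_e$; an exact
reciprocal law then fits with coefficients $(0, 1)$ and zero residual, and
curvature left by the first pass is absorbed by the quadratic or cubic
terms. `recalibrate` adds one robust trimming pass (drop pairs beyond 3
residual RMS and refit) to guard against fragment peaks that sit near the
diagonal by coincidence.

## The forward simulator (synthetic data cubes)

`generate_cube` is the package's synthetic-data generator. It represents
the ion cloud's radius by the scalar drive amplitude
$a(n) = A\,M(f_s, n)$ — a resonant-response proxy that keeps the model
analytic — and composes four mechanisms:

* **UVPD** (`uvpd_survival`): a coaxial Gaussian beam is most intense on
  the axis, so $p(a) = p_{max} e^{-a^2/2\sigma^2}$ with
  $\sigma = $ `laser_sigma_frac` $\times A$. Fragment traces are 180° out
  of phase with the precursor radius.
* **In-trap CID** (`intrap_cid_survival`): a hard onset at
  `cid_threshold` volts with a linear ramp — the clipped, asymmetric
  waveform is what feeds harmonic peaks at $2f_e$, $3f_e$.
* **Exit transmission** (`flux_transmission`): unity below `v_crit`, then
  a smooth Gaussian-tailed roll-off to `1 - loss_max` (a hard step would
  produce pathological spectra). This is the flux-periodic mode; with
  `v_crit = Inf` the simulator runs flux-constant and the per-index total
  of precursor plus fragments is conserved to machine precision.
* **Beam CID**: a constant fraction of *transmitted* precursors fragments
  downstream, so those product traces share the precursor's frequency and
  phase.

Channel weights are normalized within each mechanism so that precursor and
fragment intensities sum to the injected abundance; without that
normalization the flux-constant conservation property cannot hold when
nominal yields sum below one.

Peaks are painted on a ToF-like product axis as bin-integrated Gaussians
(ppm-constant FWHM, default 20 ppm), which makes intensity bookkeeping
exact rather than approximate. Noise follows the experimental observation
that the noise amplitude is proportional to the signal: per bin and index,
sd $= 0.05 \times$ signal plus a floor of $0.001 \times$ the cube maximum.
The 50-fold trap-and-release averaging per index is folded into the noise
scale rather than simulated fill-by-fill. A small fraction (default 2%) of
each fragment channel is emitted as *upstream* (pre-trap) photofragments:
independently trapped species that modulate at their own secular frequency
and therefore land on the autocorrelation line, emulating the unavoidable
irradiation of ions in the transfer optics.

The modulation truth uses the exact continued-fraction secular frequency by
default (`fs_method = "exact"`), emulating a real trap: the closed-form
first-pass axis is then the accurate one and the reciprocal Dehmelt axis
shows its low-mass curvature, which is the situation the recalibration
exists to fix. Setting `fs_method = "dehmelt"` instead makes the
reciprocal-law predictions exact — useful for identity tests.

What the generator deliberately does *not* emulate: space charge and trap
capacity, ion-ion reactions, secular-frequency line width (amplifier dither,
collisional damping), mass-dependent detector response, and ToF peak-shape
asymmetry. Tests passing on these cubes therefore validate the decoding
mathematics and bookkeeping, not robustness to every artifact of real
hardware.

## The trajectory simulator

`run_pulse_sequence` is the higher-fidelity cross-check: a compiled
velocity-Verlet integration of ions in the ideal quadrupole RF field plus
the dipolar SWIM field $V_{exc}(t)/r_0$, restricted to the radial plane
(the axial motion decouples in an ideal trap and the laser propagates along
the axis). Each SWIM index receives a freshly sampled thermal cloud
(Gaussian, default sd 0.2 mm, 300 K), standing in for the collisionally
cooled distribution a full injection-optics model would provide.
Hard-sphere collisions with background gas sample a Maxwell-Boltzmann
partner and scatter the relative velocity isotropically; velocities keep a
z component so all three degrees of freedom thermalize to $\tfrac32 kT$.
UVPD applies the path-averaged fluence of the final secular orbit through
the Gaussian beam (0.6 mm FWHM, 25 uJ defaults), and the Monte Carlo fate
draw uses $p = 1 - e^{-k\,\Phi}$ with $k$ calibrated so an on-axis ion
survives with probability one half. An exit-aperture criterion (radial
excursion beyond a configurable fraction of $r_0$) reproduces the
flux-periodic loss mechanism.

Numerical choices: the integrator step must satisfy
$dt \le 1/(50 f_{trap})$ (20 ns at 1 MHz), at which the secular envelope is
stable to $10^{-4}$ over 1000 RF cycles and recovered secular frequencies
match the continued-fraction values to better than 0.5% for $q \le 0.4$.
The scheme converges at second order, so positions at a fixed end time
carry a percent-level discretization offset at the dt bound; frequencies —
the quantity the method encodes — are far less sensitive. Desk-scale
defaults (2 ms pulses, reduced DAC rate, a few hundred ions, 16-64
indices) keep a full run in seconds while leaving the trap RF, band edges
and geometry at acquisition scale. The simulator reproduces the laser
misalignment phenomenology: scanning the beam offset along the excitation
axis collapses the fragment modulation depth at a null offset and reverses
its phase beyond it.

## Decoding

`transform_cube` subtracts each product column's mean (unmodulated
background — e.g. upstream photofragments of out-of-band parents — then
stays in row 0 instead of smearing along the diagonal logic), zero-fills
once ($N \to 2N$), transforms, and keeps the $N$ non-negative-frequency
magnitude rows. No apodization is applied by default; the Hann option
exists but the resolving-power figures quoted here are for the rectangular
window. Phase is discarded: at the unpadded transform rows the magnitude is
exactly invariant to a circular shift of the index origin.

Peak picking requires 2D local maxima with SNR above a threshold (default
5), with noise estimated per product column as $1.4826 \times$ the median
absolute deviation — this same rule suppresses the vertical streaks that
signal-proportional noise paints under intense precursors. Two refinements
are the package's own: candidates weaker than 25% of a stronger peak within
100 rows of the same column are rejected (the rectangular window's sinc
sidelobes are genuine 2D local maxima and would otherwise dominate
noiseless peak counts), and each peak's precursor coordinate is refined by
a 7-point intensity-weighted centroid (apex row plus/minus 3) computed in
m/z coordinates. Harmonics are labeled afterwards: a peak whose frequency
sits within 1.5 zero-filled bins of an integer multiple of a stronger peak
sharing its product m/z gets that multiple as its `harmonic_order`.

Rows that map outside the nominal display range (default m/z 90-4500),
including the $f_e = 0$ row, carry the sentinel `NA` in the precursor axis
— they are reported, never silently dropped. The autocorrelation section
samples, for each row, the strongest product column inside that row's own
precursor-bin footprint: the reciprocal axis is orders of magnitude coarser
than the 20 ppm product peaks, so a literally point-sampled diagonal would
thread between them.

### Resolution

With $N$ modulation steps, a rectangular window and one round of
zero-filling, the FWHM of a single precursor's frequency-domain peak is
about $1.21/N$ cycles/index. On the reciprocal mass axis this translates to

$$\frac{M}{\Delta M} = \frac{f_e + k_0}{\Delta f_e},$$

which for a mid-band species ($f_e \approx 0.11$) at $N = 1024$ gives
$M/\Delta M \approx 100$ — the package measures 108 on its own simulated
peak (`precursor_resolving_power`). The product axis keeps the ToF
performance untouched: product m/z values pass through the whole pipeline
bit-identically, which is what lets a 3+ isotope cluster emerge from
simulate-plus-decode with its 0.334 m/z spacings intact.

## Problem sizes used by the tests

The unit and property tests run reduced configurations chosen to exercise
the identical code paths at interactive speed: 256-512 SWIM indices and a
few thousand product bins for decode properties, 2 MS/s x 5 ms pulses for
waveform checks, and 100-200 ions x 16-32 indices for trajectory runs.
The acceptance-level checks (resolving power, isotopologue spacing, the
four-species end-to-end decode) run at the full 1024 indices.

## Known limitations

* The scalar-amplitude cloud model has no secular line width, so simulated
  frequency peaks are transform-limited; real peaks broaden with amplifier
  dither and collisions.
* The closed-form beta inversion is an approximation (0.7% worst case);
  the exact continued-fraction route is available but slower.
* Upstream fragments are modeled as unfragmentable pseudo-species; their
  own UVPD depletion is neglected.
* $r_0$ is a fixture convention (see above); absolute encoding-frequency
  predictions inherit it, though the autocorrelation-line recalibration
  removes the dependence from decoded spectra, exactly as intended on a
  real instrument where $V_{trap}$ is not accurately known either.
* The trajectory simulator is 2D radial with an ideal field: higher-order
  field components, fringe fields and axial gating dynamics are out of
  scope.
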