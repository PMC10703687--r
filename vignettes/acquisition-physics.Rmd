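---
title: "Acquisition physics behind gradient-coil performance comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acquisition physics behind gradient-coil performance comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradepi)
```

# What this package models

A head gradient coil is characterized by three numbers that bound every
pulse sequence run on it: the absolute amplitude limit $G_{abs}$ (mT/m),
the duty-cycle-limited nominal amplitude $G_{nom}$ usable through a
sustained EPI readout, and the slew-rate limit $SR$ (T/m/s).  `gradepi`
derives from these, from first principles, the quantities by which gradient
coils are compared in high-resolution neuroimaging: minimum echo spacing
and echo time in EPI, T2*-driven point-spread-function (PSF) blurring,
closed-form SNR scalings, Stejskal–Tanner diffusion-encoding timing,
peripheral-nerve-stimulation (PNS) supervision, parallel-imaging g-factor
maps on synthetic receive arrays, and susceptibility distortion.

Three presets ship with the package: `impulse` (200/85 mT/m, 900 T/m/s,
with forbidden echo-spacing bands at 0.82–0.92, 0.46–0.48, 0.35–0.36 and
0.26 ms where mechanical resonances prohibit operation), `ac84`
(80/50 mT/m, 333 T/m/s) and `xr_body` (80/40 mT/m, 200 T/m/s).  One
published source sentence lists a conflicting slew rate for the strongest
coil; we use 900 T/m/s, the value its specification table and every derived
number are consistent with.

# EPI timing model

The readout lobe of one EPI echo must traverse the read axis of k-space,
a gradient area of $N/(\gamma\,\mathrm{FOV})$ with
$\gamma = 42.576$ MHz/T.  `trapezoid_for_area()` returns the
minimum-duration symmetric trapezoid (or triangle, when the amplitude limit
is not reached) under $G_{nom}$ and $SR$; timing is continuous, with no
gradient-raster rounding.  Echo spacing is this duration plus a fixed
per-echo dead time, 30 µs by default.  We model ramp-sampled acquisition
(the ADC is active over the ramps), which is how such scanners reach their
published echo spacings; the dead time absorbs ADC gaps and phase-blip
overhead.  With these defaults the four published echo-spacing operating
points (0.58/1.21 ms at 0.6 mm and 0.68/1.41 ms at 0.5 mm, strongest versus
whole-body coil) are reproduced within 1%:

```{r}
p06 <- epi_protocol(0.6, 192, 320, grappa_r = 3, partial_fourier = 6/8)
min_te(p06, load_coil_preset("impulse"))
```

Minimum TE adds a fixed 1.3 ms pre-readout time (excitation half-duration
plus phase pre-winders) to the traversal of
$\lceil N(PF - 1/2)/(R \cdot \mathrm{segments})\rceil$ echoes before the
k-space centre.  Both constants are configurable arguments; the defaults
reproduce the published TE pairs (17/34 ms at 0.6 mm, 23 ms at 0.5 mm).
Echo-count conventions (ceiling at every division, the centre echo counted
among the pre-centre echoes) are fixed here because no published convention
exists to match.  When a computed echo spacing lands in a forbidden band it
is bumped to the band's upper edge with a warning, mirroring scanner
practice.

`achievable_resolution()` inverts the model by scanning matrix sizes; at a
target TE of 26 ms (FOV 200 mm, GRAPPA 4, PF 0.75) it ranks the three
presets in the published order (finest for the strongest coil).  The exact
published resolutions at that operating point depend on acceleration and
constraint details that are not fully printed, so only the ordering is
claimed; our solver lands within ~10% of the published values.

# PSF and SNR scalings

T2* decay across the echo train multiplies k-space line $i$ (centre $c$)
by $\exp(-t_i/T_2^*)$ with $t_i = TE + (i - c)\,es_{\mathrm{eff}}$ and
$es_{\mathrm{eff}} = es/(R\cdot \mathrm{segments})$; partial-Fourier lines
are zero-filled rather than conjugate-synthesized, because the PSF of the
directly transformed modulation is what the blurring comparison quantifies
(POCS-style recovery is out of scope).  The PSF is the magnitude of the
Fourier transform of this modulation transfer function on a 64-fold
zero-padded grid — padding keeps the interpolation error of the FWHM
measurement below 0.1% — and the FWHM is read off by linear interpolation
at half maximum.  A rectangular window gives the sinc main-lobe width of
1.207 voxels, the no-blurring floor.  With $T_2^* = 25$ ms (a typical 7 T
white-matter value, and the value used in the published simulations) the
FWHM-in-mm curve over nominal resolution dips near 0.5 mm for the strongest
preset before echo-train lengthening takes over, and the three presets stay
ordered at every resolution.

SNR scalings are closed forms: `relative_snr_te()` is
$e^{TE_1/T_2}/e^{TE_2/T_2}$ (with white-matter $T_2 = 46$ ms, shortening a
diffusion TE from 110 to 59 ms yields 3.03, "up to threefold");
`volumetric_gain()` is $(r_1/r_2)^3$ and returns the exact cube ratio
(3.76 for 0.7 to 0.45 mm) — note that the ratio of voxel volumes rounded
to two decimals (0.23/0.09 µl) gives 2.55 rather than the exact 2.49 for
the 0.61 to 0.45 mm pair; `bandwidth_penalty()` is $\sqrt{bw_1/bw_2}$.

# Diffusion encoding

`b_value()` implements the Stejskal–Tanner expression for trapezoidal
monopolar lobes, $b = \gamma^2 G^2[\delta^2(\Delta - \delta/3) +
\epsilon^3/30 - \delta\epsilon^2/6]$, verified in the tests against 1 µs
numeric integration of $\gamma^2\int q(t)^2 dt$.  At constant $b$ this
yields the $b = G^2 t^3$ scaling: `encoding_time_factor(2.5)` = 0.54 for
the 80-to-200 mT/m amplitude step.  `min_te_pgse()` packs lobes at
$G_{abs}$ (diffusion encoding is low duty cycle, so the absolute limit
applies) tightly around the refocusing pulse and bisects the lobe duration
to the target b.  Spin-echo symmetry forces
$TE = t_{refocus} + 2(\delta + \epsilon) + 2\,t_{readout\to centre}$; the
refocusing duration (default 7 ms, including crushers) and pre-echo readout
time (default 8 ms) are explicit inputs because no published values exist.
With these defaults the strongest-versus-body TE ratio at $b = 10{,}000$
s/mm² is about 0.64, while the encoding-time ratio (TE net of the fixed
overheads) is 0.50–0.54 — the published 59/110 ms TE pair implies overhead
conventions that are not printed (the published comparison even held the
EPI readout at body-coil performance in both arms), so the package claims
the ordering and the encoding-time ratio, not the absolute TEs.

# PNS supervision

`safe_response()` implements the filter–rectify–weight surrogate used for
real-time stimulation monitoring: per gradient axis the slew $|dG/dt|$
passes through a weighted bank of first-order low-pass filters (defaults:
time constants 0.12/0.6/3 ms, weights 0.6/0.3/0.1, mimicking fast and slow
membrane components), axes combine root-sum-square, and the time-maximum is
reported as a fraction of the first-level ceiling Stimlim; normal operating
mode is capped at 0.8 Stimlim.  The response is positively homogeneous and
shift-invariant by construction.  The scanner's fitted filter constants
derive from a 33-participant threshold study and are not public, so the
defaults are a synthetic calibration with a documented contract: the scale
(1/240 per mT/m/ms of sustained slew) is set so that the loudest allowed
readout — a 98 mT/m triangle train at 213 T/m/s, echo spacing 0.92 ms —
evaluates just below Stimlim (0.89), while full-performance switching
(200 mT/m at 900 T/m/s) exceeds it severalfold.  `operating_curve()`
bisects trapezoid amplitude at each rise time against the normal-mode
limit, reproducing the qualitative amplitude-versus-rise-time geometry of
such scanners: PNS-limited at short rise times, amplitude-limited beyond a
few milliseconds.  Users with access to fitted constants can replace every
parameter via `safe_params()`.

# Synthetic receive arrays and g-factors

`build_helmet_array()` tiles an ellipsoidal helmet (semi-axes 110/125/110
mm, sized to clear a full-FOV phantom grid) with rows of circular loops —
12/18/24 in the top three rows and 42 in the rim band at 96 channels —
with loop radius set by equal-area tiling with ~15% overlap, giving ~4 cm
loops at 96 channels and ~6 cm at 32.  Sensitivities are quasi-static
Biot–Savart loop fields, $S = B_x - iB_y$; the noise covariance is
$\Psi = \sigma^2(I + c\,K)$ with a Gaussian overlap kernel on inter-loop
distances, eigenvalue-floored to stay positive definite.  `snr_map()` is
the noise-covariance-weighted optimal combination
$\sqrt{S^H\Psi^{-1}S}$; `retained_snr_map()` computes SENSE-algebra
g-factors over each aliasing set (in-plane folding crossed with
CAIPI-shifted SMS slices),
$g_j = \sqrt{[(S_A^H\Psi^{-1}S_A)^{-1}]_{jj}[S_A^H\Psi^{-1}S_A]_{jj}}$.
SENSE algebra stands in deliberately for k-space-kernel reconstructions:
sensitivities are known exactly in simulation, making analytic noise
propagation the natural model, and the tests verify it against brute-force
Monte-Carlo propagation through the unfolding matrix (10⁵ draws, 2%).
Channel-count comparisons (32/64/96) are evaluated at the combination
acceleration such scanners actually run (in-plane 4 × SMS 3, CAIPI shift
1), where channel count genuinely differentiates arrays; at mild
accelerations all three arrays saturate.  Central/peripheral statistics
split the brain mask at 40% of its maximal centroid distance — the
published comparisons did not print their ROI definition, so only orderings
are claimed, never in vivo percentages.

# Phantoms and distortion

`make_phantom()` builds nested smoothly-perturbed ellipsoids
(background/CSF/gray/white) with tissue proton density and T2* (white
25 ms, gray 33 ms, CSF 100 ms), plus an off-resonance map: a low-order
polynomial with a focal anterior-inferior (sinus-like) perturbation,
bounded at ±80 Hz and zero outside the head.  Everything is deterministic
given the seed.  `simulate_multicoil()` adds circular complex Gaussian
noise with channel covariance $\Psi$; the synthetic data thus have exactly
the statistical structure the SNR/g-factor algebra assumes — which is the
point of the phantom, and also its limit: no physiological noise, no
motion, no B1+ inhomogeneity, no realistic anatomy.  Passing tests show
the algebra and its implementation are right, not that scanner data will
meet the model's assumptions.

A voxel off-resonant by $\Delta f$ is displaced along phase encode by
$\Delta f \cdot N_{pe}\,es_{\mathrm{eff}}$ voxels; `epi_distort()` applies
this with cubic interpolation and Jacobian intensity modulation (signal
conservation), and is validated against a full discrete EPI phase-accrual
simulation to 0.1 pixel.  Distortion is linear in echo spacing, which is
the entire mechanism of the coil comparison.  `estimate_warp()` recovers
the equal-but-opposite displacement field of an opposed phase-encode pair
by a symmetric coarse-to-fine scheme (demons-style Gauss–Newton along the
PE axis, Gaussian smoothing of the update as the regularizer, three
pyramid levels); on synthetic pairs it recovers known smooth fields to
better than 0.3 mm RMSE inside the head and scales with echo spacing as
the forward model predicts.  The published comparison used an external
nonlinear alignment tool whose regularization is unprinted; this is a
minimal bespoke implementation of the same principle, not a re-creation of
that tool.

# Numerical choices and problem sizes

Timing solvers are closed-form or bisection to 2⁻²⁰⁰-scale brackets;
the PSF grid is padded 64-fold; the warp estimator uses 60 iterations per
level with smoothing sigma 1.5 voxels.  The test and acceptance suites run
the image-domain analyses on deliberately small grids — 24³-scale phantoms
at 6 mm, 16×16 Monte-Carlo toys, 64×64 distortion slices — chosen so the
whole suite completes in well under a minute while every comparison retains
its full structure; all sizes scale up by argument.  Degenerate inputs
(zero areas, all-zero MTFs, rank-deficient aliasing sets, non-positive
definite covariances) raise errors or flagged values rather than silent
results.

# Reproducing the headline numbers

`scripts/acceptance.R` recomputes the seven EPI timing quantities (echo
spacing and minimum TE at 0.6 and 0.5 mm for the strongest and whole-body
presets) from the package alone and writes them as JSON; see the README.
The test suite (`tests/testthat/`) carries every other check described
above at its stated tolerance.
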