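---
title: "Methods: single-microbubble spectroscopy and coating quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-microbubble spectroscopy and coating quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bubblespec)
```

`bubblespec` characterizes single phospholipid-coated microbubbles along two
axes: their acoustic behaviour, read out from ultra-high-speed radius–time
(R–t) recordings during ultrasound insonification, and their coating
morphology, read out from two-channel 3D fluorescence stacks. This vignette
is the package's account of the models, the tunable parameters, the numerical
choices, and what the validation on synthetic data does and does not show.

## The linear coated-bubble oscillator

A gently driven coated microbubble behaves as a damped harmonic oscillator in
the relative radial excursion $x = (R - R_0)/R_0$:

$$\ddot x + \delta\,\omega_0\,\dot x + \omega_0^2\,x = -\frac{P(t)}{\rho R_0^2},$$

whose steady-state amplitude under a sinusoidal drive of pressure amplitude
$P$ at transmit frequency $f_T$ is

$$x_0(f_T) = \frac{|P|/(4\pi^2\rho R_0^2)}
  {\sqrt{(f_0^2-f_T^2)^2 + (\delta f_T f_0)^2}}.$$

The coating enters through two parameters. The shell elasticity $\chi$ (N/m)
stiffens the restoring force and raises the eigenfrequency

$$f_0 = \frac{1}{2\pi}\sqrt{\frac{1}{\rho R_0^2}\left[3\gamma P_0 +
  2(3\gamma-1)\frac{\sigma_w}{R_0} + \frac{4\chi}{R_0}\right]},$$

and the shell viscosity $\kappa_s$ (kg/s) adds dissipation to the damping
coefficient

$$\delta = \frac{\omega_0 R_0}{c} + \frac{4\mu}{\rho\omega_0 R_0^2} +
  \frac{4\kappa_s}{\rho\omega_0 R_0^3},$$

the three terms being acoustic radiation, liquid viscosity and shell
viscosity. The resonance frequency is $f_{res} = f_0\sqrt{1-\delta^2/2}$,
real only while $\delta^2 < 2$. Defaults are water and a C$_4$F$_{10}$ core:
$\gamma = 1.07$, $P_0 = 10^5$ Pa, $\sigma_w = 0.072$ N/m,
$\rho = 10^3$ kg/m³, $c = 1500$ m/s, $\mu = 10^{-3}$ Pa·s
(`physical_constants()`).

Assumptions: small-amplitude (linear) oscillation, so the model is valid at
gentle drive pressures (tens of kPa) and fits are meaningful only there;
spherically symmetric oscillation; damping evaluated once per bubble at
$\omega_0$ rather than per drive frequency; no thermal damping; no nonlinear
shell rheology (buckling or rupture regimes are out of scope). At strong
drive (≳ 150 kPa) real bubbles oscillate nonlinearly and these fits should
not be used.

## From recordings to an amplitude spectrum

One *spectroscopy session* is a baseline recording without ultrasound plus
one recording per transmit frequency on the 1–4 MHz grid in 0.2 MHz steps
(16 recordings, `default_ft_grid()`), each 128 frames at ~17 Mfps. Per
recording:

* the resting radius $R_0$ is the mean of the first five frames;
* the excursion is band-pass filtered with a third-order Butterworth centred
  at $f_T$ with 300 kHz bandwidth. Filtering is zero-phase
  (forward–backward), so the excursion maximum is not phase-shifted; the
  −3 dB bandwidth refers to the single-pass design. Because the impulse
  response of a 300 kHz-wide filter is a sizeable fraction of a 128-frame
  record, the record is extended by odd reflection at both ends before
  filtering and cropped afterwards; without this, edge transients bias the
  maximum;
* $x_0$ is the maximum absolute filtered excursion divided by $R_0$.

The 16 $(f_T, x_0)$ points are fitted by unweighted least squares with
$(\chi, \kappa_s)$ free, bounded to the physical ranges $\chi \in [0,5]$ N/m
and $\kappa_s \in [0, 10^{-6}]$ kg/s. Initialization inverts the
eigenfrequency formula at the spectrum peak for $\chi$ and matches the peak
height for $\kappa_s$; three deterministic starts (the initial point and
half/double perturbations) guard against the flat off-resonance valley of
the objective. Convergence uses the Levenberg–Marquardt criteria; an
all-zero spectrum is reported as non-converged at the bounds rather than
fitted. When the measured spectrum peaks at a grid end point the resonance
is poorly constrained and the fit is flagged. Cohorts are summarized as
median and IQR over converged fits only; quartiles use linearly
interpolated order statistics (R's default type 7) — the convention matters
for small cohorts and is stated here because IQR values depend on it.

A known, physically real bias: an 8-cycle tapered burst does not hold the
bubble at steady state, and the band-pass filter clips part of the burst's
spectral width, so the measured $x_0$ sits a few percent below the
steady-state value near resonance. The fit absorbs this mostly into
$\kappa_s$, which end-to-end simulations recover ~15–20% high, while $\chi$
(set by the peak location, not height) recovers within a few percent. Fits
to noise-free steady-state spectra recover both parameters to machine
precision, which separates the estimator from the burst physics.

## Nonlinear response classification

R–t spectra are computed as magnitude FFTs of the mean-removed excursion in
dB (20·log₁₀, amplitude normalized so an on-grid sinusoid of amplitude $a$
metres peaks at $20\log_{10}a$). No window is applied — the records are
short transients — and spectra are zero-padded 4× because the native bin
width (~133 kHz) is coarse relative to the 300 kHz analysis bands. The
bubble's noise floor in a band is the median in-band amplitude of the
baseline recording's FFT; the median is robust to isolated spikes, and an
in-band (rather than global) floor is used so the criterion adapts to
coloured noise. A harmonic is detected in a recording when the 300 kHz band
centred at $\tfrac12 f_T$ (subharmonic) or $2 f_T$ (second harmonic)
contains a local maximum at least 6 dB above that floor; local maxima are
strict against the preceding bin and plateaus take the lowest-frequency
bin. A bubble is classified as exhibiting the behaviour when at least two
recordings of the session show a detection. The harmonic amplitude is the
maximum in-band amplitude minus the fundamental amplitude (the maximum in
an equally wide band around $f_T$), a dB difference in which any absolute
calibration cancels.

## Stability and population variability

Deflation is $(D_0 - D_{end})/D_0$ with $D_0$ the mean diameter over all
frames of the baseline recording and $D_{end}$ the mean over the last ten
frames of the last recording; a growing bubble gives a negative value,
reported with a warning rather than clipped. The variability grid is the
IQR of $x_0$ (in %) per transmit frequency and 0.5 µm diameter bin; bins
are right-open and aligned to multiples of the width, and a cell is
reported only when it holds more than three bubbles (N > 3, i.e. at least
four). The grid summary is the maximum and median over populated cells.

## Coating quantification

The coating is analyzed on a sphere fitted to the red (lipid-dye) channel:
an intensity-weighted algebraic least-squares sphere through the
above-Otsu-threshold voxels, run twice — the second pass restricted to a
band of ±3 voxels around the first sphere so that bright off-shell
structures (buckles) cannot bias the geometry. On synthetic shells the fit
recovers centres to well under a voxel and radii to well under 1%.

The sphere is subdivided into 32 parts: 4 polar bands bounded at equal
steps in $\cos\theta$ crossed with 8 azimuthal sectors. All parts then have
area $4\pi R^2/32$, so area-based scores are quantized in uniform steps of
3.125%. Mean green and red intensities per part are taken over voxels
within ±half a band thickness (default 3 voxels) of the fitted radius.
Parts without voxels — poles clipped by the imaged volume — are excluded
and the analyzed area reduced accordingly. All classification rules are
ratios, so no intensity calibration is needed:

* *ligand inhomogeneity*: part flagged when
  $|I_{part} - I_{median}| > \tfrac23 I_{median}$ (green);
* *LC phase*: part flagged when $I_{part\text{-}rhod} < \tfrac13
  I_{median\text{-}rhod}$ (red); LC area is the flagged-part area in µm²
  and as % of the analyzed area;
* *buckles*: 6-connected components of bright red voxels outside the shell
  band (with one voxel of clearance for sphere-fit jitter) but within 2 µm
  of it, counted when their equivalent spherical diameter is ≥ 1 µm, and
  mapped to none / single / 2–4 multiple / ≥5 extensive (the category
  boundaries are a package choice and configurable).

Depth attenuation leaves the equator of each bubble dimmer than the poles.
The correction factor of part $j$ is the global median intensity over all
parts of all bubbles in a cohort (at least 3) divided by the across-bubble
median of part $j$, per channel. Parts that a bubble's own rules flag are
excluded from these medians: a dye-excluding LC part carries no information
about laser attenuation, and at desk-scale cohorts (five bubbles) a part
that happens to be dark in three of five bubbles would otherwise receive a
nonsense factor that flips boundary parts out of the LC class. A part with
no informative cohort value borrows the median factor of its polar band,
which is legitimate because the artifact is a polar profile. On unbiased
cohorts the factors are ~1 and scores change by well under half a part.

## Synthetic data: what it emulates, and what it does not

Every generator records its ground truth in a sidecar so tests consume
truth only through it, and a seed fixes all randomness.

`simulate_rt()` integrates the oscillator ODE (deSolve's `lsoda`, relative
tolerance $10^{-9}$, maximum step 1/40 of the fastest period) driven by an
8-cycle burst whose Gaussian envelope has its −6 dB (half-amplitude)
duration spanning the 8 cycles — the taper parameter itself is a package
choice. The drive scaling is fixed by requiring that a long
constant-amplitude drive reproduce the closed-form steady-state amplitude,
which it does within 0.1% (and within 0.2% of an independent fixed-step
RK4 integration). Injected sub/second-harmonic components are added at a
stated dB level relative to the peak fundamental excursion, sharing its
envelope; Gaussian radius noise and a linear inter-recording deflation of
the resting radius complete the session model. Camera sampling is point
sampling at the frame rate; exposure blur is not modelled.

`synth_shell()` voxelizes a spherical coating (default 3 voxels thick,
0.1 µm voxels) with dye-excluding spherical-cap LC domains, green hotspot
caps, bright attached buckle balls, and a polar attenuation profile
$1 - a(1-|\cos\theta|)$. Cap centres are drawn from the 32 equal-area
part-centre directions — a quasi-uniform angular grid — under a greedy
non-overlap rule, with overlapping placement (flagged, realized coverage
recomputed from the voxelization) as fallback; the requested LC coverage is
realized by default as `round(32·f)` caps of one part quantum each. This
alignment is a deliberate design choice with a consequence worth stating
plainly: a part is classified LC only when roughly two thirds of it is
dark, so a cap that straddles part boundaries is eroded out of the count.
Grid-aligned caps make the quantized LC readout exact and stable across
seeds; under *arbitrary* rotations of the same pattern the readout can drop
by several quanta — an intrinsic property of hard threshold-on-coverage
rules, not of the generator. The suite therefore asserts exact invariance
under the partition's own symmetry (45° rotations about the polar axis,
which permute sectors) and treats general-rotation sensitivity as a
documented limitation. Consequently, passing LC-recovery tests show that
the classifier faithfully reads patterns commensurate with its partition;
they do not show that an arbitrary real domain layout is measured with
sub-quantum accuracy.

`synth_size_distribution()` draws lognormal diameters onto Coulter-style
bins (1–30 µm); percentile diameters d10/d50/d90 interpolate the cumulative
number fraction linearly between bin centres, and the span is
$(d_{90}-d_{10})/d_{50}$.

## Problem sizes and numerical tolerances

The validation suite runs at desk scale: 16-point spectra; cohorts of 100
synthetic bubbles per coating type for the noisy-recovery checks (5%
multiplicative amplitude noise, sizes uniform in 1.75–3.25 µm, parameters
lognormally scattered ~15% around the type medians); 512–1024-frame records
for steady-state checks; shells of 3.6–6.4 µm at 0.1–0.15 µm voxels
(~50³–80³ voxel stacks) and 5-replicate cohorts for the attenuation
correction. Equation-level identities are checked to $10^{-9}$ relative;
ODE steady states to 1%; filter round trips to 5%; harmonic amplitudes to
1 dB with detection exact at the 6 dB boundary; LC coverages to one part
quantum. Tie-breaks: the excursion maximum takes the first time index;
plateau FFT peaks take the lowest-frequency bin; the part assignment at
band/sector boundaries goes to the higher index (a measure-zero choice on
real data).

## Known limitations

* The linear model is blind to pressure-dependent shell behaviour;
  sessions at high drive pressure should not be fitted.
* $\kappa_s$ from burst-derived spectra carries the finite-burst bias
  discussed above; comparisons are meaningful within a protocol, not
  across different burst shapes.
* The 32-part readout quantizes areas at 3.125% and erodes domains that
  straddle part boundaries; LC percentages on real data are best read as
  lower bounds with one-quantum resolution.
* Buckle detection automates a judgement usually made manually; labels can
  be supplied to override it, and the multiple/extensive boundary is a
  convention.
* The tracker (`track_radius`) is a thresholded equivalent-area estimator
  for bright disks; it does no sub-pixel contour refinement and is not
  meant for low-contrast experimental footage.
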