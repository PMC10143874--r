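---
title: "Designing hyperpolarized pyruvate acquisitions: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing hyperpolarized pyruvate acquisitions: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpMRsim)
```

## The physical model and its assumptions

Hyperpolarized [1-¹³C]pyruvate magnetization is a finite resource. After
injection it decays irreversibly with T₁, is partially consumed by every RF
excitation, and is transferred to lactate at the apparent first-order rate
k_PL. hpMRsim models this as **two chemical pools in one physical
compartment**: the state vector holds the transverse and longitudinal
magnetizations of pyruvate and lactate, and free evolution over an interval
`dt` is the matrix exponential of a rate matrix acting on the longitudinal
components,

$$\frac{d}{dt}\begin{pmatrix}M_{Pz}\\ M_{Lz}\end{pmatrix} =
\begin{pmatrix}-(k_{PL}+R_{1P}) & 0\\ k_{PL} & -R_{1L}\end{pmatrix}
\begin{pmatrix}M_{Pz}\\ M_{Lz}\end{pmatrix},$$

with $R_{1P} = 1/T_{1P}$, $R_{1L} = 1/T_{1L}$. The assumptions baked in:

- **Unidirectional exchange.** The reverse rate k_LP is omitted; in vivo the
  large unlabeled lactate pool makes back-conversion of labelled lactate a
  second-order effect on the timescale of one acquisition.
- **No transverse relaxation.** Transverse rows of the rate matrix are zero.
  A spoiler follows every excitation, so transverse magnetization never
  survives a TR, and T₂* blurring across the short single-shot readout is
  deliberately not modelled. This is also why the printed signal equations
  only ever involve post-excitation transverse magnitudes.
- **Spatially local kinetics.** Each voxel evolves independently; there is
  no perfusion exchange between voxels, only a shared bolus scaled by a
  per-region perfusion amplitude.

One TR applies, right to left, `expm(R·TR)`, then spoiling, then the RF
rotation; the post-rotation transverse magnitude is the acquirable signal.
The rotation axis (x) is a fixed convention — after magnitude detection the
transverse phase carries no information, so the choice is inconsequential.

## The bolus input

Arriving pyruvate is a gamma-variate: `inputFunction(fwhm, arrivalTime,
amplitude, gammaShape)`. The FWHM (default 8 s) is the only property tied to
typical in vivo bolus measurements; the gamma **shape is a free knob**
(default 4), chosen once as a realistic fast-rise/slow-decay asymmetry. The
scale parameter is solved numerically so the density's FWHM matches the
request exactly. Input is deposited into longitudinal pyruvate as a lump at
the start of each timepoint (or phase encode), the same convention the
discrete signal equations use; `bolusEvolution()` integrates the RF-free
system on a 5 ms grid with exact exponential stepping.

With the defaults (k_PL = 0.05 1/s, T₁ = 20/30 s), pyruvate peaks ≈ 11 s
and lactate ≈ 25 s after bolus arrival.

## Dynamic EPI and the CSI encode train

`simulateEPIDynamics()` implements the metabolite-specific EPI timepoint:
add the bolus increment, excite and read pyruvate (spectrally selective
pulse, spoil), evolve for `intraTR` (default 0.13 s ≈ one spectral–spatial
pulse plus one EPI readout), excite and read lactate, evolve for the rest of
the temporal resolution. Urea, when present, is an independent
non-exchanging pool with its own T₁ and flip; it never touches the exchange
pair and is excluded from all derived quantities.

`simulateCSIFrameWeights()` walks the phase-encode train of a single CSI
frame. Every encode excites **both** pools — a hard pulse is not metabolite
selective — records each pool's transverse magnitude at that k-space
location, spoils, and evolves one per-encode TR (default `temporal
resolution / (n_x n_y)` = 4.25/64 ≈ 66.4 ms for the default protocol) with
relaxation, exchange and continued inflow. Centric ordering sorts encodes by
distance from the k-space centre; ties are broken deterministically by angle
from the +kx axis (counter-clockwise), and the centre of an even axis sits
at index n/2 + 1 (DFT convention). Neither tie-break nor centre convention
affects any magnitude-PSF metric; they are fixed so runs are reproducible.

### The CSI frame start

A CSI frame's k-space weighting depends on where in the bolus the frame
opens: early (signal rising) the outer encodes are weighted *up*, which
sharpens the main lobe but throws energy into sidelobes; late (signal
falling) k-space is apodized and the main lobe broadens. The frame start is
therefore an explicit parameter (`frameStart`, seconds after bolus
arrival). The default, **16 s**, sits between the pyruvate and lactate
peaks, where both pools carry appreciable magnetization and the resulting
resolution metrics are representative of a mid-bolus preclinical frame;
with it, the default CSI frame gives pyruvate FWHM 5.53 mm / width10
13.46 mm and lactate FWHM 5.24 mm / width10 20.92 mm — the lactate pool,
replenished by conversion during the frame, decays less across encodes, so
its weighting stays flatter: narrower FWHM but much wider 10% extent.

## PSF metrics

`weightsToPSF()` zero-pads a weight map symmetrically (default factor 16),
takes the inverse DFT magnitude and peak-normalizes; `profileMetrics()`
measures the y = 0 slice. Numerical choices:

- **Zero-fill 16** plus linear interpolation between grid samples makes both
  metrics stable to better than 0.1% under factor doubling (asserted by a
  property test); metrics are quoted to 0.001 mm.
- **FWHM** is the distance between the two half-maximum crossings of the
  main lobe, walking outward from the peak.
- **width10** uses the *outermost* 10% crossings, not the main-lobe ones:
  the quantity is meant to capture how far sidelobes carry signal (bleed).
  For a flat-weighted (periodic-sinc) PSF the second sidelobe peaks at
  ≈ 0.127, so the outermost crossing sits on its outer flank — 10.81 mm for
  a 16×16, 2 mm-nominal frame whose main-lobe FWHM is only 2.42 mm.
- All-zero weight maps are rejected (the PSF is undefined), and a profile
  that never drops below a threshold within the FOV raises an
  "unresolvable width" error rather than returning a fabricated number.

The analytic Dirichlet kernel (`dirichletKernel()`) is kept in the package
as the closed-form oracle for flat weights and is compared against the
numeric pipeline in the tests.

## Protocol optimization

`snrGrid()` sweeps flip-angle pairs (default 1–90° in 1° steps) and temporal
resolutions (default {2, 3, 4, 5} s), scoring each cell by the sum of
modelled magnitude signal over an 18-timepoint run — a relative SNR that
ignores readout bandwidth and coil factors common to all cells. Structure
worth knowing: pyruvate SNR is exactly independent of the lactate flip
(lactate is downstream), and lactate SNR decreases monotonically in the
pyruvate flip because RF consumption competes with conversion. With the
default kinetics the lactate-SNR maximum sits at very low pyruvate flip,
lactate flip near 30°, temporal resolution 3 s; the pyruvate-SNR maximum
sits near 42°.

`montecarloKplSD()` measures fit precision: simulate once, add independent
zero-mean Gaussian noise to the magnitude timecourses per iteration, refit,
report the sd of estimates. The noise model is a deliberate simplification
of Rician magnitude statistics, adequate at the SNR it defaults to: when no
sd is given it is set to (peak pyruvate)/50, a typical preclinical peak SNR.
Negative noisy samples are kept (clipping would bias the fit). Estimates
pinned at an optimizer bound are excluded from the sd and a warning fires
beyond a 5% pinning rate. 500 iterations gives ≈ 3% sd stability; the
default `monteCarloConfig()` uses that.

## The inputless k_PL fit

`fitKpl()` estimates k_PL without an arterial input function: the measured
pyruvate drives the lactate equation. Signals are mapped to longitudinal
estimates through sin(flip), each excitation costs cos(flip), and the first
lactate point initializes the predicted lactate. Between timepoints the fit
uses the **exact piecewise-exponential recursion**: pyruvate is taken to
decay mono-exponentially at rate k_PL + R₁P from its measured post-pulse
value, and the lactate update is the closed-form solution of the two-pool
system over the interval, split into two segments so the lactate excitation
sitting `intraTR` after the pyruvate excitation is honoured. We chose this
over the common trapezoidal approximation of the pyruvate integral after
quantifying the trapezoid's behaviour on bolus-driven data: the measured
pre-pulse pyruvate at the end of an interval contains freshly arrived
bolus that did not contribute to conversion during that interval, and the
trapezoid (even relaxation-weighted) inherits a double-digit percent bias
from it, while the exponential recursion needs only the post-pulse value at
the interval start and is exact for lump-per-timepoint inflow. The price is
one extra fixed parameter: T₁ pyruvate joins T₁ lactate (defaults 20 s and
30 s, the simulation values) as a fixed, not fitted, constant. Both are
exposed.

The estimate itself is bounded scalar least squares on k_PL ∈ [0, 1] 1/s via
golden-section/parabolic search (`stats::optimize`, tolerance 1e-8) —
deterministic, no starting point, no stochastic restarts. Estimates within
1e-4 of a bound are flagged (`converged = FALSE`) rather than erroring;
identically zero pyruvate is an error (k_PL unidentifiable).

`fitKplMap()` normalizes by the mean of the noise-region voxels over time
(after which signal is in noise-floor units), fits the ROI-mean timecourses
once, then each ROI voxel. Voxels whose peak lactate is below `snrFloor`
(default 3) times the normalized noise level are masked out — below that,
estimates pin at bounds and the map fills with garbage.

## The digital phantom: what it emulates, what it does not

`makeDefaultPhantom()` builds a 32 mm field of view on a 1 mm grid: a
vessel strip (4 mm wide, perfusion 1.75×, k_PL 0.014 1/s) one nominal 4 mm
voxel away from a tumor disc (12 mm diameter, perfusion 1×, k_PL 0.05 1/s —
the standard simulation value, inside the 0.02–0.11 1/s range reported for
implanted tumors). Geometry and contrast are **synthetic package
constants**, selected once so that the vascular-bleed phenomenon (two
distinct lactate peaks along a vessel–tumor line under EPI, one merged peak
under CSI) is robust across noise seeds; they are not measurements of any
particular animal. The per-frame complex noise default (sd 0.002 in signal
units) puts the CSI lactate AUC around SNR 50.

`forwardImage()` evolves every fine voxel with its region's kinetics and
perfusion-scaled bolus. EPI frames are the instantaneous transverse image
band-limited to the acquisition matrix (flat k-space weighting). CSI frames
are assembled encode by encode from the DFT of the *evolving* object — the
object changes between encodes, which is exactly the mechanism that
apodizes k-space differently for pyruvate and lactate. Complex Gaussian
noise is added per frame and the magnitude taken, giving Rician statistics.
Voxel values scale with voxel area, so halving the matrix quadruples the
per-voxel signal at fixed noise — the reason coarser grids buy SNR.

Features of real data the phantom does **not** carry: motion and
respiration, coil sensitivity profiles, B₀/B₁ inhomogeneity, Nyquist ghosts
and their reference-scan correction, T₂* decay across the readout, partial
slice profiles, and vascular washout (the vessel keeps the same T₁ kinetics
as tissue). Tests passing on the phantom therefore validate the *encoding
and fitting mathematics*, not robustness to those confounds.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by choice: PSF
grids up to 16× zero-fill on 16×16 matrices, the full 90×90×4 SNR landscape
(32 400 dynamic simulations, a few seconds via the closed-form longitudinal
core, which the tests verify against the explicit 6×6 operator
composition), Monte Carlo runs of 500 iterations, and phantom series at
8×8–16×16 matrices over 18 timepoints. Every stochastic stage takes an
explicit seed and is bit-reproducible given it; nothing seeds from the
clock.

## Known limitations

- k_LP, alanine/bicarbonate pools, and multi-compartment vascular models
  are out of scope; k_PL here is the *apparent* rate under those omissions.
- The fit fixes both T₁ values; misspecified T₁L trades directly against
  k_PL, as in any inputless one-compartment scheme.
- Relative SNR compares protocols under identical readout assumptions; it
  is not an absolute SNR prediction.
- The CSI PSF depends on the frame-start parameter; quote it together with
  any metric you report.
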