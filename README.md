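# hpMRsim

Simulation, protocol optimization and pharmacokinetic fitting for
hyperpolarized [1-¹³C]pyruvate MRI.

Hyperpolarized [1-¹³C]pyruvate imaging watches injected pyruvate being
converted to lactate in real time. The magnetization is non-renewable: it
decays with T₁ and every RF pulse spends part of it, so sequence design —
flip angles, temporal resolution, and the choice between single-shot
metabolite-specific EPI and phase-encoded CSI — directly determines both the
SNR of the metabolite maps and the precision of the quantitative biomarker,
the apparent conversion rate k_PL. This package is for preclinical imaging
scientists who want to make those design choices with simulations before
spending animals and polarizer time.

## The model

The magnetization state is a 6-vector
M = (M_Px, M_Py, M_Pz, M_Lx, M_Ly, M_Lz)′ of pyruvate and lactate
transverse and longitudinal components in one physical compartment. Across
one repetition time TR,

    M_n = rot(α) · spoil · expm(R·TR) · M_{n−1},

where `rot(α)` is the RF rotation (pool-selective for spectral–spatial
pulses), `spoil` zeroes transverse magnetization, and R encodes
unidirectional two-site exchange on the longitudinal components:

    dM_Pz/dt = −(k_PL + 1/T1P) · M_Pz
    dM_Lz/dt = k_PL · M_Pz − (1/T1L) · M_Lz.

Bolus arrival is a gamma-variate input (default FWHM 8 s) deposited into
M_Pz. Default kinetic parameters are k_PL = 0.05 1/s, T1 pyruvate = 20 s,
T1 lactate = 30 s. On top of this core the package builds:

- **Dynamic EPI simulation** — per timepoint: pyruvate excitation/readout,
  an intra-timepoint delay, lactate excitation/readout, then free evolution
  to the next timepoint.
- **CSI k-space weighting** — one non-selective excitation per phase
  encode; the hyperpolarized decay and metabolic conversion across the
  centric-ordered encode train apodize k-space.
- **PSF analysis** — zero-filled inverse DFT of a k-space weight map, with
  FWHM and width-at-10%-of-max (outermost crossings, capturing sidelobe
  bleed) of the y = 0 profile.
- **Protocol optimization** — relative SNR (sum of modelled magnitude
  signal over the dynamic run) over flip-angle pairs and temporal
  resolutions, plus Monte Carlo k_PL-fit precision.
- **Inputless k_PL fitting** — the measured pyruvate drives the lactate
  equation, with flip-angle correction; ROI-averaged and voxelwise maps.
- **Digital mouse phantom** — a vessel/tumor phantom with a forward imaging
  simulator (EPI and CSI, Rician noise) that reproduces the vascular
  signal-bleed phenomenon and closes the simulate→fit loop.

## Worked example

```r
library(hpMRsim)

params <- pkParams()                      # kPL = 0.05 1/s, T1 = 20/30 s
input  <- inputFunction()                 # gamma bolus, FWHM 8 s

## dynamic metabolite-specific EPI run: 18 timepoints every 3 s,
## pyruvate 10 deg / lactate 30 deg
tc <- simulateEPIDynamics(epiProtocol(), params, input)
tc
#> SignalTimecourse: 18 timepoints over 51 s
#>   peak pyr 0.1036 @ 12 s, peak lac 0.09769 @ 21 s

relativeSNR(tc)
#>       pyr       lac
#> 0.6356723 0.9338618

## inputless fit recovers the conversion rate from the simulated signals
fitKpl(tc@pyr, tc@lac, c(pyruvate = 10, lactate = 30), tc@times)
#> KplFitResult: kPL = 0.05 1/s (residual norm 1.929e-18, 17 points)

## CSI resolution penalty: one 4.25 s frame, 8x8 at 4 mm nominal
w <- simulateCSIFrameWeights(csiProtocol(), params, input)
psfMetrics(w$pyruvate)
#> PSFMetrics: FWHM = 5.529 mm, width at 10% = 13.462 mm
psfMetrics(w$lactate)
#> PSFMetrics: FWHM = 5.243 mm, width at 10% = 20.916 mm
psfMetrics(epiFrameWeights(epiProtocol(matrixSize = c(16, 16), fov = 32)))
#> PSFMetrics: FWHM = 2.416 mm, width at 10% = 10.796 mm
```

The CSI frame is nominally 4 mm resolution, but signal decay across the
phase-encode train broadens the effective FWHM to ~5.5 mm and spreads >10%
sidelobes over ~2 cm — the mechanism behind vascular signal bleeding into
adjacent tumor voxels. The single-shot EPI frame keeps the ideal
periodic-sinc PSF of its 2 mm grid.

A command-line surface wraps the same functionality
(`inst/cli/hpmrsim <psf|optimize|simulate|fit|dynamics> --out dir ...`),
writing CSV/NIfTI/JSON artifacts plus a manifest per run.

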