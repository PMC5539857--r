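---
title: "Quantitative microultrasound tissue characterization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative microultrasound tissue characterization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qusim)
```

## The problem

High-frequency (micro)ultrasound of the gastrointestinal wall resolves the
mucosa and submucosa, the layers where pre-cancerous disruption typically
begins. Beyond the qualitative B-mode image, calibrated pulse-echo data
supports *quantitative* ultrasound (QUS): per-A-line estimates of acoustic
impedance $Z_t$, attenuation $\alpha$, and backscatter coefficient $\mu_B$,
which are physical tissue properties rather than display intensities. qusim
implements that analysis chain end to end — a pulse-echo simulator of layered
phantoms that plays the role of the scanner, a digital segmentation of the
mucosa/submucosa band, the three estimators, the acoustic-output arithmetic
for a miniature focused therapy transducer, and the transepithelial
electrical resistance (TER) analysis used to quantify barrier-function
response to insonation.

Because the estimators are exercised exclusively on synthetic scans with
exported ground truth, every number the package produces can be checked
against the configuration that generated its input.

## Estimation model

**Impedance.** At normal incidence, the echo from the coupling–tissue
interface has amplitude $V_r = V_i (Z_t - Z_w)/(Z_t + Z_w)$, where $Z_w$ is
the impedance of the imaging medium and $V_i$ the incident amplitude.
Inverting,
$$Z_t = Z_w \frac{V_i + V_r}{V_i - V_r}.$$
$V_i$ is not observable directly; it is calibrated by imaging a flat
reflector of known impedance (fused quartz, default $Z_q = 13.1$ MRayl in
water/dPBS at $Z_w = 1.48$ MRayl) and inverting the same relation,
$V_i = V_{r,q} (Z_q + Z_w)/(Z_q - Z_w)$. The calibrate→estimate round trip is
an exact identity in noiseless arithmetic, and the test suite asserts it.
Per scan, $V_r$ is taken per line as the peak envelope of the ROI
top-surface echo within a short window (default 0.2 mm) below the ROI top;
the amplitude picker is a package choice and is configurable.

**Attenuation.** With a reference reflector under a homogeneous slab of
thickness $d$ (substitution method),
$$\alpha = -\frac{20}{2d}\,\log_{10}\frac{V_r}{V_a} \quad \text{(dB mm}^{-1}\text{)},
\qquad a' = \alpha / 8.686 \quad \text{(Np mm}^{-1}\text{)},$$
where $V_a$ is the reflector echo without tissue. The relation ignores the
interface transmission losses of the real experiment; the simulator includes
them by default and offers a switch to disable them, which is the
configuration under which the estimator recovers the configured slab value
exactly. The dB and neper scales are stored side by side and are exactly
consistent by construction.

**Backscatter coefficient.** Per gated A-line,
$$\mu_B = \frac{R_q^2}{2\pi(1-\cos\theta_T)}
\cdot \frac{\int_{t_1}^{t_2} |V_s(t)|^2\,dt}{\int |V_q(t)|^2\,dt}
\cdot \frac{4a'}{e^{-4a'd_1} - e^{-4a'd_2}},$$
a product of transducer geometry ($R_q$ the quartz reflection coefficient,
$\theta_T$ the half-angle subtended by the transducer face at the focus),
the gated sample energy normalised by the full-window quartz reference
energy, and attenuation compensation over the tissue depth span
$[d_1, d_2]$. The grouping of the three factors is fixed as written and the
internal consistency check is the $a' \to 0$ limit of the last factor,
$1/(d_2 - d_1)$: the numerical path at $a' = 10^{-9}$ agrees with the limit
to at least six significant digits. Integrals are discrete sums times the
sample period; the reference gate is the full recorded reference window.
Attenuation entering the compensation is *pre-calculated* (from separated
homogeneous slabs), mirroring ex vivo practice; in-vivo attenuation
estimation is out of scope.

**Aggregation.** Estimates are computed per A-line, then summarised as mean
and standard deviation across lines. The default is the population (n)
standard deviation, switchable to sample (n−1); lines whose ROI is empty are
skipped and counted, never silently imputed.

## Segmentation

The mucosa/submucosa ROI is isolated from the envelope image (per-line
analytic-signal magnitude, computed via the FFT construction, normalised to
the brightest pixel of the whole scan and log-compressed) in four steps:

1. *Threshold* at −26 dB relative to the brightest echo. The comparison is
   inclusive (a pixel exactly at the threshold belongs to the echo region)
   and the reference is the scan-wide maximum, not a per-line maximum.
2. *Closing* with an elliptical structuring element, default radii 3 samples
   (axial) × 2 lines (lateral). The mask is padded with background by the
   kernel radius before the operation so the closing has infinite-plane
   semantics; this makes it provably extensive and idempotent, which the
   property tests verify over thousands of random masks.
3. *Largest-region selection* under 8-connectivity (configurable to 4). The
   number of regions before selection is recorded. Depths are converted as
   `depth = depth_origin + sample_index · c_assumed / (2 · f_s)` with 0-based
   sample indexing, measured from the transducer-side image top, using the
   assumed sound speed stored in the scan metadata.
4. *Masking*: RF outside the ROI is zeroed; inside it is bit-identical to the
   source, making mask application idempotent.

Variable-thickness analysis trims each line's ROI from its own top surface
down to a fixed thickness; lines with thinner ROIs keep their full ROI.

## The synthetic-data generator

The simulator is a discrete single-scattering model, not a wave solver: no
diffraction, focusing, nonlinearity or multiple scattering. Each A-line
contains specular interface echoes (round-trip delay from the cumulative
path over per-layer sound speeds; amplitude from the interface reflection
coefficient, optional down/up transmission products, and the round-trip
attenuation $10^{-2\alpha d/20}$ per traversed layer) plus diffuse speckle
from Poisson-placed point scatterers with zero-mean Gaussian amplitudes
whose variance is the layer's backscatter strength — the simplest model that
yields developed speckle with a controllable expected backscattered energy,
which is exactly what the $\mu_B$ estimator needs. Additive white Gaussian
noise on the RF stands in for thermal noise. Identical configuration and
seed give bit-identical output, including the on-disk CSV/JSON container.

Default study conditions: a 48 MHz transmit pulse with 50% fractional
bandwidth sampled at 400 MHz (the scanner's bandwidth and sampling rate are
design choices of this package, declared rather than inferred); 61 lines at
0.5 mm pitch spanning a 30 mm scan; coupling medium at 1.48 MRayl and
1480 m/s with a 2 mm standoff; mucosa (1.60 MRayl) and submucosa
(1.55 MRayl) layers of 1.5 mm each at 1540 m/s with one-way attenuation
1.86 dB/mm; a stiff-agar substrate at 1.58 MRayl; fused-quartz reference at
13.1 MRayl. Scatterer density defaults to 200 mm⁻² with a backscatter
strength (4×10⁻⁴) placing the speckle plateau roughly 12 dB below the
brightest pixel, i.e. comfortably inside the −26 dB segmentation window —
the regime in which tissue parenchyma is actually segmentable. With these
defaults the −26 dB mask overlaps the true tissue band with IoU ≈ 0.97; the
residual disagreement is pulse-length smear at the band edges.

What the generator does *not* emulate: depth-dependent diffraction and
focal gain, electronic time-gain compensation, frequency-dependent
attenuation (a single $\alpha$ per layer is applied to the whole pulse),
anisotropic or structured scatterers, and refraction at oblique interfaces.
Passing tests therefore demonstrate correctness of the estimators under the
stated forward model, not robustness to every artefact of a physical
scanner.

Exact-recovery checks use two special configurations: a *specular* phantom
(scatterer density 0) for impedance, so the surface-echo peak is
uncontaminated by speckle, and *impedance-matched diffuse* phantoms (all
layers and substrate at 1.48 MRayl) for relative backscatter, so the signal
is pure speckle. On the speckled default phantom the surface-peak picker is
biased upward by a few percent — speckle adds to the max within the surface
window — which is a property of the measurement, not a defect of the
estimator; the same bias direction is expected on real scans.

## Transducer acoustic output

For the 4 MHz miniature focused transducer, the electrical input power of a
sinusoidal drive into a resistive load is $W_\mathrm{input} = V_{pp}^2/(8Z)$
— the only dimensionally consistent reading of the drive arithmetic, and the
one that reproduces the measured input-power column with a single constant
impedance. That constant, 49.25 Ω, was fitted once by least squares to the
ten (drive voltage, input power) pairs of the bundled characterization
dataset and is shipped as a documented, overridable constant
(`focused_transducer_impedance`); the electrical impedance at the drive
frequency was never measured directly. Efficiency is
$100\,P_\mathrm{ac}/W_\mathrm{input}$; intensity is the spatial average over
the −6 dB beam disc, $P_\mathrm{ac}/[\pi (D/2)^2]$; the mechanical index is
the regulatory form $p\,[\mathrm{MPa}]/\sqrt{f\,[\mathrm{MHz}]}$ without
derating, appropriate for water-tank characterization. Radiation-force-
balance masses convert through a manufacturer calibration factor, with the
physics default $g \cdot c_\mathrm{water}(T)$ (Marczak sound-speed
polynomial) when none is supplied. Rows whose acoustic power was below the
balance's resolution carry absent efficiency and intensity; any row implying
efficiency above 100% is flagged, never silently accepted.

## TER barrier-function analysis

TER is the blank-corrected, area-scaled meter reading
$(\mathrm{Res} - \mathrm{Res}_\mathrm{control}) \times \mathrm{Area}$,
with a default membrane area of 1.13 cm² (12-well insert format,
configurable). A monolayer counts as an acceptable small-intestine barrier
model when TER lies in 500–1000 Ω cm², inclusive on both ends. The baseline
is the mean of all pre-insonation samples — more robust than a single
initial reading and identical to it when the window holds one sample. The
drop statistic is $100(\mathrm{baseline} - \min \mathrm{TER})/\mathrm{baseline}$
over the post-baseline record, and recovery is the first time after the
minimum at which TER is back within 1% of baseline (configurable).

The generator's insonation response is a step drop at insonation onset with
exponential return, the time constant chosen so the trace re-crosses the
recovery tolerance exactly `recovery_time` minutes later. Two sources of
randomness are separated deliberately: well-to-well variability of the drop
fraction (default CV 0.20) and additive measurement noise (default
2 Ω cm²). Recovery studies of the *mean* drop use the well-to-well channel
with measurement noise off, because a minimum-based drop statistic is
upward-biased under additive noise — the minimum of a noisy flat trace sits
below its mean — and that bias does not shrink relative to the standard
error as replication grows. The per-arm means therefore estimate the
configured truths without bias, and the three-arm ordering
(microbubbles only < ultrasound only < ultrasound + microbubbles) is a
property of the configured means, recovered by the analysis rather than
asserted.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 61-line scans (about
61 × 3000 RF samples), two diffuse phantoms for the backscatter ratio, 1000
random 16 × 24 masks for the morphology properties, and 50 wells per TER
arm; these sizes make every stochastic check tight (ratios within 10%,
means within 3 SEM) while the whole suite runs in well under a minute.
Larger scans are generated by code on demand; nothing is stored.

## Known limitations

* The forward model is single-scattering with straight-ray geometry; no
  diffraction, focusing or frequency-dependent attenuation.
* The impedance picker reads the first-interface echo only; layered tissue
  below the surface does not influence $Z_t$.
* $\mu_B$ is reported on the relative scale implied by the adopted grouping;
  cross-instrument absolute comparisons would additionally require a
  diffraction correction, which is out of scope.
* The impedance-vs-thickness curve is reported, not interpreted: whether a
  rising trend reflects tissue density or gating effects is left open.
* No inferential statistics are attached to the TER arm comparison; the
  package reports per-arm summaries only.
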