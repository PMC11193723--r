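---
title: "Methods: neuronal energy fitness under shifting lactate/glucose availability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuronal energy fitness under shifting lactate/glucose availability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Activated microglia reprogram their metabolism toward glycolysis and can
transiently raise the lactate/glucose (Lac/Glc) ratio of inflamed brain
tissue. This package asks the downstream question: over which substrate
conditions and energy demands can a neuron keep itself energetically fit?
It combines a reduced kinetic model of single-neuron energy metabolism
with the measurement pipelines used around such experiments — gamma-band
local-field-potential (LFP) spectra, oxygen microsensor profiles,
plate-assay standard curves, comparative-Ct expression, and automated
microglia counting — plus synthetic-data generators that make every stage
testable against known ground truth.

## The kinetic model

The model tracks a cytosolic and a mitochondrial compartment with 15
states: cytosolic glucose, pyruvate, lactate, ATP/ADP, NADH/NAD+;
mitochondrial ATP/ADP, NADH/NAD+, an FADH2-equivalent pool; the
mitochondrial membrane potential $\Delta\Psi$, the transmembrane pH
gradient $\Delta$pH, and matrix Ca$^{2+}$. Adenine and NAD pools are
conserved per compartment by construction (paired derivatives), as is
total FAD.

Reactions are lumped to the coarsest structure that preserves every
input, output and conserved pool of neuronal energy metabolism:

* **GLUT transport** — saturable gradient-driven carrier, so glucose
  influx is non-negative whenever extracellular exceeds cytosolic
  glucose.
* **Glycolysis** — upper (ATP-investing) and lower (ATP/NADH-producing)
  stages composed at quasi-steady state into a single flux per glucose
  (2 ATP invested / 4 produced, 2 NADH), requiring ATP, ADP and NAD+.
  No explicit triose intermediate is carried; at steady state the two
  stages run at equal rate anyway.
* **LDH** — reversible mass action toward its equilibrium constant
  (lactate side favored, $K'_{eq} = 9000$ at the fixed cytosolic pH);
  the rate constant is large because LDH operates near equilibrium.
* **MCT2** — H$^+$-coupled saturable carrier; the fixed pH difference
  (7.3 outside, 7.0 inside) weights the outward-facing lactate term.
  Intracellular pH dynamics are out of scope.
* **Pyruvate oxidation + citric acid cycle** — one Ca-activated flux:
  4 NADH + 1 FADH2 per pyruvate.
* **NADH shuttles** — malate–aspartate (into matrix NADH) and
  glycerol-3-phosphate (into FADH2), coupling the cytosolic and
  mitochondrial redox pools.
* **Respiratory chain** — NADH-fed (10 H$^+$) and FADH2-fed (6 H$^+$)
  proton pumping with Michaelis O$_2$ dependence ($K_m \approx 1$ mmHg,
  so the standard 60 mmHg is saturating) and a sigmoidal $\Delta\Psi$
  back-pressure.
* **ATP synthase** (3 H$^+$/ATP, driven by the proton-motive force
  $\Delta\Psi + 61.5\,\Delta\mathrm{pH}$ mV), **ANT** (electrogenic, one
  charge per exchange), and an exponential **proton leak**.
* **Energy demand** — a single ATPase,
  $v_{ATPase} = k\,\mathrm{ATP}/(\mathrm{ATP} + K_m)$; raising $k$
  raises demand.

$\Delta$pH relaxes toward a fixed fraction (20%) of the $\Delta\Psi$-
equivalent proton-motive force rather than carrying its own ion budget:
cation/anion electrophysiology beyond the lumped leak is out of scope,
and the fixed partition reproduces the usual 75–80% $\Delta\Psi$ share.
Matrix Ca$^{2+}$ is a fast quasi-steady modulator of the citric acid
cycle driven by $\Delta\Psi$; nothing in the inputs drives Ca transients,
so a dynamic Ca protocol would be unidentifiable here.

### Calibration protocol

No rate constants are printed for the original molecularly-resolved
model, so this reduction is calibrated by construction, in three frozen
steps (values in `inst/params/default_parameters.yaml`):

1. Capacities are scaled so the steady state on 5 mM glucose / 0 mM
   lactate at low demand holds cytosolic ATP near 2.5 mM (adenine pool
   2.5 mM) with an oxidative ATP yield of ~26–30 per glucose.
2. The named demand levels are fixed fractions of the maximal steady
   ATP turnover on 5 mM glucose (`t_max_atp`, 0.4807 mM/s): 10% (low),
   45% (intermediate), 85% (high). `max_atp_turnover()` recomputes the
   frozen value.
3. One free global scaling of MCT2 capacity (`mct_vmax = 0.045` mM/s)
   was chosen so that the two glucose-fitness thresholds *emerge* from
   the model; they are outputs checked by the acceptance tests, not
   inputs.

Two calibration choices deserve comment. The effective MCT2
half-saturation is 3 mM rather than the textbook ~0.7 mM of the isolated
transporter: the lumped carrier absorbs diffusion and LDH limitation,
and — decisively — a low-$K_m$ carrier saturates its export side, so at
high glucose *and* high external lactate glycolytic overflow exceeds the
export ceiling and no steady state exists (cytosolic lactate grows
without bound). The 3 mM carrier keeps export headroom everywhere on the
phase map. Second, the energy-deficit criterion is hard-coded at
cytosolic ATP < 1 mM (configurable via `atp_min` for sensitivity
analyses).

### Steady-state numerics

`steady_state()` alternates stiff integration (lsoda, starting at a
1000 s horizon and doubling while slow modes persist — the FAD pool
near collapse boundaries relaxes over hundreds of seconds) with damped
Newton refinement on the reduced system (conserved partners removed so
the Jacobian is non-singular), and finally approaches from the
de-energized side if the energized start crawls past a saddle-node
ghost. Convergence requires the full right-hand side below $10^{-9}$ in
native units; non-convergence is a classed error carrying the last
state, never a silent partial result. Both documented initial states
(energized / de-energized) reach the same steady state to $10^{-6}$
relative on the tested conditions — the model is monostable there, so
phase-map cells are initial-condition-independent.

Bisection for the glucose-fitness threshold brackets [0, 5] mM to a
0.01 mM width (13 steady-state solves including bracket checks and the
final monotonicity verification across the bracket). Ties to the
phase maps: sweeps warm-start each cell from its neighbor along the
glucose axis, with a cold retry on any failure, and abort only if more
than 20% of cells fail.

With the frozen calibration the thresholds at 5 mM lactate come out at
0.249 mM (intermediate demand) and 1.450 mM (high demand) — the same
values the acceptance script recomputes — and 0 at low demand (fit on
lactate alone). The acceptance checks fix lactate at 5 mM, the top of
the swept range and hence the most conservative reading of a
lactate-independent glucose floor; the floor is verified, not assumed,
to be non-increasing in lactate on a 1/3/5 mM grid.

## LFP spectral chain

The analysis chain mirrors standard field-potential practice: data
segments are low-pass filtered (digital Butterworth, 200 Hz corner;
order 4 — a common electrophysiology choice since the order is not
dictated by the corner alone — applied forward–backward for zero
phase, with odd-reflection padding against edge transients), then
reduced by Welch's method with a Hamming window of 8192 samples (bin
width 1.2207 Hz at 10 kHz), 50% overlap and per-segment mean
detrending. Density normalization satisfies Parseval, so a
unit-amplitude sinusoid integrates to 0.5 mV².

Features: peak frequency and power are the in-band PSD maximum (search
band 20–100 Hz, wide enough that sub-gamma peaks are measurable yet
classifiable); FWHM interpolates the two half-maximum crossings
linearly, reporting a flagged band-limited width when a crossing is not
reached; equal maxima resolve to the lower frequency. A trace counts as
a gamma oscillation when peak frequency exceeds 24 Hz and peak power
exceeds $10^{-4}$ mV²/Hz. Paired pre/post comparisons report
per-feature fold changes, and `cohort_paired_t()` is a thin harness
over the paired t test.

The synthetic generator plants an amplitude-modulated sinusoid (slow
Gaussian envelope, 4 Hz bandwidth — giving a controllable peak and a
realistic FWHM of a few Hz) over spectrally shaped $1/f^{\alpha}$
noise. The default oscillation amplitude (0.1 mV, peak density
~$10^{-3}$ mV²/Hz) sits above the classification threshold by design;
the recording amplitude scale is a generator choice, not a measured
value. What these fixtures do *not* emulate: non-stationary frequency
drift, harmonics, line noise, or spike contamination — pipeline
robustness to those is untested.

## Bench-data reductions

Standard curves regress signal on concentration (quadratic for the
IL-6 ELISA, linear for nitrite and lactate), verify monotonicity over
the standards' range, and invert only in-domain (selecting the
in-domain quadratic root; out-of-range signals refuse to extrapolate).
The regress-then-invert direction is a convention of this
implementation; plate-reader software does not document its internal
parameterization. Dilution ladders reproduce the kit series (8000 pg/mL
two-fold eight-point; 80 µM nine-point; 1000 µM six-point, with 1:5
sample dilution folded in at inversion).

Oxygen sensors calibrate linearly against 0/20/95% saturation
solutions (warning below r² = 0.99, drift flag at >10% slope change
between pre/post calibrations). Depth geometry: a 20 µm advance at 55°
descends 16.38 µm per step (printed as ~16 µm); six steps span 98.3 µm,
matching the 80–96 µm core depths. The slice core is the profile
minimum; ties resolve shallow with a flag, and a minimum at the last
step is flagged as possibly not reached.

Comparative Ct uses beta-actin as endogenous control and the control
group as reference; per-sample loading offsets cancel exactly. Heatmap
z-scores use the sample (n−1) standard deviation — matching common
heatmap software — and clustering is Euclidean/Ward ("ward.D", the
classic unsquared-distance update); constant rows are zeroed and
flagged.

## Microglia counting

The counting chain follows the published macro order exactly:
z-projection (maximum intensity; mean available) → background
subtraction on the Iba1 projection only (grayscale opening with a 50 px
disc standing in for the rolling ball; the radius is configurable since
the original is not printed) → "default dark" automatic threshold
(iterative intermeans on a 256-bin histogram, foreground strictly above
threshold — invariant to constant offsets) of the DAPI projection →
dilation of the nuclear mask (5 px default) and gating of the Iba1
image → second intermeans threshold → despeckle (3×3 median) and
bright-outlier removal → particle counting at 8-connectivity with a
400 px minimum area. The cutoff is implemented as a *minimum* (its
stated purpose is excluding small specks where other nuclei touch
microglial ramifications); particles are counted, not measured further.

Synthetic stacks render nuclei as Gaussian blobs (sigma = half the
soma radius), microglia as a soma disk plus 3–5 line ramifications at
8-bit intensities, distributed across slices with a Gaussian axial
profile. Somata are kept at least three radii apart so dilated masks
stay disjoint; ramifications may approach foreign nuclei — exactly the
speck case the cutoff removes. Not emulated: optical PSF blur, uneven
illumination, overlapping/touching cells, so the planted-count accuracy
(exact on all 50 default-noise test stacks) is an upper bound on
real-data performance.

## Problem sizes and budgets

Defaults keep everything desk-scale: phase maps 11×11 cells per demand
level (~2 minutes for all three), thresholds 13 solves each (~6 s),
LFP fixtures 1.5–3 s at 10 kHz, image stacks 320×320×6. The full test
suite runs in about 3 minutes.

## Known limitations

A single neuron with fixed extracellular conditions: no tissue
gradients, no oxygen co-variation (pO$_2$ fixed at 60 mmHg), no
astrocyte or microglia compartments, no gene-expression dynamics. The
reduction's absolute fluxes are calibrated, not measured; only the
emergent qualitative regimes and the two glucose thresholds are
anchored. Ramification morphology is not quantified, and the LFP
pipeline deliberately omits time–frequency analysis.
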