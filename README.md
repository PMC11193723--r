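# neuroenergetics

Activated microglia shift their metabolism toward glycolysis and can
transiently raise the lactate/glucose ratio of inflamed brain tissue.
Whether nearby neurons stay energetically fit then depends on how much
glucose remains available and how hard the neuron is working. This
package is for computational neuroscientists and neuroimmunologists who
want to explore those boundary conditions quantitatively and to process
the accompanying bench readouts: it provides

* a **reduced kinetic model of single-neuron energy metabolism**
  (glycolysis, citric acid cycle, NADH shuttles, respiratory chain,
  oxidative phosphorylation, mitochondrial electrophysiology, MCT2
  lactate transport, LDH) with steady-state solution and flux
  extraction;
* a **sweep engine** producing phase diagrams of glucose influx,
  lactate flux and cytosolic ATP over extracellular glucose × lactate
  at three energy-demand levels, with bisection for the minimal glucose
  concentration sustaining energy fitness;
* the **gamma-oscillation LFP chain** (zero-phase Butterworth low-pass,
  Welch power spectra, peak/FWHM features, oscillation classification,
  paired substrate-switch comparison);
* **bench-data reductions**: plate-assay standard curves with monotone
  inversion, oxygen microsensor calibration and depth profiling,
  comparative-Ct (2^-ddCt) expression, heatmap row z-scores with
  Euclidean/Ward clustering;
* an automated **two-channel microglia counting** pipeline (DAPI-gated
  Iba1 particle counting);
* **synthetic-data generators** with known ground truth for every input,
  so all stages are testable without any external data.

## The model in brief

Energy demand is a single ATPase,

    v_ATPase = k * ATP / (ATP + Km),

and demand levels are fixed fractions (10 / 45 / 85 %) of the model's
maximal steady ATP turnover on 5 mM glucose. A neuron is in *energy
deficit* when steady-state cytosolic ATP falls below 1 mM. Lactate
enters through an H⁺-coupled MCT2 carrier and reaches the citric acid
cycle via reversible LDH; cytosolic NADH reaches the chain through the
malate–aspartate and glycerol-3-phosphate shuttles; the respiratory
chain pumps 10 (NADH) / 6 (FADH2) protons with saturable O₂ dependence
(60 mmHg is saturating); ATP synthase and the adenine nucleotide
translocator close the phosphate loop against the proton-motive force
ΔΨ + 61.5·ΔpH. Pools (adenine, NAD per compartment, FAD) are conserved
exactly. See the methods vignette
(`vignettes/neuroenergetics-methods.Rmd`) for rate laws, the
calibration protocol and numerical details.

## Worked example

```r
library(neuroenergetics)
p <- default_parameters()

# A resting neuron on 5 mM glucose: fit, and a net lactate exporter.
ss <- steady_state(p, external_conditions(glc_ext = 5, lac_ext = 0),
                   demand_level("low", p))
ss$state[["atp_cyt"]]   # 2.489  (mM cytosolic ATP: well above the 1 mM deficit line)
ss$fluxes$j_lac         # +0.0020 (mM/s; positive = lactate release)

# Withdraw glucose but supply lactate: still fit at low demand ...
steady_state(p, external_conditions(0, 5),
             demand_level("low", p))$state[["atp_cyt"]]   # 2.487

# ... but at high demand fitness requires a glucose floor:
glucose_threshold("high", lac_ext = 5, params = p)$glc_star
# 1.450  (mM: below this, ATP collapses despite abundant lactate)

# Gamma-oscillation features of a synthetic 10 kHz field potential:
tr <- gen_lfp(lfp_spec(duration_s = 3, osc_freq_hz = 40, seed = 11))
ft <- extract_features(welch_psd(lowpass_200(tr)))
c(ft$peak_freq_hz, ft$peak_power, ft$fwhm_hz)
# 40.28 Hz   3.35e-03 mV^2/Hz   1.79 Hz      (1.2207 Hz frequency bins)
classify_gamma(ft)      # TRUE: > 24 Hz and > 1e-4 mV^2/Hz
```

The numbered scripts under `analysis/` run the full workflow — phase
diagrams (`01`), glucose-fitness thresholds across lactate levels
(`02`), a paired substrate-switch LFP cohort with oxygen profiles
(`03`), plate/qPCR/heatmap reductions (`04`) and counting accuracy
(`05`) — writing tables under `results/`.

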