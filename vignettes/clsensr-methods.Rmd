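---
title: "Models and methods behind clsensr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clsensr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clsensr)
```

`clsensr` simulates and analyzes two-wavelength ratiometric imaging of the
genetically encoded chloride indicator Cl-Sensor (CFP fused to the
chloride-quenched YFP variant YFP_Cl). This vignette documents the models,
the parameters that matter, the numerical choices, and — importantly — what
the synthetic data do and do not emulate.

## 1. Sensor photophysics

**Chloride quenching.** YFP_Cl emission is scaled by
$$Q(\mathrm{Cl}) = q_r + \frac{1 - q_r}{1 + (\mathrm{Cl}/EC_{50})^{h}},$$
with Hill exponent $h = 1$ and unquenchable fraction $q_r = 0$ by default:
a single halide binding site, fully quenchable. $Q$ is 1 at zero chloride
and strictly decreasing.

**Apparent EC50 is a per-configuration quantity.** In vitro values for
YFP_Cl are 30–50 mM, but the apparent in-cell value is shifted by pH,
organic anions and ionic strength. The neuron calibration configurations
use the value implied by the sensor's measured ratio dynamic range
(0.7 ratio units at 5 mM, 4.0 at 150 mM): with the 430 nm channel's YFP
share fixed at $\alpha = 0.287$, the two anchor ratios form a 2×2 linear
system whose closed-form solution (`solve_calibration_scale()`) gives
$EC_{50} \approx 18.4$ mM and a zero-chloride ratio $R_0 \approx 0.586$.
The neuroblastoma (N2a) configurations use 50 mM, the top of the in vitro
band; see §3 for why the upper end is the coherent choice there. We do not
attempt to reconcile the two scales — the apparent EC50 genuinely differs
between cellular contexts, and each canned configuration carries its own
value.

**Channel composition.** The 500 nm excitation sees only YFP_Cl:
$F_{500} \propto X \, Q_r (1-d_{430})(1-d_{500})$, where $X$ is expression,
$Q_r = Q(\mathrm{Cl})/Q_\mathrm{ref}$ is the quench factor relative to the
configuration's resting reference state, and the $d$ terms are dark
fractions (below). The 430 nm excitation mixes photostable,
chloride-insensitive CFP with a YFP share $\alpha$:
$F_{430} \propto X\,[(1-\alpha) + \alpha\, Q_r (1-d_{430})(1-d_{500})]$.
$\alpha = 0.287$ is the ratio of the two channels' fractional responses to
the same chloride load (6.2/21.6). Any FRET contribution to the 430 nm
channel is absorbed into $\alpha$ rather than modelled separately. CFP is
treated as perfectly photostable.

**Photoinactivation (dark states).** Each excitation wavelength drives its
own reversible dark pool. An illumination event of duration $t$ and
relative intensity $i$ delivers dose $t \cdot i$ (reciprocity) and advances
the pool by a saturating exponential,
$d' = d + (f_\mathrm{max} - d)\,(1 - e^{-ti/\tau_\mathrm{inact}})$; in
darkness each pool relaxes as $e^{-\Delta t/\tau_\mathrm{rec}}$. The two
pools act multiplicatively on the YFP signal. The defaults are *derived by
root-finding* from two measured inhibition fractions per wavelength
(`derive_inactivation_params()`):

| pool | anchor points | $f_\mathrm{max}$ | $\tau_\mathrm{inact}$ | $\tau_\mathrm{rec}$ |
|------|----------------|------------------|----------------------|---------------------|
| 430 nm | 2.8% @ 20 ms, 30% @ 1 s | 0.3023 | 0.206 s | 50 s |
| 500 nm | 0.34% @ 1 s, 3.0% @ 10 s | 0.1208 | 35.0 s | 60 s |

The recovery constants are set so the 430 nm pool is fully recovered after
a 5 min inter-pulse interval (e^(−6) ≈ 0.25% residual) while still
producing a stable 97–98% plateau under 20 ms/10 s pulsing, and the 500 nm
pool recovers within about 3 min. A single reversible pool per wavelength
cannot simultaneously reproduce a stable plateau *and* the partially
irreversible component seen after very long 430 nm exposures; an optional
slowly recovering sub-pool (`slow_pool_weight`) is exposed but defaults to
0, because the stable plateau is the behaviour the recording protocol
relies on.

**Milieu offset hook.** Cell-to-cell differences in pH/organic anions that
quench YFP independently of chloride are exposed as a per-cell
multiplicative factor on the YFP component (`yfp_scale` in the scene). It
shifts a cell's absolute ratio without changing its response kinetics and
is the source of the overlapping resting-ratio distributions in the
population configurations. No quantitative pH model is attempted.

## 2. Chloride dynamics

Each compartment integrates
$$\frac{d[\mathrm{Cl}]_i}{dt} =
   \underbrace{g\,p_\mathrm{open}(V_m - E_\mathrm{Cl})\frac{S}{V}c}_{\text{GlyR/GABA}_A}
 \; \underbrace{- \,u\,(1 - b_\mathrm{furo})\ln\frac{K_i\,\mathrm{Cl}_i}{K_o\,\mathrm{Cl}_o}\frac{S}{V}c}_{\text{KCC2}}
 \; + \underbrace{k_\mathrm{leak}(\mathrm{Cl}_\mathrm{leak} - \mathrm{Cl}_i)}_{\text{leak}},$$
with $E_\mathrm{Cl} = -59.16\,\mathrm{mV}\cdot\log_{10}(\mathrm{Cl}_o/\mathrm{Cl}_i)$
(the Nernst slope at the recording temperature), $S/V$ the
surface-to-volume ratio and $c$ an effective coupling factor. KCC2 runs
down the summed K⁺ and Cl⁻ chemical potentials: zero flux at product
equality, reverse-mode influx when bath potassium is high. NKCC1 exists in
the parameterization but is silent by default since every bath solution
carries 10 µM bumetanide. Furosemide blocks 85% of cotransport;
strychnine silences the tonic (agonist-independent) GlyR term while a
saturating 50 µM glycine application overcomes the 0.3 µM competitive
block.

**Membrane potential** is a two-parameter mixture
$V_m = w\,E_K + (1-w)\,V_\mathrm{off}$ with defaults $w = 0.7$,
$V_\mathrm{off} = 0$: about −72 mV in control saline and 0 mV under full
140 mM KCl substitution. A voltage-clamp event overrides it. Extracellular
chloride is computed from the salts (≈150.5 mM for the control saline).

**Compartments.** Soma, thin dendrite and spine differ only in effective
surface-to-volume scaling (1×, 6×, and 3× — the spine's high nominal S/V is
neck-limited, modelled as reduced coupling). Shared membrane parameters
then order recovery half-times dendrite < spine < soma, which is the
qualitative behaviour the neuron configuration targets; absolute spine
values are not calibrated.

**Integration** is fixed-step explicit Euler with dt = 0.1 s and a 0.1 mM
floor on chloride. The dynamics are non-stiff at these rates; the test
suite checks that halving dt moves no recorded point by more than 0.5%.
Determinism was preferred over adaptive stepping because the assay
estimators feed acceptance checks.

## 3. Calibrated transport constants

Four constants are not taken from tables but solved, once, against the
reference outcomes that define the respective protocols, end-to-end through
the full simulate → render → extract → estimate chain (their frozen values
live in `R/configs.R`):

* `k_leak` = ln 2 / 56.6 min: with tonic GlyR silenced by strychnine the
  only clearance path is the first-order leak, and the ratio recovery
  half-time is then exactly the leak half-time.
* `g_glyr` sets the 5 min glycine + 100 mM KCl load so the F500 channel
  drops 21.6% at its peak.
* `p_tonic` sets the control (no strychnine) recovery half-time to
  6.8 min.
* `u_kcc2` sets the KCC2 extrusion half-time after the same load to
  2.0 min.

One parameterization note: the load amplitude and the control recovery
speed jointly constrain the GlyR conductances. Because recovery at −72 mV
works against a ~20 mV driving force while loading at −6 mV enjoys ~50 mV,
the tonic pathway must carry a conductance comparable to the
agonist-recruited one. `p_tonic` is therefore a dimensionless
open-probability *scale* that may exceed 1 (the tuned value is ≈0.87 with
the agonist term at one-third occupancy); it lumps trace agonist
contamination of the saline with any constitutive gating, and should not be
read as a literal single-channel open probability. The N2a apparent EC50
of 50 mM (upper end of the in vitro band) is part of the same resolution:
smaller values make the load/recovery pair mutually inconsistent under this
membrane model.

**Ratio gain blocks.** Acquisition gains are balanced per configuration so
the resting ratio sits near 1, mirroring the experimental gain-balancing
step (performed on the *measured*, use-darkened signal — so the calibration
configuration references its target ratio to the settled dark state). The
reverse-mode influx configuration carries its own, larger gain block,
anchored once so that the reference KCC2 response equals 4.5 ratio units;
the mock and furosemide responses are then predictions through that same
scale. Absolute ratio units are not comparable across configuration
families — each assay defines its own arbitrary-unit scale, which is also
why the influx response can exceed the calibration curve's 4.0 ceiling.

The mock (no KCC2) influx response deserves a caveat: under this transport
model neither the first-order leak nor any pathway compatible with the
56.6 min leak-only recovery responds appreciably to depolarization alone,
so the simulated mock response is near zero rather than a small positive
value. The influx assay tests treat the mock as a direction check (mock ≪
KCC2; furosemide removes >70%), not a quantitative target.

## 4. Synthetic imaging

Scenes place parametric cells (disks, or axis-aligned squares) on a pixel
grid; everything outside a cell is background. The canned configurations
use square cells aligned to 8-pixel block boundaries so that every binned
camera block is pure cell or pure background — block-mean binning then
commutes exactly with ROI extraction, and the noise-free pipeline
reproduces the forward model to numerical precision (this exactness is a
tested invariant). Binning is block *mean*, not sum, so per-pixel values
are binning-invariant and exposure-based gain balancing works as in the
real workflow. Counts are floats internally and are rounded to 16-bit
integers only when writing TIFF files (saturation above 65535 is clipped
and flagged in the frame metadata). Camera noise is optional Gaussian read
noise plus a Gaussian approximation of shot noise (variance proportional to
expected counts), fully determined by a seed. Dark-state bookkeeping is
per cell and per illumination event, not per pixel; recovery runs from the
*end* of one exposure to the start of the next.

In the photoinactivation probe configurations, the conditioning pulse is
placed so that it ends 0.1 s before the next acquisition; with a 50 s
recovery constant this keeps the measured transient within ~0.2% of the
delivered dark-state increment instead of attenuating it by several
percent of recovery during a half-period gap.

**What the generator does not emulate:** optics (no PSF, no focus drift),
cell movement, per-pixel dark states, bicarbonate fluxes or volume
regulation, pH dynamics (only the static per-cell offset hook), and
photon-exact noise statistics. Passing tests therefore validate the
estimators and protocol logic, not robustness to segmentation error or
motion artifacts in real recordings.

## 5. Analysis conventions

* ROI masks live on the unbinned pixel grid (0-based, row-major, origin
  top-left); frames are aligned to that grid by block replication before
  extraction, and the background mean is subtracted per frame.
* Ratio pairing takes one R₄₃₀/₅₀₀ per acquisition cycle, timestamped at
  the cycle's first exposure; orphaned frames at stack boundaries are
  dropped with a warning count.
* `inhibition_percent` uses the mean of the last 3 pre-event samples as
  baseline; `steady_state_level` averages the last 5 samples;
  `extrusion_assay` baselines on the last 5 pre-load samples (windows
  chosen as the smallest that are robust at the 0.05 Hz cadence, and the
  pre-load tail avoids the early dark-state settling transient).
* `half_time` interpolates the midpoint crossing linearly; when the
  recording never crosses the midpoint it fits a single exponential to the
  decay above baseline and reports τ·ln 2, flagged as extrapolated. The
  extrusion peak is the *last* maximal sample in the load window, so
  recovery is timed from washout.
* The dose-response is a 4-parameter logistic in log₁₀ chloride fitted by
  Levenberg–Marquardt. Note that under the channel-composition model with
  h = 1 the true ratio is *linear* in chloride, so the fitted 4PL is an
  empirical calibration curve (its r_max is weakly identified and can be
  large); evaluation and inversion inside the calibrated range are
  accurate, and the closed-form inverse round-trips to 1e−10.
* Pearson p-values are two-tailed from the t-distribution on n−2 degrees
  of freedom; the KS test reports the exact D statistic with the
  asymptotic p-value.
* The expression filter keeps cells with baseline F430 in [1000, 8000]
  relative units, boundaries inclusive. Below this window, ratio responses
  correlate with expression; the population configuration reproduces the
  expression-independence of the ratio above it. A small negative
  correlation between baseline F430 and ratio emerges in noisy populations
  from two real mechanisms — the YFP share of F430 couples it to the
  per-cell milieu offset, and ratio-of-counts estimators carry a
  brightness-dependent bias — mirroring the weak negative correlation such
  experiments report.

## 6. Problem sizes and determinism

Canned runs use small fields (one to a few hundred 8×8-pixel cells), 20 s
acquisition cycles and 10–40 min simulated time; an end-to-end run takes
seconds. All randomness (camera noise, population heterogeneity) is
seed-controlled: configuration-level draws take a build seed, camera noise
takes a run seed, and noise-free runs are bit-reproducible with no seed at
all. `scripts/acceptance.R --seed N --out f.json` recomputes the headline
quantities from scratch at any seed.

## 7. Known limitations

* Single-exponential dark-state recovery understates the partially
  irreversible component of very long 430 nm exposures (see
  `slow_pool_weight`).
* The membrane model is a potassium-Nernst mixture, not GHK; it is only as
  good as its two anchors (−72 mV rest, 0 mV at 140 mM KCl).
* Absolute [Cl⁻]ᵢ estimates from `cl_from_ratio()` are crude by design:
  the calibration scale varies cell-to-cell (milieu offsets), so inverted
  values carry that systematic uncertainty.
* `p_tonic` is phenomenological (see §3); pharmacology of partial agonists
  and antagonist kinetics are reduced to occupancy factors and block
  fractions.
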