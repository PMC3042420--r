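---
title: "Methods: a GHK membrane simulator and whole-cell I-V pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a GHK membrane simulator and whole-cell I-V pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghkclamp)
```

`ghkclamp` studies a benzamil-sensitive, Na⁺-selective whole-cell
conductance of the kind carried by αβγ-ENaC in inner-ear and other
absorptive epithelia. Because no raw recordings are distributed for such
studies, the package is built around a synthetic-data generator whose
defaults encode the study conditions, and an analysis pipeline that treats
the generated recordings exactly as bench data. This vignette documents
the model, its parameters, the numerical choices, and what the simulations
do and do not establish about real recordings.

## The membrane model

The channel population is modelled with the GHK current equation per
permeant cation:

$$I_X(V) \;=\; P_X\, u\, \frac{[X]_i - [X]_o e^{-u}}{1 - e^{-u}},
\qquad u = \frac{zFV}{RT},$$

with the removable singularity at $V=0$ replaced by its second-order
expansion for $|u| < 10^{-6}$. $P_X$ is an *effective permeability
product* in pA/mM — membrane area, channel count and the usual $PF^2/RT$
prefactor folded into one number, so that $I(0) = P(c_i - c_o)$ for a
monovalent ion. Gating kinetics are not modelled: the analyses only ever
use a steady-state window at the end of each voltage step, so a quasi-static
current model is sufficient and every step's steady state is the
fixed point of the series-resistance loop (below).

Benzamil block is a Woodhull-type open-channel block at electrical
distance $\delta$:

$$f_\mathrm{block}(V) = \frac{B}{B + K_d(0)\, e^{\delta z_b FV/RT}},$$

monotone in $B$ and, for a cationic blocker with $\delta > 0$, stronger at
hyperpolarized potentials — which is what makes the drug-*sensitive*
difference current inwardly rectifying even when the underlying channel
I–V is nearly linear. Rundown multiplies the channel permeabilities (never
the leak) by $\mathrm{floor} + (1-\mathrm{floor})e^{-t/\tau}$.

The recorded current adds, per sample:

* an ohmic leak $g_\mathrm{leak}(V - E_\mathrm{leak})$ (seal/background;
  not blocked, no rundown);
* a capacitive transient at every command edge, one exponential of
  amplitude $\Delta V/R_s$ and time constant $R_s C_m$ (whole-cell
  dominated; no separate pipette-capacitance term);
* an Ornstein–Uhlenbeck baseline drift (slow seal/access instability);
* white recording noise.

The membrane potential seen by the channels is not the command: the
simulator solves $V_m = V_\mathrm{cmd} - \mathrm{LJP}(\mathrm{bath}) -
I(V_m)\,R_s$ at every sample (damped fixed-point iteration, loop gain
$\approx g\,R_s \approx 0.1$, converged to $10^{-7}$ mV), and the analyzer
must undo both corrections from the recorded current alone — so the
correction step is exercised end to end.

## Solutions and equilibrium electrochemistry

The nine canonical bath (B1–B5) and pipette (P1–P4) recipes are entered as
salts and dissociated into full ionic inventories; HEPES is split into its
neutral/anionic forms at the recipe pH (pKa 7.5), EGTA is carried as the
2− species, and the named pH titrant cation (NaOH/KOH/LiOH/NMDG) is added
to exact electroneutrality. Junction potentials use the Henderson
equation over these inventories with published limiting equivalent
conductivities (25 °C values used uncorrected at 37 °C — the temperature
enters through $RT/F$; mobility *ratios* change little). The sign
convention is fixed package-wide: `henderson_ljp(pipette, bath)` is the
value *subtracted* from the command potential, and the simulator and
analyzer share it through one code path.

Two checks pin this machinery down. The computed correction for the
low-Na⁺/high-NMDG⁺ pipette against the Na⁺-rich bath reproduces the
−6.9 mV value reported for that configuration to about 0.1 mV. For the
K-methanesulfonate pipette against the Na-methanesulfonate bath the
Henderson value is ≈5.7 mV, whereas 4.1 mV is the figure usually quoted
for that configuration. No physically plausible mobility table reconciles
the two: with both major salts at 150 mM and a common anion, the value is
controlled by $\ln[(\lambda_K + \lambda_X)/(\lambda_{Na} + \lambda_X)]$,
and forcing 4.1 mV would require the methanesulfonate mobility to exceed
that of Cl⁻. Quoted corrections of that kind typically fold in a
reference-electrode/agar-bridge junction change, which depends on an
unreported bridge solution; the package therefore reports the honest
two-solution Henderson value and documents the difference rather than
tuning the mobility table.

Ca–EGTA buffering is a single-site apparent-Kd equilibrium solved in
closed form (quadratic root in $[0, \mathrm{Ca_{tot}}]$). The default
apparent $K_d$ = 172.5 nM is calibrated once so the canonical pipette
recipe (0.367 mM Ca, 1 mM EGTA, pH 7.3, 37 °C) buffers to 100 nM free
Ca²⁺; full pH/Mg²⁺ speciation is out of scope. Ideal osmolarity is a
unit-coefficient particle sum — an upper-bound sanity check (it runs
~5–15 mOsm above measured values), not a measurement model.

## Default parameters and where they come from

| parameter | default | units | rationale |
|---|---|---|---|
| `P_Na` | 3.8 | pA/mM | sets symmetric-Na⁺ I(−100) ≈ −2.2 nA, g(−) ≈ 22 nS, the scale reported for these cells |
| `ratio_Li` | 1.3 | — | P_Li/P_Na of the ENaC-like channel |
| `ratio_K` | 0.002 | — | a highly selective channel (P_Na/P_K = 500, consistent with "> 80" and with unmeasurably small K⁺ currents) |
| `ratio_NMDG` | 0 | — | NMDG⁺ as the impermeant substitute |
| `Kd0` | 0.3765 | µM | calibrated (see below) |
| `delta`, `z_blocker` | 0.3, +1 | — | voltage-dependent block; fixed a priori |
| `tau_on/off` | 2 | s | finite-speed bath exchange |
| `rundown_tau`, floor | 1200, 0.3 | s, — | slow rundown of channel activity only |
| `leak_nS` | 0.5 | nS | a 2 GΩ seal; reversal 0 mV |
| `capacitance_pF` | 20 | pF | small epithelial cell |
| `series_resistance_MOhm` | 5 (drawn 3.3–9.6) | MΩ | the reported pipette range |
| `drift_sd_pA`, `drift_tau_s` | 40, 30 | pA, s | slow baseline instability; sized so paired condition differences scatter by tens of pA, the scale on which small drug effects on K⁺ currents are statistically unresolvable |
| `noise_sd_pA` | 20 | pA | post-filter recording noise |
| cohort `variability` | 0.2 | log-normal σ | between-cell scatter of channel density, leak, C_m, R_s |

`Kd0` is the one *calibrated* default: with δ fixed, a one-dimensional
root-find (`scripts/calibrate_defaults.R`) sets it so that the **full
pipeline** — simulate a default cell through the control/benzamil
timeline, extract sweeps, average the steady-state windows, correct
voltages, take I(−100) per condition — reports 87.5% inhibition of the
whole-cell inward current by 1 µM blocker. The calibration target is the
whole-cell (leak-included) figure, not the bare channel block, because
that is what the percent-inhibition analysis measures; the implied channel
block at −100 mV is ≈94%. Both `Kd0` and δ are synthetic defaults, not
measurements of benzamil pharmacology.

The baseline-drift term deserves a note: without it, a paired t test at
these noise levels detects even a few-pA systematic drug effect on the
small symmetric-K⁺ currents at any realistic cohort size, which
contradicts the non-significant K⁺-series outcomes such experiments
report. Real whole-cell recordings carry slow seal/access drift that
dominates paired condition differences; the OU term reproduces that
scale. It is part of the noise model, switched off (`drift_sd_pA = 0`)
wherever a test needs determinism.

## The analysis pipeline's numerical choices

* **Steady-state window**: [end − 32 ms, end − 2 ms] of each step; the
  2 ms guard excludes the off-edge capacitive transient. On a 200 ms step
  this is 168–198 ms.
* **Sweep extraction**: annotation-based when annotations exist,
  otherwise reconstructed from command-voltage edges (the two agree
  exactly on synthetic data); sweeps cut by the recording edge or by an
  epoch boundary are dropped, and a sweep only counts toward a condition
  when it starts ≥ 3 exchange time constants after the solution change.
* **Voltage correction**: $V = V_\mathrm{cmd} - \mathrm{LJP} - I R_p$
  with each point's own steady-state current; $R_p$ is the nominal access
  resistance from the metadata (no dynamic estimation).
* **Reversal voltage**: linear interpolation on the corrected curve,
  using the sign-change bracketing pair nearest 0 mV; with no crossing the
  value is extrapolated from the two smallest-|I| points and flagged.
* **Terminal conductances** g(−), g(+): the two-point slope at the curve
  extremes, *not* the chord $I/(V - V_r)$. For rectifying currents the
  chord underestimates the local conductance at the steep end (for an
  inwardly rectifying GHK curve the terminal slope exceeds the chord —
  the relation reported summary tables show), so the slope is the
  quantity summarized.
* **Currents at ±100 mV**: interpolation on the corrected axis, with
  linear terminal extrapolation when the corrected span stops short of
  ±100 mV. The series-resistance correction contracts the span by
  $I R_s$ — up to ~30 mV at 9.6 MΩ and 3 nA — so the metrics path allows
  40 mV of extrapolation while the low-level `current_at()` keeps a
  strict 10 mV default.
* **Paired bi-ionic analysis**: the last complete sweep before the switch
  vs the first settled sweep after it (≈10 s apart at the fast protocol),
  so rundown (τ = 1200 s) moves the pair by <1% and cancels almost
  entirely in $\Delta V_r$.
* **Statistics**: classical Student t tests (two-sided; unpaired tests
  pool variances, a `welch` switch is provided), ‡ marking p < 0.05, no
  multiple-testing correction — matching the conventions of the summary
  tables this report emulates. Zero-variance paired differences are
  reported as p = 0 (nonzero shift) or p = 1 (identical) with a note.

## What the simulations establish — and what they do not

The generator emulates: the 11-step +100→−100 mV protocols (300 ms/16.7 s
and 200 ms/5.3 s presets) at 5 kHz; bath-exchange timelines with blocker
epochs; junction offsets; series-resistance error; capacitive edges;
rundown; drift; white noise; and log-normal between-cell scatter. Cohort
timelines in the tests and analysis scripts are shortened to a few settled
sweeps per epoch (e.g. 200 s rather than tens of minutes per cell) and the
null-calibration study runs at 1 kHz with a compressed two-epoch protocol;
these sizes are the package's choice to keep the full study cheap to
re-run, and none of the analyzed quantities depend on epoch length beyond
having ≥ 2 settled sweeps.

It does **not** emulate: single-channel stochastic gating, Markov gating
kinetics (so the slow time-dependent inward rectification sometimes seen
in long steps is absent — simulated control curves in symmetric solutions
are nearly linear, and g(+) ≈ g(−) where real tables show g(+) < g(−));
temperature or electrode drift beyond the OU term; acquisition-format
quirks. Two known fidelity limits: (i) the quoted 4.1 mV junction
correction discussed above; (ii) with a non-saturating 1 µM blocker the
simulated unblocked residual (~5% of the channel current) differs
resolvably from the NMDG⁺-bath current in a paired test, whereas real
recordings' larger, leak-dominated residuals masked that difference — the
NMDG⁺ ≡ full-block equivalence is exact in the model only at saturating
blocker, and is tested there.

Passing the included tests therefore shows that the *pipeline* recovers
known truths from data with these noise and error structures (Nernst
reversals to <1 mV, bi-ionic ratios to ±0.05 noiseless and ±0.1 at 20 pA
noise with n = 5, the calibrated 87.5% inhibition to within [85, 90]%, a
5% paired-t false-positive rate); it does not by itself validate the
biophysical parameter values against new bench data.

## Reproducibility

Every stochastic element — cell draws, drift, noise — descends from one
integer seed per simulation (`withr::with_seed`), and a bundle's metadata
(protocol, timeline, solutions, cell parameters, applied junction offsets,
seed) is sufficient to re-simulate it bit-identically or re-derive every
correction at analysis time. Bundles persist as CSV plus a JSON sidecar;
summary tables as CSV/JSON.
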