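---
title: "Windkessel simulation and temporal complexity of PPG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windkessel simulation and temporal complexity of PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wkppg)
```

## The model

`wkppg` simulates peripheral blood pressure and photoplethysmography (PPG)
with a four-element Windkessel whose **central compliance varies within each
cardiac cycle**. The heart is a flow source $q_{in}(t)$; the arterial tree is
the lumped circuit (central compliance $C_1$, inertance $L$, distal
compliance $C_2$, peripheral resistance $R$):

$$
\frac{dq}{dt} = \frac{p_c - p_p}{L},\qquad
\frac{dp_c}{dt} = \frac{q_{in}(t) - q}{C_1(p_c)},\qquad
\frac{dp_p}{dt} = \frac{q}{C_2} - \frac{p_p}{R\,C_2}.
$$

$C_1$ follows the Langewouters arctangent pressure–area law, whose pressure
derivative is

$$
C_1(p) = \frac{A_m\,l}{\pi P_1\left(1 + \left((p - P_0)/P_1\right)^2\right)},
$$

maximal ($A_m l/\pi P_1$) at the pressure of maximal compliance $P_0$ and
falling off with the steepness pressure $P_1$. Ejection is an analytic
half-sine upstroke / quarter-cosine decay parameterized by peak flow $q_0$,
period $T$, ejection time $T_s$ and peak-time fraction $\alpha$ (default
$1/3$); its integral over the cycle is the stroke volume, so cardiac output
fixes $q_0$ in closed form (`q0_from_co()`). The printed form of the second
waveform branch carries the bound "$\alpha T$"; the package uses
$\alpha T_s < t \le T_s$, the only reading that is continuous and terminates
ejection at $T_s$.

PPG is produced from $p_p$ by a site-level arctangent pressure–volume
transfer with a sensor gain and offset (`pv_spec()`): the same functional
family whose derivative is the compliance law, which keeps the
pressure-to-volume translation self-consistent.

### Numerical route and its cross-check

Two mathematically equivalent formulations are implemented:

* **first order** (default): the three-state system above, integrated by an
  adaptive Dormand–Prince RK45 in compiled code (relative tolerance $10^{-6}$,
  steps clamped to land exactly on the 0.01-s output grid);
* **third order**: the scalar ODE in $p_p$ obtained by eliminating $q$ and
  $p_c$, with $C_1$ evaluated at the reconstructed central pressure —
  integrated by an independent plain-R RK45.

The test suite requires the two routes to agree within 0.5 mmHg pointwise on
the flagship scenario (they agree to ~$10^{-5}$ mmHg), and halving the output
step to change nothing beyond 0.1 mmHg. Initial state is
$q = 0,\ p_c = p_p = 80$ mmHg; warm-up beats (copies of beat 1) are discarded
once the cycle-to-cycle change falls below 0.1 mmHg (at most 10).

### The compliance scale: choice of the unit length `l`

The published arctangent parameters describe a *per-centimetre* segment
compliance; the source material never states the length it lumps into $C_1$.
With $l = 1$ cm the central compliance is $\sim 5\times10^{-3}$ mL/mmHg at
working pressure, which makes the $L$–$C_1$ pair a nearly undamped 13-Hz
resonator: the simulation is then chaotic (it never reaches a periodic
steady state and diverges under tolerance changes) and the flagship
scenario's systolic pressure (~340 mmHg) would fail the protocol's own
80–220 mmHg retention band. The package therefore attaches `l = 100` cm to
all simulation profiles — an *effective arterial-tree length* that scales
the unit-length law to a whole-tree central compliance of order 0.5 mL/mmHg
at working pressures, the physiological magnitude. Under this choice the
flagship scenario sits inside the retention band (SBP ≈ 208 mmHg), sweep
corners are genuinely filtered, and every numerical contract holds.
`compliance_c1()` itself is linear in `l`, so unit-length evaluations are
unaffected.

## Stimulus protocols

* **SV pulse**: one beat's $q_0$ increased by 20% (`make_sv_pulse()`).
* **Mini pulse**: instantaneous inflow increased by 10% for one 0.01-s
  window (`make_mini_pulse()`), by default at the peak-ejection instant,
  where the response is maximal.
* **Random stimuli**: per-beat multiplicative white noise, uniform on
  ±5% of the CO and R baselines (analytic SD $5/\sqrt3 \approx 2.89\%$ —
  the source text prints 2.83%, which no reading of "uniform on ±5%"
  reproduces; the stated distribution is implemented).
* **Sweep**: 45 compliance profiles × R ∈ {0.7, 0.9, 1.1, 1.3} mmHg·s/mL ×
  CO ∈ {4.25, 5.1, 5.95} L/min, with rows discarded when SBP leaves
  80–220 mmHg.

The response to a stimulus is quantified on the *distortion* (PPG with
stimulus minus PPG without, on an identical warm-up and beat grid): its
per-beat peak magnitudes, linearly interpolated at beat centers, form the
response envelope, whose width at half peak is the half-width (HW) and whose
peak is the overshoot (OS). The continuous-envelope construction is the
package's choice; the source never states how its response curve is
extracted from a pulsatile signal.

A note on magnitudes: with the stated protocol, the mini-to-SV peak
distortion ratio is pinned by the injected-volume ratio
$(0.1\,q_0\,\Delta t)/(0.2\,SV) \approx 1/45 \approx 0.022$, at every beat
of the envelope and regardless of PPG gain, compliance scale or 10-Hz
preprocessing. The reported order of $10^{-3}$ is only reachable if the mini
pulse is placed at a near-zero-flow instant; the package keeps the stated
peak-flow default and documents the discrepancy (the corresponding
acceptance check is intentionally left failing rather than re-tuned).

The 45-profile set ships the two published exemplars verbatim
(Aorta1: 3.5 cm², 50.4 mmHg, 42.3 mmHg; Aorta2: 6.18 cm², −2.3 mmHg,
21.6 mmHg); the remaining 43 are a *fixed, internally seeded* sample of
$A_m \in [3,7]$ cm², $P_0 \in [-10,60]$ mmHg, $P_1 \in [15,45]$ mmHg — a
synthetic stand-in for a published table that is not reproduced here.

## Morphology and temporal complexity

Beats are detected on the PPG by prominence-based peak picking (prominence
≥ 0.3× the *local* 10-s peak-to-peak range — local so that slow gain drift
cannot swamp the threshold — and separation ≥ 0.4× the median interval),
with beat feet at inter-peak minima. Eight per-beat features (AC, DC, Area,
notch index, systolic/diastolic slope means and SDs) are median-aggregated
per 20-s epoch, one epoch per beat. DC is the per-beat mean (a foot-value
reading was rejected as noise-sensitive); Area normalizes both amplitude and
time.

Temporal complexity uses the Higuchi curve lengths
$L(k),\ k = 1\ldots5$ — implemented exactly as the printed estimator,
including the $1/k$ average over the $k$ offsets — and the log–log fits:

* `HFD_wave`: slope $a_1$ of the **linear** fit on the 100-Hz waveform;
* `HFD_DC`, `HFD_AC`: intercept $a_0$ of the **cubic** fit on the per-beat
  baseline/amplitude series (≥ 11 beats required);
* `ACF_HW`: the lag (s) where the biased-normalized autocorrelation of the
  20-s waveform first reaches 0.5, linearly interpolated.

Each series is normalized by its window mean before the curve-length
computation. Rationale: the intercepts of raw series shift by $\ln(s)$ under
amplitude scaling $s$, yet the protocol treats all three measures as robust
to sensor-coupling scale changes; mean-normalization reconciles the two
(the slope is scale-invariant analytically). The cubic fit over five
abscissae is near-saturated (4 parameters, 1 residual degree of freedom);
its covariance-based standard errors are reported with that caveat, and all
slope/gradient analyses against hemodynamics use bisquare IRLS
(`MASS::rlm`).

## Hemodynamic fitting and consistency

`fit_windkessel()` selects, per subject, the compliance profile (out of the
45) and $(R, L, C_2)$ minimizing the RMSE between simulated and measured BP,
with the per-beat inflow set from measured stroke volumes and the search
seeded at $R = \mathrm{MAP/CO}$. Because the measured segment starts at a
detected foot (which lags the true inflow onset), the RMSE allows a small
signed, fractional-sample alignment lag. Quick model-free estimates —
$R_{alt} = \mathrm{MAP/CO}$ and the relative compliance
$C_{1,alt} = \mathrm{median(AC)/median(PP)}$ — back a consistency discard:
samples are dropped when the two R estimates disagree by more than 30%
(the source says only "considerably different"; 30% is the package's
documented, configurable choice).

## Evaluation harness

Epoch features are evaluated against reference MAP/PP by
leave-one-subject-out protocols, with epochs stratified at the pooled
median of the CO-fluctuation index (mean |ΔCO| over consecutive beats;
ties go to the low stratum):

* `linreg_eval()`: plain OLS, no calibration;
* `bnn_eval()`: a single-hidden-layer network (15 tanh units) trained per
  EasyEnsemble subset and ensemble-averaged, followed by a per-subject
  linear calibration on the first 10 chronological epochs (excluded from
  scoring). "Bayesian" is realized as weight decay re-estimated by the
  evidence approximation (MacKay updates on the Gauss–Newton Hessian) — the
  source names no architecture beyond the 15-unit layer, so this element is
  the package's documented choice and is swappable. EasyEnsemble is a
  classification technique; the regression adaptation (5 equal-count target
  bins, 10 undersampled subsets) is likewise an invented, documented
  adaptation. "MAE" is the *median* absolute error throughout, following
  the protocol's own wording.

`sensitivity_map()` bins epochs on (CO, R, C1) (8×6×6 by default, bins with
under 5 epochs dropped) and estimates partial gradients by robust fits
within slices of the other two axes.

## The synthetic cohort: what it emulates, what it does not

`make_cohort()` emulates the *shape* of the reference recordings: ~40
subjects, ~5 min of time-aligned PPG/BP/SV at 100 Hz. Hemodynamics are drawn
uniformly from the sweep-protocol ranges; the compliance profile is drawn
from the bundled 45-profile set so that profile identification is
well-posed; cardiac period 0.7–1.0 s; per-beat CO/R stimuli are stationary
AR(1) sequences (marginal SD = halfwidth/√3, clipped at ±3 SD; φ = 0.3 by
default, φ = 0 reproduces the white-noise protocol — realistic φ magnitudes
are not published, and 0.3 is a deliberately mild choice); PPG gain is
uniform on 0.8–1.2 per subject, with 1% white measurement noise. Subjects
whose SBP leaves 80–220 mmHg are rejection-resampled (the emulated cohort is
healthy); repeated *simulation failures* abort after 3 retries.

The generator does **not** emulate respiration, motion artifacts,
arrhythmias, heart-rate variability (the period is fixed per subject), or
any autonomic feedback: a green test therefore establishes correctness of
the pipeline mechanics and of model-implied directions, not performance on
real recordings — the experimentally derived numbers of the source are out
of scope by design.

`info_inject = TRUE` is *test scaffolding*, off by default: it adds (a)
heterogeneous per-subject stimulus levels (0.4–1.6× the nominal half-width)
so the pooled CO-fluctuation split separates genuinely calm and unstable
subjects; (b) a slow sinusoidal R drift (100-s period) whose amplitude
scales with the subject's CO-fluctuation level, so per-epoch MAP drift — and
the temporal-feature information that tracks it — is largest exactly where
CO fluctuates; and (c) a slow multiplicative sensor-gain wander (±30%, 75-s
period) that corrupts amplitude-based morphology while leaving
scale-invariant temporal features nearly untouched. It exists to make the
directional evaluation test possible and is not a claim about physiology.
The corresponding acceptance check compares the calibrated-ensemble r of
the combined and morphology-only feature sets in the high-fluctuation
stratum, aggregated over five cohort replicates (single-replicate r values
carry ~0.05–0.1 ensemble sampling noise at desk-scale cohorts).

## Numerical choices and degenerate inputs

* Zero-phase low-pass: FFT-domain squared-magnitude 4th-order Butterworth at
  10 Hz with reflection padding (−6 dB at cutoff, the filtfilt equivalent);
  the filter family/order is unstated in the source, only the cutoff.
* Envelope half-width with a zero peak is *missing*, not zero; an ACF that
  never reaches 0.5 yields a missing ACF_HW; a beat without a notch yields a
  missing notch index; constant series make the Higuchi log undefined and
  error out.
* Profile-fit ties break to the lowest profile index.
* All randomness is seed-controlled; the bundled profile sampler uses a
  fixed internal seed and restores the caller's RNG state.

## Known limitations

Open-loop only (no baroreflex); a single lumped site (no vascular tree, no
multi-site PPG); the analytic ejection waveform is deliberately simple; the
BNN is a reference implementation, not a tuned estimator; and all
experimental-data-dependent magnitudes in the source are reproduced only as
*directions* on synthetic data, never as numbers.
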