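---
title: "Methods: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pulsebp` estimates systolic, diastolic and mean arterial pressure (SBP /
DBP / MAP) from two-site arterial pulse waves and a PPG channel. This
vignette records the model, the assumptions, the stated world of the
synthetic-data generator, and the numerical decisions — in enough detail
that a maintainer can tell which behaviours are physics, which are
engineering choices, and which are open by design.

## 1. The hemodynamic layer

All internal physics is SI (Pa, m, s, kg/m³); mmHg appears only at public
interfaces, with 1 mmHg = 133.322 Pa. This avoids silent unit mixing
between the wave-speed relations (Pa) and the clinical quantities (mmHg).

The chain of closed-form relations is:

* `pwv_from_ptt()`: `PWV = L / PTT`, `L` the inter-sensor distance. `L`
  defaults to 0.02 m; it is a device property, configurable, and not a
  published constant.
* `mk_pwv()` / `youngs_modulus()`: the Moens–Korteweg wave speed
  `PWV = sqrt(E h / (D ρ))` with the exponential pressure law
  `E = E0 exp(ξ P)` (`ξ` in 1/mmHg). The symbol `ξ` is used throughout;
  the specific-heat ratio of the sensor chamber keeps `γ`.
* `mk_pressure()`: the exact algebraic inverse,
  `P = ln(PWV² ρ D / (h E0)) / ξ`; it approximates MAP.
* `regression_fit()` / `regression_predict()`: ordinary least squares of
  pressure on `ln(PTT)` — the popular regression arm.
* `pulse_pressure()`: `ΔP = ρ PWV² (2 ΔD/Dd + (ΔD/Dd)²)`.
* `map_p_beta()` / `beta_calibrate()`: `MAP = 2 ρ PWV² Dd / (β D)` and its
  one-point inversion. The printed form retains the `Dd/D` factor even
  though the default `D = Dd` makes it neutral (systolic and diastolic
  diameters differ by under 10 % over a cycle), so the literal relation is
  what is computed.
* `track_sbp_dbp()`: `DBP = k·MAP`, `SBP = MAP + (1−k)·DBP` with
  `k = 0.76` by default. The pulse pressure is computed and reported but
  **not** consumed by this decomposition — that is exactly how the
  tracking step is printed, even though the surrounding prose mentions
  obtaining MAP *and* PP first. An explicitly non-default
  `tracking_variant = "pp"` substitutes `SBP = MAP + (1−k)·PP` for anyone
  who wants the PP-consuming reading.

`K1` is expected to be negative after fitting on physiological data
(pressure falls as transit time rises); nothing enforces this, and the
pooled fit degrades gracefully into whatever the data support.

## 2. The stated world of the simulator

The generator's defaults are the conditions the pipeline is validated
under; they were fixed before the acceptance criteria were evaluated and
are not revisited:

* Cohort marginals, drawn uniformly: MAP 70–120 mmHg, heart rate 50–100
  bpm, end-diastolic diameter 2.0–3.0 mm, fractional diameter excursion
  3–9 %, wall thickness 0.2–0.4 mm. Stiffness `E0` 50–90 kPa and `ξ`
  0.014–0.018 /mmHg place the radial wave speed in the physiological
  few-m/s range across the pressure span. `k` is fixed at 0.76 for the
  whole cohort.
* Each subject's SBP/DBP follow the tracking decomposition from their MAP,
  so that model error — not generator–model mismatch in the BP
  decomposition — is what the cohort criteria measure.
* Visit-to-visit variation: each session's MAP is the subject baseline
  plus a zero-mean normal offset with SD 4 mmHg. Short-term repeated-visit
  MAP variability of a few mmHg is realistic, and without it the
  regression arm's two anchors would be degenerate (two sessions at an
  identical pressure carry no slope information).
* Sessions are 25 s; piezo channels at 5 kHz, PPG at 100 Hz with an
  18-bit ADC; noise is white Gaussian at a configurable SNR (20 dB for the
  cohort criteria), defined against the **variance** of the clean signal —
  a mean-square reference would be meaningless for the DC-dominated PPG.
  PPG quantization is applied after the noise.
* The beat template is a sum of two Gaussians: systolic peak at 18 % of
  the cycle (width 5 %), dicrotic reflection at 55 % (width 9 %, amplitude
  0.35), with ±2 % cycle jitter. Any smooth single-upstroke template
  would do; the parameters are config-exposed.
* The distal channel is the proximal one delayed by
  `L / PWV(session MAP)`, evaluated analytically — the delay is exact, not
  interpolated. The PPG shares the same cardiac phase (the optical sensor
  sits between the piezo pair; no extra transit delay by default).
* The piezo path runs displacement → sealed-chamber compression
  (`Pa = −γ P_A A x / V`, valid while `A·x ≪ V`) → a piezo transduction
  constant (V/Pa) → the analog front end.

Crucially, the generator's wave speed follows the Moens–Korteweg
exponential-modulus law at the session pressure, while the P–β estimator
assumes `MAP ∝ PWV²` with a pressure-independent `β`. These disagree away
from the calibration pressure — deliberately: that residual is the P–β
model's own error, the thing the cohort statistics measure. It grows with
`ξ·MAP` and with the visit-to-visit offset, and it dominates the cohort
error budget (the timing error contributes roughly half as much).

What a green cohort test does **not** establish: anything about motion
artifacts, sensor placement error, arrhythmia, BMI-dependent optical
depth, or population transfer — none of which the generator emulates.

## 3. Signal processing

* **Decimation**: the published FIR band lives at 5 kHz, where a 0.7 Hz
  linear-phase high-pass edge would need ~10⁴ taps; the pipeline
  decimates to a working rate first (anti-alias cutoff `0.4·fs_target`,
  Hamming windowed sinc, stopband > 50 dB).
* **Working rate 500 Hz**: the design originally targeted 200 Hz, but the
  measured bias of sub-sample foot refinement at 200 Hz leaves a
  worst-case noiseless round-trip error of 1.7 mmHg — in conflict with
  the ≤ 1 mmHg round-trip contract. At 500 Hz the worst case is
  0.43 mmHg. `fs_work` is config-exposed.
* **Band-pass**: windowed-sinc Hamming FIR, transition ≤ 0.35 Hz, with
  the ideal cutoffs tuned by a small root search so the measured −3 dB
  edges land on 0.7 and 9.5 Hz (well within ±0.1 Hz). Applied zero-phase
  with odd-reflection edge padding — zero padding lets the long
  low-frequency tail smear a multi-second transient into the record and
  swallow early beats.
* **Beat detection**: threshold = 0.5 × an exponentially decaying running
  peak (time constant 2 s), 300 ms refractory; the timing fiducial is the
  maximum systolic upslope, refined by a three-point parabola on the first
  difference. Beats whose foot-to-peak amplitude falls below 0.4 × the
  upper-quartile amplitude are flagged invalid: at low heart rates the
  dicrotic lobe outlasts any fixed refractory, and the amplitude gate is
  what rejects it. Inter-beat intervals outside 0.3–2.0 s also invalidate
  the flanking beats. Beats within 1 s of the record edges are dropped by
  the pipeline (filter transient region).
* **Template re-timing**: at 20 dB SNR, single-point fiducials carry
  70–300 µs of session-median PTT error — intolerable against a 2–8 ms
  transit time, since MAP scales with PWV². The pipeline therefore
  re-times every beat on both channels by the parabolic peak of its
  correlation with one ensemble-average beat template built from the
  proximal channel. A *common* template means any constant centering
  offset cancels in the transit difference; per-beat errors drop to
  ~25 µs median (noiseless: < 1 µs). The per-beat foot/pairing/median
  structure is unchanged; `dsp$template_refine` turns it off.
* **Pairing and aggregation**: each valid proximal foot pairs with the
  nearest later distal foot within 150 ms; the session PTT is the median
  of per-beat values (robust to spurious or missed beats), and the session
  PIR is likewise a per-beat median.
* **AFE model**: first-order high-pass at `1/(2π R1 Cp)` (0.995 Hz for
  20 MΩ and 8000 pF — the design prose's "≈ 0.1 Hz" does not follow from
  the formula and is not used), flat 18× gain with the half-supply offset
  passing at unity, and the Sallen–Key low-pass (equal R, equal C, 10.6 Hz;
  |H| = 1/2 at the cutoff for this Q = 0.5 design). Stages are discretized
  by the bilinear transform without pre-warping: all corners sit orders of
  magnitude below fs/2, so the warping error is negligible (each stage is
  tested against its analog magnitude to 2 %). Output clips to the rails
  with a saturation warning.

## 4. PPG and diameter estimation

Per cycle, `IH` and `IL` are the raw PPG extrema (parabolically refined so
the 100 Hz sampling does not truncate the true extremum), `AC = IH − IL`,
`DC` is the cycle mean. The normalized PPG `ln(AC)/ln(DC)` is read as a
quotient of logarithms: the alternative `ln(AC/DC)` reading goes negative
whenever AC < DC (always, for reflective PPG) and would break a monotone
diameter mapping; both readings are implemented
(`ppg_norm(reading =)`), the quotient is the default. Cycles containing
saturated samples are flagged invalid.

`ΔD = ln(PIR)/α` inverts the Beer–Lambert swing; `α` is calibrated per
subject against a reference excursion (`alpha_calibrate()`, exact round
trip). The end-diastolic diameter comes from a linear regression of
`ppg_norm` against reference diameters (the ultrasound-surrogate table
shipped by the simulator; any externally supplied table with columns
`subject_id, dd_mm, delta_d_mm, depth_mm` works). Predictions outside the
fitted range are flagged as extrapolation. Note that with `D = Dd` the
diameter cancels out of the MAP estimate, so diameter-model error affects
only the reported pulse pressure.

## 5. Calibration and estimation

One-point calibration (P–β): a session plus one reference reading yields
`β` (exact inversion at the reference MAP), `α`, and `k = DBP_ref/MAP_ref`.
Quality gates: ≥ 3 paired beats, beat-interval CV < 25 % (computed over
non-gap intervals — a dropped beat leaves a near-double interval that is a
detection artifact, not arrhythmia), session PIR ≥ 1.001. The regression
arm needs anchors from ≥ 2 sessions (two-point minimum for `K1`, `K2`).

The regression arm never reads the PPG channel; the P–β arm never reads
regression coefficients (tested). Estimates are deterministic given the
session bytes and the calibration state.

**Cohort comparison**: `run_cohort()` evaluates both arms. The regression
comparison arm defaults to a *pooled* fit — one `K1, K2` per pressure
across all subjects' anchors. The package's per-subject two-anchor
regression is also available (`regression_scope = "subject"`), but in this
generator pressure is exactly log-linear in PTT within a subject, so a
per-subject fit with well-spaced anchors is nearly exact and the
arm-ordering comparison would reduce to a coin flip on anchor spacing.
The heterogeneity argument for the P–β model is about a *shared*
PTT-to-BP curve failing across subjects with different arterial
parameters; the pooled arm is that curve, and against it the ordering
(P–β error SD smaller, all three pressures) is robust at every seed
tested.

## 6. Numerical choices and degenerate inputs

* Tolerances: algebraic inverses round-trip to 1e−9 (relative) or better;
  the ISO criterion-2 bound is solved by bisection to 1e−6 and matches
  the closed form `10/Φ⁻¹(0.925)` at zero mean.
* ISO criterion bounds are inclusive (≤), as printed.
* Criterion 2 is computed per-subject-first: mean difference per subject,
  then the SD across subjects, compared against the bound solved at the
  grand mean.
* Differences are `estimate − reference` throughout.
* Degenerate inputs: non-positive PTT/PWV/diameters raise typed
  invalid-input errors; a flat signal yields zero beats with a quality
  flag (not an exception); a flat PPG fails the PIR gate and rejects
  calibration with a reason; estimates that violate `SBP ≥ MAP ≥ DBP`
  (possible for independently regressed pressures) are returned flagged
  invalid rather than discarded.
* All randomness flows from explicit seeds; per-subject and per-session
  seeds derive arithmetically from the cohort seed, and every generator is
  bit-reproducible under a fixed seed.

## 7. Known limitations

* The piezo→voltage transduction constant is a single linear gain; no
  charge-amplifier dynamics, op-amp noise, drift or slew limits.
* No motion artifacts, no arrhythmia logic, no beat-to-beat BP output —
  session-level medians only.
* The optical model is single-wavelength Beer–Lambert with one static
  path; no photon-transport geometry, no BMI-dependent depth beyond a
  carried (unused) depth column.
* The dynamic-threshold detector is a faithful stand-in for a device
  algorithm whose published description is external; its parameters are
  config-exposed rather than canonical.
* With `D = Dd`, MAP from the P–β arm is insensitive to the diameter
  model; an application that separates `D` from `Dd` would make the
  diameter regression load-bearing and should revisit its 5 % RMS
  accuracy.
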