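---
title: "Validating heat-flux double-sensor core thermometry: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating heat-flux double-sensor core thermometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsagree)
```

## The problem

Core body temperature (CBT) during targeted temperature management
(TTM) after cardiac arrest is usually monitored with an esophageal
probe — accurate, but invasive. A disposable heat-flux *double sensor*
on the forehead offers a non-invasive alternative: two stacked
thermistors separated by insulation measure the skin temperature
$T_{h1}$ and the temperature $T_{h2}$ on the environment side of the
insulation. Assuming steady state, the heat flux through the insulation
equals the flux through the underlying tissue, and the core temperature
follows algebraically:

$$T_{core} = T_{h1} + \frac{K_s}{K_g}\,(T_{h1} - T_{h2}),$$

with $K_s$ and $K_g$ the heat-transfer coefficients of the insulation
and of tissue. `dsagree` implements this model, a synthetic TTM cohort
generator, the stream pairing and artifact filtering needed to compare
the 1 Hz sensor against a 30-minute reference, and the
method-comparison statistics — Bland–Altman limits of agreement (LoA),
the intraclass correlation coefficient (ICC) with F-based confidence
intervals, threshold coverage, and ICC-based study sizing.

The package treats the whole analysis as a fitted model: the central
function `method_agreement()` returns a classed object with `print`,
`summary`, `coef`, `plot` (Bland–Altman) and `residuals` methods.

## The sensor model and its one parameter

The device vendor does not publish numeric $K_s$, $K_g$ values, so the
single dimensionless ratio $K_s/K_g$ is a configuration parameter,
default 0.5. This is less arbitrary than it looks: the simulator's
forward model (`forward_skin_temps()`) is the exact algebraic inverse
of `compute_core_temp()`, so every statistic downstream of the pairing
stage is invariant to the ratio as long as the same value is used on
both sides. The test suite asserts this invariance, and asserts the
round-trip identity to below $10^{-9}\,^\circ$C for ratios spanning
$10^{-2}$ to $10^{2}$. A ratio of exactly 0 is accepted by
`compute_core_temp()` only (the estimate degenerates to the skin
reading); the model constructor and the inverse require a strictly
positive ratio.

## What the simulator emulates

No patient-level raw data are publicly deposited for this kind of
study, so the pipeline is exercised end-to-end on synthetic cohorts
whose statistical structure matches the published summaries.

`ttm_protocol()` encodes the clinical protocol: induction cooling to
33 °C, a 24 h maintenance plateau, rewarming at exactly 0.25 °C/h to
37 °C, and a 24 h normothermia hold. Induction rate (1.5 °C/h) and the
admission temperature (35.5 °C) are not part of the published protocol;
the defaults reflect the mild spontaneous hypothermia typical of
post-arrest patients and are configurable. The noiseless trajectory is
continuous and piecewise linear; stationary AR(1) jitter (marginal SD
0.05 °C, per-second autocorrelation 0.99) prevents a perfectly
deterministic plateau and can be switched off for analytic tests.

Per patient, `simulate_patient()` draws

* a systematic sensor bias from $N(0, 0.45^2)$ °C,
* a sensor lag, uniform on 0–10 min, applied as a pure time shift of
  the core trajectory (the simplest reading of an individual,
  position-dependent lag; nonlinear lag kernels are out of scope),
* an ambient level from $N(25.22, 1.48^2)$ °C, recorded alongside,

and then generates the reference stream (true core at each 30-min tick
plus $N(0, 0.15^2)$ noise) and the double-sensor stream at 1 Hz: lagged
true core, plus bias, plus a slowly varying AR(1) measurement error
with marginal SD 0.25 °C and a 300 s correlation time, converted to raw
$(T_{h1}, T_{h2})$ channels through the inverse sensor model with a
1 °C core-to-skin offset.

The 300 s correlation time deserves a note. The dispersion budget is
calibrated so the pooled SD of paired differences is
$\sqrt{0.45^2 + 0.25^2 + 0.15^2} \approx 0.53$ °C, the value
characteristic of this sensor class. A *white* 1 Hz error would be
averaged away by the 60 s pairing window (contributing
$0.25/\sqrt{61} \approx 0.03$ °C); physically, forehead-sensor error is
dominated by perfusion and coupling drift, which moves on minutes, not
seconds. Modelling it as AR(1) with a correlation time long against the
pairing window but short against the 30-min pairing cadence preserves
the quadrature budget and keeps paired differences serially
uncorrelated. Measured over seeds, 20-patient cohorts give a mean
pooled difference SD of about 0.53 °C; individual cohorts scatter
roughly between 0.45 and 0.69 because the realised SD of 20 bias draws
is itself noisy.

Artifacts are injected at pairing-epoch granularity — each 30-min tick
is hit with probability 0.05, adding a single $N(0, 3^2)$ °C shock to
all sensor samples within 60 s of the tick — because artifact counting
in this design is per *pair*, not per raw sample. Logger dropouts blank
configurable time segments. The generator returns the ground truth
(true core series, bias, lag, artifact epochs) so recovery can be
tested; one master seed plus a fixed seed-mixing rule makes cohorts
bit-identical across runs.

What the simulator does **not** emulate: pharmacological vasomotion,
device feedback control, shivering countermeasures, clock drift between
loggers, and the heavier-than-Gaussian centre of real difference
distributions (see limitations below). Passing tests therefore
demonstrate the correctness and calibration of the *pipeline*, not
clinical performance of the sensor.

## Pairing and the artifact rule

`pair_streams()` reduces the 1 Hz stream to one candidate pair per
reference tick: the sensor value is the mean of the derived core
temperature over a centred 60 s window (a `"nearest"` mode is available
for sensitivity analysis). Ticks with an empty window are skipped and
counted. The difference is always sensor minus reference.

`remove_artifacts()` implements the conventional exclusion rule:
compute the mean $m$ and SD $s$ of the pooled differences once, in a
single pass, and flag pairs with $|d - m| > 2s$. The rule is applied
exactly once; re-running it would trim further, and the pipeline
structure prevents that. Two documented ambiguities are resolved by
defaults with config switches: the corridor is centred on the pooled
mean difference (not zero), and pooled over the cohort (not per
patient), because cohort-level analyses report a single artifact count.
On clean Gaussian differences the flagged fraction is the 2-SD normal
tail, ≈ 4.55 %. With the default artifact injection the filter catches
roughly the fraction a normal mixture model predicts (about 60 %:
shocks of SD 3 °C often land inside the inflated corridor); a filter
this simple is a blunt instrument, which is faithful to practice.

## The agreement battery

On the retained pairs, `method_agreement()` computes:

* **Paired t-test** — `t = mean(d)/(sd(d)/sqrt(n))`, two-sided p on
  $n-1$ df. A zero-SD input is rejected rather than reported as
  $t = 0$.
* **Bland–Altman** — bias, SD, LoA $= \text{bias} \pm 1.96\,\text{SD}$
  (the conventional 1.96 multiplier, not the t quantile, so the LoA
  midpoint is identically the bias and the width identically
  $3.92\,\text{SD}$); bias CI via the exact t quantile; LoA CIs via the
  standard-error approximation
  $\text{SD}\sqrt{1/n + 1.96^2/(2(n-1))}$.
* **ICC** — single-measure, two-way mixed, consistency (ICC(3,1)):
  $(MS_R - MS_E)/(MS_R + (k-1)MS_E)$ from the two-way ANOVA mean
  squares, with the exact F-method CI. Consistency is the right variant
  when a fixed offset between methods should not count against
  reliability; the absolute-agreement variant (A,1) is available behind
  `icc_type = "agreement"` for sensitivity analysis, with the
  McGraw–Wong Satterthwaite CI.
* **Cicchetti class** — poor [0, 0.4), moderate [0.4, 0.6), good
  [0.6, 0.75), excellent [0.75, 1]; the half-open convention closes the
  gaps the published cutpoints leave at 0.59–0.6 and 0.74–0.75.
* **Coverage** — percent of pairs with $|d| \le$ 0.5 °C, boundary
  inclusive; 0.5 °C is the conventional a-priori acceptability limit,
  the magnitude of circadian variation.

Nothing is rounded internally; the print method rounds to 2 decimals
for °C, ICC and t and 2 significant figures for p, and the JSON
serialisation (`write_agreement_report()`) keeps full precision and
round-trips exactly.

```{r}
set.seed(1)
fit <- suppressMessages(run_pipeline(run_config(
  cohort = cohort_config(n_patients = 25, duration_h = 48, seed = 1))))
fit
```

## Study sizing for ICC reliability

`icc_power()` gives the exact F-distribution power of the one-sided
test of $H_0: \rho = \rho_0$ against $\rho_1 > \rho_0$: with
$C(\rho) = (1 + (k-1)\rho)/(1-\rho)$, the test rejects when
$MS_R/MS_E > C(\rho_0) F_{1-\alpha}$, and under $\rho_1$ the statistic
is a scaled central F, so no approximation is needed.
`icc_sample_size()` returns the minimal $n$ reaching a target power;
the test suite validates both against a brute-force Monte-Carlo power
oracle to within 3 points. Alpha is one-sided by default because the
hypothesis is directional; `two_sided = TRUE` spends $\alpha/2$.

A design scan shows which hypothesis pairs imply a 16-subject
reliability study at 90 % power and $\alpha = 0.05$ with two raters —
useful when a published sample-size statement omits its assumptions:

```{r}
icc_designs_for_n(16, p0_grid = c(0.6, 0.7, 0.75, 0.8),
                  p1_grid = seq(0.8, 0.97, 0.01))
```

The scan is exploratory; it recovers plausible assumptions (for
example $\rho_0 = 0.6$ against $\rho_1 = 0.9$) without asserting what
any particular study actually assumed.

## Numerical and design choices

* Timestamps are seconds from stream start; the two loggers are
  assumed clock-aligned (no drift estimation).
* Pairing windows are closed on both ends; the window mean on a linear
  ramp equals the midpoint value exactly, which the tests exploit.
* Degenerate inputs fail loudly and specifically: zero-SD t-test,
  all-identical ICC tables, fewer than 3 pairs for the filter, empty
  stream files (distinct from parse errors), non-monotone timestamps
  (with the offending line number).
* Sensor readings outside a 15–45 °C plausibility corridor are flagged
  (`suspect`), never dropped, so the 2-SD filter remains the sole
  exclusion step.
* The per-patient lag induces a small systematic difference during the
  induction and rewarming ramps (up to ≈ 0.02 °C at a 10-min lag on
  the 0.25 °C/h ramp), so per-patient bias recovery is checked as
  "within 3 standard errors for ≥ 90 % of patients", not for every
  patient.
* Problem sizes in the test suite — 20–25 patient cohorts at full 48 h
  / 1 Hz resolution, 1 000 null cohorts for type-I calibration, 1 319
  pairs per simulated agreement run, 4 000–5 000 Monte-Carlo studies
  for the power oracle — were chosen to keep Monte-Carlo error well
  inside every asserted tolerance.

## Known limitations

* The repeated-measures structure (≈ 50–100 pairs per patient) is
  pooled in the LoA and ICC, as is conventional in this literature; a
  within-subject LoA correction would widen the limits and is
  deliberately not implemented.
* A Gaussian difference model with bias 0.02 °C and SD 0.53 °C puts
  ≈ 65 % of differences within ± 0.5 °C; published coverage figures
  near 71 % for such data imply a heavier-centred real distribution.
  The simulator is Gaussian and so reproduces the former, not the
  latter.
* The standard-error-based LoA confidence intervals are the textbook
  approximation; exact methods for LoA CIs exist and give slightly
  different widths at small n.
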