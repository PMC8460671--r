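---
title: "Models and methods behind cardiomvd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiomvd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomvd)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and the numerical choices made where the design was open.

## 1. The measurement problem

In diet-induced cardiometabolic disease, dysfunction of the coronary
microvascular endothelium develops before global cardiac indices change.
A way to probe it *in vivo* is pharmacological: inhibiting nitric-oxide
synthase (with L-NAME) perturbs NO-dependent microvascular tone and water
exchange, which transiently changes myocardial T1. An intact endothelium
responds with a T1 rise of roughly +15% of baseline peaking about 8
minutes after injection; a dysfunctional one responds less, or with a
decrease. The package quantifies this response and the accompanying
cardiac phenotype (LV volumes and rates, myocardial strain, coronary flow
reserve, glucose tolerance) from data any preclinical MRI/Doppler setup
can export: image stacks, volume curves, point trajectories, velocity
traces and glucose curves.

## 2. T1 relaxometry and the cumulative ΔT1 index

### Signal model

The spoiled gradient-echo steady state is
$$S(\alpha) = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},
\qquad E_1 = e^{-TR/T_1}.$$
`spgr_signal()` implements it; `ernst_angle()` gives the maximising angle
$\arccos E_1$. TE is carried as metadata only: with a fixed echo time
across all scans the T2* weighting is a constant factor absorbed into the
apparent $M_0$, and it cancels exactly in post/pre ratios.

### Baseline map (VFA/DESPOT1)

With signals at the five angles 2, 5, 8, 11, 13 degrees (TR = 10 ms),
regressing $y = S/\sin\alpha$ on $x = S/\tan\alpha$ gives slope $E_1$ and
intercept $M_0(1-E_1)$ (`fit_vfa_t1()`). Pixels with slope outside (0, 1)
or degenerate signals are flagged `fit_ok = FALSE` and excluded — never
imputed. On noiseless input the fit inverts the model to better than
1e-6 relative; this round trip is part of the test suite.

### Dynamic inversion

Post-injection scans use a single angle (13 degrees, the largest of the
protocol, chosen for SNR). Assuming $M_0$ is unchanged by the injection —
a modelling assumption the ratio method requires — the post/pre signal
ratio at fixed angle determines the new T1 in closed form
(`invert_dynamic_t1()`): with $g(E) = (1-E)/(1-E\cos\alpha)$ and
$q = r\,g(E_{pre})$, $E_{post} = (1-q)/(1-q\cos\alpha)$. Ratios mapping
outside $E_{post}\in(0,1)$ are flagged invalid per pixel rather than
raising errors, so single noisy pixels cannot abort a time point. Note
that the recovered T1 is strictly *decreasing* in the ratio: the SPGR
signal at fixed angle and TR always falls with T1.

### Averaging order and the index

`delta_t1_course()` inverts per pixel first and averages over the
myocardial ROI second. The alternative (inverting the ROI-mean signal)
gives a different number on heterogeneous tissue because the inversion is
nonlinear; the per-pixel-first order is the documented default and a test
constructs a two-compartment ROI to pin the difference down. Invalid
pixels are excluded per time point (preserving ROI coverage elsewhere); a
time point with more than half its pixels invalid is flagged.

`cumulative_delta_t1()` integrates the percent-change course over time by
the trapezoid rule, in %·min. Since ΔT1 is zero at the moment of
injection by definition, an implicit (0 min, 0%) anchor is prepended
whenever the course starts later. The area is signed: negative excursions
(the dysfunctional phenotype) subtract. The %·min unit is adopted as the
natural scale of the index.

### Dynamic timing grid

The acquisition protocol implies six back-to-back 4-minute post-injection
scans; their mid-times default to {4, 8, 12, 16, 20, 24} min. This grid
is an assumption exposed as a parameter (`timepoints_min` of
`group_response_spec()`), not hard-coded.

## 3. Synthetic phantoms and the response generator

`make_phantom()` rasterises a myocardial annulus (default inner/outer
radii 10/18 px on a 64×64 grid) around a blood cavity, with exact
per-pixel ground truth (myocardium 1500 ms, blood 1900 ms — typical
high-field mouse values). `simulate_vfa_series()` applies the forward
model per angle; noise is additive Gaussian on magnitude with SNR defined
as mean myocardial signal at 13 degrees over the noise SD. The Rician
floor is deliberately ignored: at the SNR regime of interest (≈ 30) the
Gaussian approximation is accurate and keeps the inversion analytic. This
is a limitation for very low-signal pixels (background), which the ROI
never includes.

The T1 response to NOS inhibition is a normalised gamma-variate
$\phi(t) = (t/t_p)^a e^{a(1-t/t_p)}$ scaled by the peak percent change:
+15% at $t_p$ = 8 min for controls, +4% for the high-fat-diet phenotype
(any magnitude below the control peak is accepted; the sign may be
negative). Only the peak and its timing are empirically constrained; the
gamma-variate shape with exponent $a = 0.8$ — a fast rise and a slow,
plateau-like decline — is a documented default, not a fitted quantity.

What the generators do **not** emulate: cardiac/respiratory motion and
gating, B1 inhomogeneity, registration errors between pre- and
post-injection geometry, partial-volume edges, k-space artefacts. Passing
tests therefore validate the *analysis chain*, not robustness to those
acquisition effects; on real data the usual co-registration and quality
control remain the user's responsibility.

## 4. LV time–volume analysis

Global indices (`global_indices()`) come from the curve extrema — EDV,
ESV, SV, EF, CO — plus BSA = 9.822·(body weight)$^{2/3}$ and CI = CO/BSA.
(The cardiac-index definition is taken as CO divided by BSA, the standard
meaning.) Without a body weight, BSA and CI are omitted rather than
defaulted.

`fit_plr()` decomposes one cycle, ordered to start at end-diastole, into
four contiguous linear segments — ejection, isovolumic relaxation,
filling, isovolumic contraction — as a continuous piecewise-linear least
squares fit in the hinge basis
$v(t) = b_0 + b_1 t + \sum_k c_k (t-k)_+$. The three interior knots are
found by exhaustive search over all frame triples: at 60 frames this is
~34k candidates, each a 5×5 solve against a precomputed Gram matrix,
done in compiled code (RcppArmadillo) in well under a second. The search
RSS is then recomputed from residuals in double precision (the Gram
shortcut loses ~1e-10 to cancellation); on noiseless four-phase input the
minimum is numerically zero and the knots are exact. A flat curve
(SV ≈ 0) is a degenerate-fit error.

Two conventions matter downstream:

* **Cycle start.** The fit assumes frame 1 is end-diastole. For curves
  acquired elsewhere, `roll_tvc()` re-bases at the volume maximum; among
  exact ties on a flat EDV plateau it picks the frame the ejection
  decline follows, so a noiseless plateau does not split a phase across
  the wrap.
* **Units.** Ejection/filling rates are |segment slope|/SV where slopes
  are per normalised cycle — i.e. SV per RR, dimensionless; durations are
  % of RR and sum to 100 exactly. Both are invariant to rescaling volume
  units or RR, which is tested.

Under 1 µl of volume noise (SV 30 µl), the mean absolute knot error
across 100 seeded curves stays within one frame and the rates within 5%
relative — the parameter-recovery study run by the acceptance tests.

## 5. Strain

`strain_from_trajectories()` computes, per tracked point, the
circumferential stretch $\lambda_c = r(t)/r(0)$ about the (per-frame)
centroid, and per sector the radial stretch $\lambda_r$ from the change
in layer-mean radial separation (wall thickness). Conventions: linear
strain $\lambda - 1$ by default, Green–Lagrange $(\lambda^2-1)/2$ by
flag — the default is the common choice of clinical strain software, and
the two are related monotonically, so group contrasts are unaffected.
Points are binned into eight sectors by reference angle; per-point Ecc is
sector-averaged. Using the per-frame centroid makes strains exactly
invariant to rigid translation, and radii make them invariant to
rotation (tested with a rotated, translated copy).

`simulate_ring_motion()` places two point layers (endo/epi) and moves
them so that both analytic strains are *exact* for this estimator:
with mid-wall radius $R$, half-thickness $d$, circumferential scale
$c(t) = 1 - s\phi(t)$ and thickness scale $h(t) = 1 + w\phi(t)$, the
layers move as $r_\pm(t) = (R\pm d)[c \pm (d/R)(h-c)]$, which keeps the
mean per-point stretch exactly $c$ and the thickness exactly $2dh$. The
generator offsets point angles half a step from sector boundaries so that
floating-point rounding cannot split an endo/epi pair across sectors.

`strain_indices()` uses these decisions, made where the original analysis
software leaves them unspecified:

* the systole/diastole boundary is the time of peak |mean Ecc|, applied
  consistently to the Err indices;
* "1/3 of diastole" is one third of the interval from that peak to cycle
  end, with linear interpolation between frames (the alternative — one
  third of the total cycle after end-systole — was considered and
  rejected as it depends on the cycle fraction occupied by systole);
* strain rates are central differences on the uniform frame grid with
  second-order one-sided stencils at the ends (no smoothing by default),
  so on smooth curves the peak-rate error falls as $O(\Delta t^2)$ —
  verified against an analytic sinusoid.

## 6. Doppler flow reserve

`beat_peak_velocity()` reduces a 2000-ms velocity trace to the mean of
per-beat maxima. Beats are local maxima with topographic prominence of at
least 25% of the trace amplitude; runs of equal samples are collapsed
first so a flat-topped peak counts once; fewer than three beats is an
error. The vendor's spectral speckle processing is out of scope — the
package starts from a velocity trace — and expiration gating is a
generator-side behaviour, not detected in analysis.

`flow_reserve()` divides by the pre-injection baseline (reserve ≡ 1
there), reports the post-injection maximum and the mean over scheduled
points in the inclusive [6, 18]-min window; with the default 18-point
schedule that window holds exactly nine points. The reserve is invariant
to the velocity unit. The default schedule keeps the 40-min tail point
and is fully configurable.

## 7. Glucose tolerance

`gtt_auc()` is the total trapezoidal AUC from zero over the
0/15/30/45/60/120-min schedule; the incremental AUC above fasting
baseline is available behind a flag but is not the default, because the
group effect of interest is defined on total glucose exposure. The
generator models baseline plus a gamma-variate excursion (control peak
250 mg/dl at 30 min over a 100 mg/dl baseline); `gtt_group_scale()`
solves in closed form for the excursion multiplier that makes the
noiseless AUC ratio exactly the configured factor — 2.0 by default,
the 14-day high-fat-diet effect size.

## 8. Statistics

`compare_groups()` reproduces the study's decision rule exactly:
Shapiro–Wilk on each group and Brown–Forsythe (median-centred Levene,
via `car::leveneTest`) across groups, all at α = 0.05; if all pass, a
two-sided *equal-variance* t-test; if any fails, the two-sided
Mann–Whitney U. Welch's correction is deliberately not used — variance
heterogeneity routes to the nonparametric arm instead, mirroring the
stated logic. Tests are two-sided (sidedness is otherwise unspecified)
and no multiple-testing correction is applied, matching the reporting
convention the marks ns/*/**/*** come from. Constant samples, where the
Shapiro–Wilk statistic is undefined, are routed to the nonparametric arm.
Under the null (both groups normal, n = 8), the gated procedure's type-I
error stays within 0.05 ± 0.02 over 1000 simulations — slightly below
nominal is expected, since the occasional nonparametric detour is
conservative at this sample size.

`build_report()` assembles per-endpoint comparisons (cumulative ΔT1, EF,
rates, strain indices, flow reserve, GTT AUC, ...) into one table with
group means ± SD, the test used, p and mark; group labels must agree
across endpoints.

## 9. Problem sizes, seeds and determinism

Every generator is a pure function of its parameters and an explicit
integer seed (no global RNG state is consumed or left behind); identical
calls are bit-identical, which the tests assert. The test and acceptance
workloads are sized to run comfortably on a laptop: cohorts of n = 6
animals on 64×64 phantoms, 100 noisy time–volume curves for the
parameter-recovery study, 1000 null simulations for the type-I error
check. These sizes were chosen as the smallest that make the stochastic
checks stable; scaling them up changes nothing qualitatively.

## 10. Known limitations

* No motion correction, registration, B1 correction or Look-Locker/MOLLI
  variants; the dynamic scans are assumed co-registered with baseline.
* The M0-unchanged assumption of the dynamic inversion fails if the
  intervention changes proton density or coil loading appreciably.
* Strain is 2D (short-axis) only; no longitudinal or 3D strain, no
  tag-line processing — the package starts at trajectories.
* The Gaussian noise model understates magnitude bias at very low SNR.
* Group phenotypes in the generators (HFD peak +4%, twofold GTT AUC) are
  calibrated effect sizes for validation, not biological predictions.
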