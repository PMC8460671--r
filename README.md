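# cardiomvd

Quantifying coronary microvascular endothelial function and global cardiac
performance from preclinical (mouse) cardiac MRI, Doppler and metabolic
measurements — with a digital-phantom simulator that makes the whole chain
testable end to end without animal data.

The package is aimed at small-animal imaging groups studying early
cardiometabolic disease (e.g. high-fat-diet models), where endothelial
dysfunction of the coronary microcirculation precedes overt changes in
cardiac function and must be detected *in vivo*.

## What it computes

**Endothelial NO-dependent function (cumulative ΔT1).** Myocardial T1 is
mapped with the variable-flip-angle (VFA/DESPOT1) method from spoiled
gradient-echo (SPGR) signals

S(α) = M₀ sin α · (1 − E₁)/(1 − E₁ cos α),  E₁ = e^(−TR/T1),

fitted by the linearised regression of S/sin α on S/tan α. After systemic
NOS inhibition (L-NAME), dynamic scans at a single flip angle are inverted
pixelwise into post-injection T1 via the closed-form signal-ratio inverse
(M₀ assumed unchanged), averaged over the myocardial ROI, and expressed as
percent of baseline. The area under the ΔT1(%)–time curve (trapezoid rule,
anchored at 0% at injection) is **cumulative ΔT1** in %·min — the
endothelial-function index. Intact endothelium shows a ≈ +15% T1 rise
peaking ≈ 8 min post-injection; a blunted or negative response indicates
microvascular dysfunction.

**LV function.** From the 60-frame time–volume curve: EDV, ESV, SV, EF,
CO, BSA = 9.822·(body weight)^(2/3) and CI = CO/BSA; plus a continuous
four-segment piecewise linear regression (ejection — isovolumic
relaxation — filling — isovolumic contraction) whose knots are found by
exhaustive least-squares search over frame triples (compiled code).
Segment slopes normalised to SV give the ejection and filling rates
(SV/RR); segment lengths give ET/IVRT/FT/IVCT as % of RR.

**Myocardial strain.** Circumferential (Ecc) and radial (Err) strain-time
curves from tracked point trajectories, averaged over 8 angular sectors;
peak strains, strain at 1/3 of diastole, and peak systolic/diastolic
strain rates with respect to the normalised cycle.

**Coronary flow reserve.** Per-time-point averaged per-beat peak velocity
from 2000-ms Doppler traces (prominence-based beat detection); reserve =
velocity/baseline; peak reserve and the mean reserve over the scheduled
points in [6, 18] min post-vasodilator.

**Metabolic state.** Total trapezoidal AUC of the glucose-tolerance curve
(0–120 min) and body-mass change as % of pre-diet mass.

**Statistics.** Two-group comparisons with the study's gated logic:
Shapiro–Wilk (normality, each group) and Brown–Forsythe (variance
homogeneity); both pass → equal-variance t-test, otherwise Mann–Whitney U;
marks ns / * / ** / *** at 0.05 / 0.01 / 0.001.

Every input has a synthetic generator (`make_phantom()`,
`simulate_vfa_series()`, `simulate_lname_response()`, `simulate_tvc()`,
`simulate_ring_motion()`, `simulate_doppler()`, `simulate_gtt()`) with
known ground truth and group-dependent effects (control vs high-fat diet).

## Worked example

```r
library(cardiomvd)

# one simulated control animal through the full T1 pipeline
coh_ctl <- simulate_endothelial_cohort(n = 6, group_response_spec("control"),
                                       snr = 30, base_seed = 1)
coh_ctl$courses[[1]]
#> Myocardial delta-T1 time course (baseline 1518 ms)
#>  time_min delta_t1_pct
#>         4        12.40
#>         8        14.51
#>        12        13.62
#>        16        11.05
#>        20         9.43
#>        24         6.76
#> cumulative delta-T1: 257.6 %*min
```

The course rises to ≈ +15% of the 1500-ms baseline at 8 min — the intact
endothelial response; its area (257.6 %·min) is this animal's cumulative
ΔT1.

```r
x <- simulate_tvc(tvc_spec(edv_ul = 50, esv_ul = 20, bw_g = 27),
                  noise_ul = 0.5, seed = 2)
global_indices(x)
#> EDV 51.0 ul  ESV 19.4 ul  SV 31.6 ul  EF 62.0 %
#> HR 500 bpm  CO 15.82 ml/min  BSA 88.4  CI 0.1789
summary(fit_plr(x))
#> Four-segment piecewise-linear TVC model
#>   phase boundaries (fraction of RR): 0.300, 0.417, 0.850
#>   segment slopes (ul/cycle): -99.7, 6.5, 67.1, 2.6
#>   RSS: 18.45
#>   residual sd: 0.579 ul
#>   ER 3.15 SV/RR, FR 2.12 SV/RR
#>   ET 30.0%  IVRT 11.7%  FT 43.3%  IVCT 15.0% of RR
```

Group comparison of the endothelial index, control vs high-fat diet:

```r
coh_hfd <- simulate_endothelial_cohort(n = 6, group_response_spec("hfd"),
                                       snr = 30, base_seed = 100)
build_report(list(cumulative_delta_t1 = list(control = coh_ctl$cumulative,
                                             hfd = coh_hfd$cumulative)))
#> Cohort report (control vs hfd)
#>             endpoint n_control mean_control sd_control n_hfd mean_hfd sd_hfd
#>  cumulative_delta_t1         6        262.3      2.967     6    69.74   2.55
#>  test  p_value mark
#>     t 3.77e-17  ***
```

The blunted HFD response collapses the cumulative ΔT1 (≈ 70 vs
≈ 262 %·min), detected by the equal-variance t-test after both gate tests
pass.

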