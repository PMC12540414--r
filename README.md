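# srsignal

Disproportionality signal detection and time-to-onset modeling for
spontaneous adverse-event reports (FAERS / JADER dialects).

## The problem

Spontaneous reporting systems (SRS) such as the FDA Adverse Event
Reporting System (FAERS) and the Japanese Adverse Drug Event Report
database (JADER) collect voluntary post-marketing reports of suspected
adverse drug events. They have no exposure denominator, ship every
received version of a case, and code events against the MedDRA hierarchy
— so before any statistics can be trusted, reports must be deduplicated,
restricted to the drug of interest as *Primary Suspect*, and counted at
case level. `srsignal` implements that pipeline end-to-end for a target
drug (fentanyl patterns are bundled as the default) and is aimed at
pharmacovigilance analysts and methods researchers who want a tested,
reproducible implementation rather than ad-hoc scripts.

## The statistics

For each preferred term (PT) a 2×2 table is built against the
rest-of-database comparator — `a` target cases with the PT, `b` without,
`c`/`d` likewise among comparator cases, `N = a+b+c+d` — and four
disproportionality statistics are computed:

- **ROR** `= ad/bc`, with the Woolf interval
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
- **PRR** `= [a/(a+b)] / [c/(c+d)]`, with the Yates-corrected
  `χ² = N(|ad−bc|−N/2)² / ((a+b)(c+d)(a+c)(b+d))`;
- **BCPNN information component**
  `IC = log₂ P(drug, event)/[P(drug)P(event)]` via the closed-form
  posterior moments with the customary pseudo-counts; `IC025 = IC − 2·sd`;
- **MGPS/EBGM**: an empirical-Bayes gamma-Poisson shrinker whose
  two-component gamma mixture prior is fitted by marginal maximum
  likelihood on the full drug×event cell set; `EBGM = 2^{E[log₂λ | a]}`,
  `EB05` the posterior 5th percentile.

A PT is a **consensus signal** only when all four algorithms pass the
literature-standard thresholds (`a ≥ 3` & ROR CI lower > 1; PRR ≥ 2 &
χ² ≥ 4; IC025 > 0; EB05 ≥ 2) *and* its Bonferroni-adjusted p-value is
below 0.05. Sex-stratified reporting odds ratios (`ROR_fm`, female:male)
quantify subgroup differences. Time to onset (therapy start → event,
day-precision dates only) is summarized by chronology bins and a
Kaplan–Meier curve, and a Weibull model is fitted by profile MLE: a shape
`β < 1` with CI excluding 1 indicates a hazard concentrated just after
therapy start.

A seed-reproducible synthetic-report generator emits both source dialects
with recorded ground truth (injected relative risks, sex rate ratios,
Weibull onset law, missingness, duplicate versions), so the whole
pipeline is testable without the licensed databases.

## Worked example

```r
library(srsignal)

cfg <- sim_config(n_cases = 6000, seed = 19)   # 5 PTs injected at RR = 10
sim <- simulate_reports(cfg, tempdir())
res <- run_pipeline(faers_paths = sim$faers, seed = 11)

dplyr::filter(res$signals, is_signal)
#>   pt         a   ror ror_lo ror_hi   prr ic025  eb05 p_adjusted
#> 1 PT_015   169  23.1  17.8    30.0 10.2   2.46  6.85  1.81e-217
#> 2 PT_025   100  12.7   9.65   16.8  8.67  2.22  6.85  3.45e-107
#> 3 PT_035    61  13.8   9.78   19.3 11.1   2.29  6.85  1.43e- 78
#> 4 PT_045    41  10.9   7.38   16.2  9.53  2.02  6.85  1.66e- 45
#> 5 PT_055    29  14.7   9.03   23.9 13.3   2.08  6.85  1.09e- 41

res$weibull
#> Weibull time-to-onset fit (MLE)
#>   n = 138, log-likelihood = -808.901
#>   shape (beta)  0.4459  [0.3914, 0.5079]
#>   scale (lambda) 115.7 days  [77.91, 171.9]
#>   hazard: decreasing
#>   GOF (parametric bootstrap, 200 reps): KS p = 0.0149, AD p = 0.00498
```

The five flagged PTs are exactly the five terms the generator injected
with relative risk 10; none of the 95 null terms is flagged. The Weibull
shape 0.45 (CI below 1) recovers the generator's onset law
(shape 0.43, scale 111.77 days) and classifies the hazard as decreasing
— most reported events occur within the first month of therapy
(`res$tto_summary$bins`: 47% ≤ 30 days here). The small goodness-of-fit
p-values reflect the day-resolution discretization of date-derived onset
times, the same pattern seen with real report data.

Plot helpers: `plot_signals(res$signals)` (forest-style ROR ranking),
`autoplot(km_estimate(res$tto$records))`, and
`autoplot(res$weibull, res$tto$records)`; `tidy()`/`glance()` methods
expose fits as tables.

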