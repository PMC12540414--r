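---
title: "Methods: consensus disproportionality analysis and onset modeling for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus disproportionality analysis and onset modeling for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it
implements, the assumptions behind them, and the design choices made
where the methodology leaves room.

## The case-report model

Everything downstream operates on one tidy case-report table: one row
per report version, with nested list-columns for drug entries (name,
role code, therapy start date) and event entries (MedDRA preferred
terms, treated as opaque labels). Both source dialects — the
`$`-delimited FAERS quarterly files and the comma-delimited JADER tables
— parse onto this model, so every statistic is dialect-agnostic.

Three cleaning rules are load-bearing:

* **Deduplication.** SRS archives ship every received version of a case;
  `deduplicate_reports()` keeps the version with the latest receipt date.
  The tie-break on equal dates (greatest source row identifier) is not
  dictated by any convention; it was chosen solely to make output
  deterministic.
* **Partial dates.** Dates arrive as 8-, 6- or 4-digit strings.
  They are carried with a `day`/`month`/`year` precision flag rather than
  silently coerced, and only day-precision dates may enter date
  arithmetic. Anything else is treated as absent.
* **Whole-token drug matching.** A drug name matches a pattern when the
  pattern's letter-token sequence occurs as consecutive tokens of the
  case-folded name (a token is a maximal run of letters). Substring
  matching would let congeners (sufentanil, alfentanil, remifentanil)
  contaminate a fentanyl series; token matching excludes them while
  still catching salt forms ("FENTANYL CITRATE") and formulation
  suffixes ("DURAGESIC-100"). The cost is that agglutinative scripts
  without separators are matched only as whole tokens — Japanese
  compound brand strings must be listed explicitly in the pattern list.

Reports with no event entries after the join are excluded from all
counts (with a logged tally): they carry no analyzable information and
would silently shrink reporting proportions.

## Contingency tables

For each PT, `build_contingency()` counts the 2×2 cells of the target
series against a **rest-of-database comparator**: all deduplicated
reports in which the target drug is not a matched primary suspect. The
comparator population and the counting unit are genuine free choices in
disproportionality work; this package uses rest-of-database (the default
in SRS practice, and the natural choice for a single-drug analysis) and
**case-level counting** — a case contributes at most once per PT however
many duplicate event rows it carries — so the margins `a+b` and `c+d`
are constant across PTs and the tables remain interpretable as report
counts. Both choices are stated here because results do change under
alternatives (drug–event-pair counting inflates margins for polypharmacy
reports; active-comparator designs answer a different question).

## The four algorithms and the consensus rule

The frequentist pair (ROR, PRR with Yates-corrected χ²) and the Bayesian
pair (BCPNN information component, MGPS/EBGM) are computed per table.
Implementation notes:

* **Zero cells.** ROR and PRR are non-evaluable when a required cell is
  zero; no continuity correction is applied. A non-evaluable statistic
  *fails* the consensus criterion rather than being imputed — the rule
  is deliberately conservative.
* **BCPNN** uses the closed-form posterior-moment approximation with the
  customary pseudo-counts (1 on margin numerators, 2 on denominators, 1
  on the joint cell; the joint denominator pseudo-count is derived per
  table so the prior IC is centred at zero). This is reproducible
  without MCMC. The approximation reports the log of posterior means;
  its error is O(1/a) — about 0.05 bits at a = 10, negligible by
  a = 100 — which is why the Monte-Carlo cross-check in the test suite
  runs at moderate counts.
* **MGPS** hyperparameters are fitted by marginal maximum likelihood on
  the *full* drug×event cell grid of the run (zero cells included; they
  inform the low-rate mixture component), with expected counts from the
  independence margins. Optimization is multi-start BFGS on an
  unconstrained transform (log shapes/rates, logit weight) from the
  canonical initialization (0.2, 0.1, 2, 4, 1/3) plus three fixed
  alternative starts; non-finite likelihoods are clamped so the line
  search cannot escape the domain. `EB05` is found by bracketed root
  search on the posterior-mixture CDF to tolerance 1e-8.
* **Multiplicity.** The framework produces exactly one p-value per PT
  (the PRR χ²); the Bonferroni correction is applied to it with m = the
  number of PTs evaluated in the run, per database, and entered as a
  fifth consensus condition. Applying it to a different statistic, or
  pooled across databases, would be defensible too; this choice is the
  most conservative one available within the framework.
* **Thresholds** (`a ≥ 3` & ROR CI lower > 1; PRR ≥ 2 & χ² ≥ 4;
  IC025 > 0; EB05 ≥ 2; adjusted p < 0.05) are the canonical cut-offs of
  the respective method literatures. They are defaults of
  `signal_thresholds()`, not constants.

Sex-subgroup odds ratios are oriented female:male, so values below 1
indicate a male excess. The p-value uses the Yates χ² but switches to
Fisher's exact test when any expected cell is below 5; with a zero cell
only the Fisher output (conditional-MLE estimate) is returned, flagged.

## Time to onset

Onset is the day count from the earliest matched primary-suspect therapy
start to the event date; negative intervals and non-day-precision dates
are excluded with a per-reason tally. **Same-day onsets map to 0.5
days** rather than being dropped: the Weibull likelihood needs t > 0 and
immediate-onset events are clinically central for a rapid-acting opioid,
so excluding them would bias the shape upward.

The Weibull fit maximizes the log-likelihood through the profile
identity λ̂(β) = (mean tᵝ)^{1/β} and a one-dimensional search over
β ∈ [0.05, 20] (tolerance 1e-9; a solution at the boundary is an error,
not a result). Confidence intervals come from the inverse observed
information on the log-parameter scale, back-transformed, which respects
positivity. The hazard classification follows the interval: decreasing
iff the upper shape bound is below 1, increasing iff the lower bound
exceeds 1, constant otherwise.

Goodness of fit uses Kolmogorov–Smirnov and Anderson–Darling statistics
with **parametric-bootstrap** p-values (default 500 replicates,
re-estimating the parameters in each replicate): the asymptotic null
distributions assume known parameters and are anti-conservative after
fitting. Two practical notes: bootstrap p-values live on a lattice of
1/(B+1); and onset times derived from calendar dates are integers, so at
large n the GOF tests correctly report this discretization as lack of
fit — near-zero GOF p-values alongside a stable shape estimate are the
expected signature of date-resolution data, not a fitting failure. The
free fit requires at least 5 observations (below 10 a warning marks the
estimates unstable); with a fixed shape the profile identity needs only
2. The Kaplan–Meier curve is delegated to `survival::survfit()`; with no
censoring — SRS records are all events — it equals one minus the
empirical CDF and is kept for its conventional presentation.

## The synthetic-report generator

`sim_config()` fixes the study conditions the test suite runs under:
20,000 cases of which 5% carry the target drug as primary suspect; a
100-term vocabulary with geometrically tapering baseline probabilities
(0.12·0.95^(i−1), about 2.4 events per case); five mid-frequency terms
injected at relative risk 10; one term with a 2-fold female rate ratio;
onset times from Weibull(shape 0.43, scale 111.77 days); missingness
rates mirroring the published demographic table (12% sex, 72% weight,
25% of therapy/event dates absent, 5% degraded to month precision); and
10% duplicated report versions. Where the emulated case series did not
pin a value (background-drug count, concomitant-drug rate, reporting
delay of 10–100 days), a single realistic choice was made and kept.
Cases that draw no event receive one probability-weighted forced draw,
so every emitted report is analyzable; the forced draws are
arm-symmetric and leave disproportionality null-neutral.

Events are independent across PTs within a case. That is sufficient for
testing contingency margins and recovery of injected effects, but it is
a real simplification: actual reports carry correlated event clusters,
polypharmacy structure, country mixes and reporting-rate seasonality
that the generator does not attempt. Passing the recovery tests
therefore demonstrates that the *algorithms* are implemented correctly
and calibrated under the null — not that real-data signals at these
thresholds have any particular positive predictive value.

## Problem sizes and determinism

The test suite runs the full pipeline at 20,000 synthetic cases for
end-to-end recovery, 5,000 for subgroup and onset-law checks, and
reduced bootstrap replicate counts (99–200) for goodness-of-fit
calibration; these sizes give comfortable separation between injected
and null effects while keeping a complete run around a minute. All
generation and detection is seed-deterministic: the same seed produces
byte-identical report files and signal tables.

## Known limitations

* Disproportionality quantifies reporting, not risk; no denominator
  exists and no causal reading is licensed.
* The BCPNN closed form is a moment approximation; for cells with very
  few reports its interval is approximate (the consensus minimum-count
  rule `a ≥ 3` keeps it out of its worst regime).
* The MGPS implementation is single-item: drug–drug interaction scoring
  is out of scope.
* JADER files carry no reporter categories beyond those coded, and the
  dialect's role vocabulary has no secondary-suspect code; the suspect
  code maps to primary suspect, a stated assumption.
* TTO analysis keys on the earliest primary-suspect therapy start; when
  several therapy episodes exist the choice of anchor is a convention.
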