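---
title: "Reproducing meta-analyses: models, thresholds, and the synthetic corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducing meta-analyses: models, thresholds, and the synthetic corpus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprometa)
```

`reprometa` implements the quantitative core of a meta-analysis
reproducibility audit: recompute a review's pooled result from its
study-level data under the methods the review (partially) reported, then
measure how far the recomputation lands from the printed numbers. This
vignette explains the statistical machinery, the parameters that matter,
what the synthetic corpus does and does not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Effect measures

Each study enters as an effect `y_i` with variance `v_i` on the
*analysis scale* — the natural-log scale for odds, risk, and hazard
ratios; the raw scale for mean differences. Three routes produce
`(y_i, v_i)`:

* **Binary arm data** (`effect_binary`): the standard 2×2 log effect
  with delta-method variance, e.g. for the log OR
  `v = 1/a + 1/b + 1/c + 1/d`. When any cell is zero the continuity rule
  adds 0.5 to all four cells of that table (the dominant software
  convention; configurable, because reviews rarely state which rule they
  used). Tables with zero events in both arms — or events everywhere —
  carry no information about a ratio and are flagged non-estimable
  rather than corrected, then excluded from pooling with a recorded
  reason.
* **Continuous arm data** (`effect_continuous`): MD with
  `v = sd1²/n1 + sd2²/n2`; SMD via the pooled SD. The default SMD
  variant is Hedges' *g*: the small-sample factor
  `J = 1 − 3/(4(n1+n2−2)−1)` multiplies the estimate and `J²` the
  large-sample variance `1/n1 + 1/n2 + d²/(2(n1+n2))`. Before–after
  designs require the pre/post correlation `r` to form the change-score
  SD `sqrt(sd_pre² + sd_post² − 2 r sd_pre sd_post)`; omitting `r` is a
  hard error naming the missing input, because silently assuming one
  (commonly r = 0.5) is exactly the kind of undocumented choice the
  pipeline exists to surface.
* **Reported estimate + CI** (`effect_from_reported`): inverting the
  Wald interval, `SE = (hi − lo)/(2 z)` after log-transforming ratio
  measures. The package always uses the exact normal quantile
  (`qnorm(0.975)` = 1.959964…), never a rounded 1.96, so that
  CI construction and inversion are mutual inverses to ~1e-10. Hazard
  ratios are accepted *only* through this route: reconstructing them
  from Kaplan–Meier curves is out of scope, matching how reproduction
  studies treat them in practice.

## 2. The pooling engine

`pool_inverse_variance` uses weights `w_i = 1/(v_i + τ²)` with τ² = 0
for the fixed-effect model. Between-study variance estimators
(`estimate_tau2`):

* **DL** — method of moments on Cochran's Q, truncated at zero.
* **REML** — Fisher scoring on the restricted log-likelihood, tolerance
  1e-10, at most 100 iterations; if the iteration leaves the feasible
  range or fails to converge, a bracketed 201-point grid followed by
  golden-section refinement (`stats::optimize`, tol 1e-12) takes over.
  In tests the converged values coincide with an independent 1e-8
  grid-search oracle to better than 1e-8.
* **PM** — the Paule–Mandel root of the generalised-Q estimating
  equation via `uniroot` (tol 1e-12), zero when the equation is already
  below its target at τ² = 0.

Intervals are Wald (`y ± z·se`, two-sided P from the normal) or
Hartung–Knapp: the weighted residual variance
`Σ w_i (y_i − ŷ)² / ((k−1) Σ w_i)` with a t interval on k − 1 df. The
plain HK variance is used — no flooring at the Wald variance — matching
common software defaults; a single-study "meta-analysis" under a
random-effects request falls back to fixed effect with a recorded note.

`pool_mantel_haenszel` pools 2×2 tables directly (fixed effect), with
the Robins–Breslow–Greenland variance for the log pooled OR and the
Greenland–Robins variance for the log pooled RR. No continuity
correction is applied inside MH — its sparse-data validity is the reason
to use it — while double-zero strata drop out with a note. The Q and I²
reported alongside an MH result come from the per-study inverse-variance
effects (continuity-corrected for that purpose only), a display
convention; the spec of the MH estimator itself never needs them.

## 3. Resolving incompletely reported methods

Most reviews report some of {software, package, model, pooling method,
τ² estimator, interval method, continuity rule, level}. `resolve_methods`
fills the gaps from an ordered rule table (`default_rule_table()`, or a
YAML file via `read_rule_table`): the first matching rule fills any
still-empty fields, never overriding what the review reported, and the
table must end in a universal fallback so resolution is total. Per-field
provenance (`"reported"` or the rule id) is returned for audit, because
which assumptions were made is itself a result of a reproduction study.

The shipped defaults: Mantel–Haenszel implies a fixed-effect model;
RevMan and Stata's `metan` imply DerSimonian–Laird; otherwise the
fallback is a random-effects inverse-variance analysis with REML — the
default of the `meta` package in R, the natural default reproduction
software. These encodings live in the table, not in code, precisely
because software defaults differ and a user auditing a different corpus
should be able to swap them without touching the package. An internally
contradictory report (MH with a random-effects model, or with a
continuous measure) is an error naming the clash rather than a silent
"fix".

## 4. Classification thresholds and meaningful differences

`classify_reproducibility` computes
`|θ̂_r − θ̂_o| / |θ̂_o|` for the estimate and the analogous relative
difference of the 95% CI widths; both below the threshold (default 10%,
sensitivity 5%) makes the attempt *fully reproducible*. Attempts with no
usable data are *cannot reproduce*. Two open choices are exposed as
options rather than guessed:

* **Comparison scale.** Ratio measures are compared on the reported
  (ratio) scale by default, since the printed review numbers live there;
  `scale = "log"` switches to the analysis scale. The scale used is
  recorded in each verdict. Relative differences on the ratio scale are
  invariant to rescaling both results by a constant.
* **Zero originals.** On a difference scale an original estimate at
  zero makes the relative difference undefined; the fallback divides the
  absolute difference by the original CI width instead (same threshold)
  and notes the fallback in the verdict.

A difference is *meaningful* when the two estimates sit on opposite
sides of the null (1 for ratios, 0 for differences) or when exactly one
of the two CIs includes the null. An estimate exactly at the null has no
direction and can never flip. P values are compared by significance band
(`<0.01`, `0.01–<0.05`, `0.05–<0.1`, `≥0.1`, boundaries in the upper
band) and only when the original reported one — absent is absent, not
discordant.

## 5. Agreement analyses

`bland_altman` summarises paired original/reproduced pooled estimates
per measure: mean difference, sample SD (n − 1), limits
`mean ± 1.959964·SD`, back-transformed for ratio measures into a ratio
of ratios with its limits. Measures with fewer than 4 pairs are skipped
with a note — limits of agreement from two or three pairs are noise.
`banksia_scale` maps each original result to the reference band
(estimate at 0, CI spanning −0.5 to 0.5) and applies the identical
affine map to the reproduced result; asymmetric original CIs keep the
estimate at 0 (endpoints at `(lo−est)/width`, `(hi−est)/width`), with
midpoint-centring available as an option since either convention is
defensible. Plots (`plot_bland_altman`, `plot_banksia`) are ggplot
objects; the statistics, not the pixels, are the tested surface.

Corpus tabulations (`tabulate_verdicts`) attach Clopper–Pearson exact
binomial intervals from beta quantiles; percentages are displayed
rounded half-up to integers, as results sections print them, while raw
proportions stay in the output.

## 6. The synthetic corpus

`simulate_review` builds one review from the ground up: study count
`k ~ round(lognormal(log 6, 0.75))` truncated to [2, 30] — median 6 with
an interquartile range of roughly 4–11, the typical size of an index
meta-analysis in published intervention reviews; per-study true effects
`θ_i = θ + u_i`, `u_i ~ N(0, τ²)`; then *arm-level* data (binomial event
counts at a 20% control risk for binary outcomes; normal means and
chi-square-distributed SDs for continuous ones; per-arm n uniform on
20–200), so both the summary-statistics route and the estimates-only
route can be exercised on the same review. Hazard-ratio reviews carry
per-study estimates and CIs only, with variances driven by simulated
event counts (`v_i = 4/events`). The "original" result is computed by
the package's own engine under the review's true method configuration —
the generator has no second analysis engine, which is what makes the
lossless identity check below exact rather than approximate.

`degrade_report` then applies reporting failure modes: dropping summary
statistics (`estimates_only`), blanking the methods (`no_methods`),
rounding every reported number to two decimals (`rounded_2dp`), removing
all usable data (`missing_all`), or replacing one digit of the printed
pooled estimate (`typo_injection`, with the truth recorded). Profiles
compose.

`run_reproduction_experiment` ties it together for a corpus. Its
defaults are fixed study conditions, chosen once: 121 reviews; an
availability mix of 33% lossless / 59% estimates-only / 8% unusable
(the usability split observed in published reproduction samples); a
measure mix of roughly MD 22%, SMD 27%, OR 28%, RR 20%, HR 3%; true
configurations drawn 50% random-DL, 30% random-REML, 10% fixed-IV, 10%
fixed-MH (binary only); τ² zero for a quarter of reviews and
exponential with mean 0.05 otherwise; difference-scale effects
`N(0.3, 0.25²)` and log-ratio effects `N(−0.4, 0.3²)` at a 20% baseline
risk; a P value printed by 54% of reviews; author involvement labelled
for 18%. Each review gets its own RNG stream derived from
`(master seed, index)`, so corpora are reproducible regardless of
generation order.

**What the generator does not emulate:** real extraction error, forest
plots as images, correspondence behaviour, non-normal outcome
distributions, correlated arms, or selective reporting. Passing the
identity and perturbation checks therefore shows the *pipeline* is
faithful — that information loss, and only information loss, drives
classification changes — not that any particular real corpus would
reproduce at any particular rate.

## 7. Problem sizes and numerical checks

The shipped tests run the corpus experiments at 60–150 reviews and the
property sweeps at 200–500 replicates — sizes at which every stochastic
assertion is stable across seeds while the whole suite stays fast. The
acceptance script uses a 121-review corpus plus a 100-review identity
corpus. Key numeric checks worth knowing about:

* Fixed-effect pooling matches a brute-force weighted mean to 1e-12;
  DL matches its closed form to 1e-12; REML matches an independent
  grid-search oracle to 1e-6 (observed: <1e-8).
* A lossless corpus reproduces with every relative difference below
  1e-6 and zero meaningful differences.
* Every perturbation of a printed estimate by ≥10% (relative, as the
  classifier measures it) is flagged not fully reproducible, and every
  10% failure also fails at 5%.
* Clopper–Pearson coverage at n = 20 is verified by exact enumeration,
  not simulation.

## 8. Known limitations

* **Rounding at the boundary.** Two-decimal rounding of a report whose
  printed estimate is near 0.1 can by itself approach the 10% rule: the
  rounding grain (0.005) is 5% of the denominator, and re-estimating τ²
  from rounded inputs can contribute a similar amount. With small
  printed estimates, borderline classifications genuinely flip under
  rounding alone — a property of the 10%-of-the-estimate rule, not a
  pipeline defect — so the guarantee tested is for printed estimates at
  least one grain above the 0.1 boundary.
* The Hartung–Knapp implementation is the plain (unfloored) variant;
  modified HK is not offered.
* Method resolution is only as good as its rule table; the shipped
  table encodes broad software conventions, not version-specific
  behaviour.
* Cross-version RNG stability of the generator is not guaranteed; the
  determinism contract is within one R version.
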