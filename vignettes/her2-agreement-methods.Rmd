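---
title: "Agreement statistics for HER2 IHC scoring panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement statistics for HER2 IHC scoring panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2agree)
```

## The problem

HER2 immunohistochemistry is scored on an ordinal four-point scale — 0, 1+,
2+, 3+ — and the score drives therapy: 3+ (or amplified 2+) tumours get
classical anti-HER2 agents, while the newer antibody-drug conjugates extend
eligibility into the "HER2-low" range (1+ and non-amplified 2+). That makes
the *reproducibility* of the score across pathologists a clinical quantity in
its own right, particularly at the 0 vs 1+ boundary that now separates
"true negative" from treatable-low. This package provides the statistical
machinery for studying that reproducibility on a panel of R observers who
each score the same N cases: agreement coefficients with intervals, category
merges and clinically motivated dichotomizations, "score assigned by at least
one observer" case subsets, observer-resampling (ONEST) curves, and a
generative simulator for testing all of it.

All analyses assume a *balanced complete* panel — every observer scored every
case. Missing cells are rejected at input rather than imputed, because every
formula below uses a constant number of ratings per case; partial panels are
out of scope.

## The three agreement statistics

**Overall percent agreement (OPA).** The fraction of cases on which all R
observers assign the identical category,
$\mathrm{OPA} = \tfrac{1}{N}\sum_i \mathbf{1}\{n_{ij}=R \text{ for some } j\}$,
where $n_{ij}$ counts the observers giving case $i$ category $j$. It is a
binomial proportion on the unanimous-case count, so its 95% interval is a
binomial interval. We use the Wilson score interval by default. The choice
matters at the boundary: panels in this setting regularly produce *zero*
unanimous cases in a subset, and a case-resampling bootstrap can never put a
nonzero upper bound on a zero count, whereas Wilson gives the informative
bound $z^2/(n+z^2)$ (for $n = 217$ that is 0.0174, i.e. "0.00 (0.00–0.02)")
and its lower bound is exactly 0 there. Clopper–Pearson is available as an
option for users who prefer a conservative exact interval; both reproduce the
same two-decimal bounds on the examples we checked.

**Fleiss' kappa.** Chance-corrected agreement for R raters and C nominal
categories, computed from the count table: per-case agreement
$P_i = \big(\sum_j n_{ij}^2 - R\big)/\big(R(R-1)\big)$, observed agreement
$\bar P = \tfrac1N \sum_i P_i$, chance agreement $\bar P_e = \sum_j p_j^2$
with pooled marginals $p_j = \sum_i n_{ij}/(NR)$, and
$\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$. The interval is
$\kappa \pm 1.96\,\mathrm{SE}$ with the Fleiss–Nee–Landis fixed-marginal
large-sample standard error. Published concordance tables sometimes print
zero-width kappa intervals (an artifact of how some software reports the
statistic); we deliberately do not reproduce that and always report the
large-sample interval. When every rating falls into a single category,
$\bar P_e = 1$ and kappa has no value: the package returns a typed
"undefined" marker rather than a numeric stand-in, and report assembly turns
it into a footnote instead of aborting.

**ICC(A,1).** The intraclass correlation from a two-way random-effects ANOVA
(cases and observers both random), absolute-agreement definition, single
rater as the unit: with mean squares $MS_R$ (cases), $MS_C$ (observers),
$MS_E$ (residual) from the $n \times k$ layout,
$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
 {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$
with the McGraw–Wong F-based interval (Satterthwaite degrees of freedom).
Ordinal categories enter as their numeric codes 0–3; after a dichotomization
the recoded schema is coded 0/1, so binary splits get a binary ICC. Coding
ordinal labels as equally spaced integers is an assumption, not a theorem —
it is the convention of the SPSS-style two-way random workflow this mirrors,
and the reason the ICC should be read alongside kappa rather than instead of
it. A panel with no variance at all (every rating identical) has no ICC and
returns the undefined marker.

## Groupings: merges, dichotomizations, subsets

`table1_report()` assembles the standard 13-row concordance table: the
4-category scheme; the 3-category scheme (merging 1+ and 2+ into "low"); the
five "X only" subsets (cases given score X by at least one observer, for
X = 0, 1+, 2+, 3+, low); and six dichotomizations (0 / not 0, 1+ / not 1+,
2+ / not 2+, low / not low, 3+ / not 3+, <2+ / ≥2+, the last being the
FISH-reflex boundary). Two conventions deserve a note:

* Subset rows keep the **original 4-category codes** — the subset changes
  which cases are analysed, not the scale. This matches the observation that
  all four categories appear inside every such subset of a real panel.
* "low only" is implemented as the **union** rule — at least one observer
  assigned 1+ *or* 2+. The alternative reading (at least one observer
  assigned the *merged* category after recoding) is equivalent, since a 1+ or
  2+ rating becomes a "low" rating under the merge.

Coarsening can only preserve or create unanimity, never destroy it, so every
merge or dichotomization has OPA at least that of the 4-category scheme; the
test suite asserts this as a property on random panels.

## ONEST

The Observers Needed to Evaluate a Subjective Test procedure asks how many
observers are needed before the panel's agreement estimate stops changing.
For a random ordering $p$ of the R observers and each $k = 2..R$, compute
$O_p(k)$, the OPA of the first $k$ observers of $p$; repeat over many
orderings and summarise per $k$ with the minimum, mean and maximum. Every
individual curve is non-increasing in $k$ (unanimity among $k+1$ observers
implies unanimity among the first $k$), and the mean curve at $k = R$ is
exactly the full-panel OPA — both are asserted in tests.

Tunables, with defaults:

* `n_permutations = 1000` sampled orderings (independent uniform draws;
  collisions are irrelevant at R = 15 where $R! \approx 1.3\times10^{12}$).
  A seed is required: the curve set is fully reproducible.
* `exhaustive = TRUE` enumerates all $R!$ orderings while
  $R! \le$ `max_exhaustive` (default 5040, i.e. $R \le 7$); the test suite
  checks the sampled bands against exhaustive enumeration on 5-observer toys.
* `plateau_epsilon = 0.01` OPA units. The plateau is defined on the **mean**
  curve: the smallest $k$ such that every later mean stays within epsilon of
  the full-panel value, returning R when nothing earlier qualifies. Published
  plateau statements are typically "approximately k raters"; epsilon is
  surfaced precisely because that criterion is soft, and plateau claims
  should be treated as ±2 observers at this epsilon.

## The simulator

`simulate_panel()` draws from the standard latent-class rater model: case
$i$ has a latent true category $T_i$ from a prevalence vector $\pi$, and
observer $r$ emits a score from row $T_i$ of its own row-stochastic confusion
matrix $M_r$, conditionally independently across observers. Heterogeneity is
parameterised as a blend $M_r = (1-\eta_r)\,T + \eta_r\,S$ between a shared
template $T$ and a "smear" matrix $S$ that spreads mass onto adjacent
categories; strata are groups of observers sharing a noise level, and a
specimen effect applies an extra blend towards $S$ for a flagged subset of
cases. Under this model the expected OPA has the closed form
$$\mathbb{E}[\mathrm{OPA}] = \sum_t \pi_t \sum_c \prod_{r=1}^{R} M_r[t, c],$$
implemented as `expected_opa()` and used to anchor the estimator-recovery
tests (simulated means must land within 3 Monte-Carlo standard errors).

The shipped `her2_default_config()` is a 460-case, 15-rater, 4-category
configuration emulating a multi-institutional gastric-cancer HER2 panel:

* prevalence $(0.25, 0.30, 0.32, 0.13)$ over 0/1+/2+/3+ — a caseload with a
  broad low-expression middle and a minority of clear 3+ tumours;
* a template whose off-diagonal mass concentrates on the 0↔1+ boundary
  (heaviest), then 1+↔2+, with 3+ calls the most reliable — the confusion
  geometry reported wherever HER2-low scoring has been studied;
* two experience strata, 8 "senior" observers at $\eta = 0$ and 7 "junior"
  at $\eta = 0.15$, so senior sub-panels agree more often by construction;
* 54 of 460 cases flagged as biopsies with extra confusion noise
  ($\beta = 0.20$), making biopsy agreement lower than surgical.

These values were fixed once, via the closed form, so that the expected
4-category OPA (0.123) sits inside the 0.08–0.22 band bracketing reported
panel OPAs, per-rater 3+ assignment probabilities (~0.14) sit inside the
reported 7.4%–19.6% per-rater range, and 0↔1+ ratings dominate the
0-subset discordance. They are calibration targets, not fitted estimates.

What the simulator deliberately does **not** reproduce: real pathologists
are not conditionally independent given a four-level truth — slides have
continuous staining intensity, shared difficulty, and batch effects that
induce correlated errors. One visible consequence: a conditionally
independent panel cannot simultaneously match a real panel's overall OPA and
its complete absence of unanimous 0-subset cases, because independence
spreads unanimity across all truth classes instead of concentrating it in
"easy" 2+/3+ cases. Chance-corrected statistics feel this too — the
simulator's kappa and ICC run higher than a real panel with the same OPA.
Passing tests therefore certify the *estimators and procedure*, not that the
generator is a statistical twin of any real panel; analyses of real data
should use the deposited study matrix via `her2_study_scores()`.

## Numerical and design choices

* **Display rounding** is half-away-from-zero at 2 decimals
  (`round_half_up()`), matching clinical table typesetting; full precision is
  kept internally and in TSV/JSON exports.
* **Wilson at the boundary**: the analytic lower bound at a zero count is
  forced to exactly 0 (the closed form underflows to ~1e-18).
* **Degenerate ICC**: when the residual mean square is exactly zero but the
  panel has case variance (observers perfectly identical), the interval
  collapses onto the estimate 1 rather than invoking the F quantiles.
* **Input dialects**: score CSVs may use labels ("1+") or integer codes (1),
  in any mixture; output always writes labels. A `transposed` flag accepts
  observer-by-case layouts. Case and observer order is preserved as read —
  per-case exports depend on input order.
* **Seed fan-out**: `run_full_analysis()` derives named substreams from one
  top-level seed, so the ONEST and simulation components of a run are
  individually reproducible; re-running a configuration is byte-identical
  (the manifest carries MD5 checksums and no timestamps).
* **Problem sizes in the test suite** were chosen to keep the default run
  fast while leaving the checks sharp: brute-force oracle comparisons on
  random panels up to 12×6, exhaustive ONEST enumeration at R = 5 (120
  orderings), recovery suites of 10–15 replicates at N = 250–300, and the
  full 460×15 configuration wherever a single simulated panel suffices.

## Limitations

* Balanced complete panels only; no missing-data support.
* No weighted kappa, pairwise Cohen's kappa, or Krippendorff's alpha; the
  three implemented statistics are the ones this analysis design uses.
* The ICC treats ordinal codes as interval-scaled; see above.
* ONEST confidence summaries are the min/max/mean band; no parametric
  convergence model is fitted to the curves.
* The simulator's conditional-independence assumption understates the
  clustering of disagreement seen in real panels; it is a test harness and
  calibration tool, not a data twin.
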