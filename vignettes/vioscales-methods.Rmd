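---
title: "Methods: violence-situation typology and scale reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: violence-situation typology and scale reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Forensic physicians who examine individuals exposed to violence certify
functional impairment — in France as days of *total incapacity to work*
(TIW) — and increasingly record subjective elements (pain, fear, perceived
life threat) on short 7-level Likert scales scored 0–6.  Whether such scales
are usable in a judicial context hinges on two questions: do they carry
information about functional impairment, and do different physicians (or the
same physician on comparable patients) rate them consistently?

A direct test–retest design is impossible here: a first consultation for
violence cannot be repeated.  The workaround implemented by this package is
a two-stage design.  First, a *typology of violence situations* is built
from the mixed consultation features (demographics, assault type, assailant,
location, physical trauma), so that patients within one profile experienced
comparable situations.  Second, patients are randomly matched *within*
profiles — between two physicians for interrater, within one physician for
intrarater reproducibility — and the concordance of their scale scores is
measured with the tie-corrected Kendall coefficient of concordance.

Because real consultation records of this kind are private, the package
includes a synthetic-cohort generator that reproduces the statistical
structure this analysis assumes.  Every stage is therefore testable end to
end against a known ground truth.

## The synthetic cohort

`generate_cohort()` draws, for each patient:

* a latent profile from five categories (A–E) with mixing proportions
  (779, 749, 719, 1092, 841)/4180 — profile A: low-impact assaults by
  single assailants; B: multiple, often unknown assailants; C: young men in
  police custody reporting police violence; D: high-impact single-assailant
  assaults with systematic injury; E: repeated intimate partner violence
  against women;
* 45 binary situation features as independent Bernoulli draws given the
  profile, with the per-profile frequencies of the packaged default
  configuration (`inst/extdata/default_config.json`);
* age and consultation delay from per-profile log-normal distributions
  matched to target medians and IQRs (meanlog = log median, sdlog =
  log(Q3/Q1)/(2·z₀.₇₅)); ages are truncated below 10 years by inverse-CDF
  sampling;
* nine ordinal scales from a latent Gaussian
  `profile mean + physician bias + patient heterogeneity + rater noise`,
  rounded and clamped to {0,…,6}.  Rounding+clamping a latent Gaussian is
  the simplest mechanism that yields the skewed, tie-heavy score
  distributions seen in practice (e.g. a floor-inflated life-threat scale);
* TIW days as `max(0, round(intercept + Σ coef·score + ε))`, computed from
  the *observed* scores, so that downstream regression recovers planted
  coefficients exactly up to rounding noise.

Physician bias is drawn once per (physician, scale) and shared by all of
that physician's patients — it is precisely the systematic component of
interrater disagreement the concordance stage must detect.  Patient
heterogeneity is drawn per (patient, scale), rater noise per observation.

Features are conditionally independent given the profile: only marginal
frequencies are credibly known per profile, and inventing a dependence
structure would add assumptions the analysis does not need.  The main
consequence is that profile separation in the synthetic data is somewhat
weaker than in real records, where features co-occur; recovery results
below should be read with that in mind.

Missingness (`apply_missingness()`) is missing-completely-at-random at the
record level: a Bernoulli-selected subset of records has a random nonempty
subset of scale fields blanked.  The generator defaults to ten physicians
with near-uniform caseloads of roughly 420 patients each, matching the
forty-five physician pairs that a ten-physician department yields and
clearing the 300-patients-per-year eligibility rule.  An optional
`profile_affinity` matrix lets physicians see different case mixes, which
is needed to demonstrate case-mix confounding of naive between-physician
comparisons.

### Noise defaults

`rater_bias_sd = 0.3`, `rater_noise_sd = 1.0` and `patient_noise_sd = 3.0`
were fixed once by a small pilot grid: they are the setting at which the
pooled interrater W of the default cohort spans roughly 0.46–0.66 across
physician pairs and scales — the "mild to good" band reported for scales
of this kind in real consultations.  The large patient-heterogeneity
component is not a nuisance choice: concordance between *different matched
patients* is bounded by the between-profile share of the score variance, so
observed W values near 0.5–0.65 *imply* large within-profile heterogeneity
under this design.

## Certificate text and mining

`render_certificates()` writes a short standardized French certificate per
record; for each active symptom flag (sleep disorder, loss of appetite,
stress symptoms, pain, fear) one lexicon surface term is embedded, corrupted
with probability `typo_rate` by a single random character edit (letters
only, so tokenization is preserved).  `extract_features()` normalizes text
(lower case, accents stripped, punctuation collapsed), tokenizes, and
fuzzy-matches tokens (and n-grams, for multiword terms) against lexicon
terms and variants under a length-banded Levenshtein policy: 0 edits below
5 characters, 1 for 5–8, 2 above 8.  The band prevents short-token false
positives ("pour" vs "peur") while tolerating one realistic typo in any
term of 5+ characters.  Negation is deliberately not handled — the
extraction is a plain term search, and the generator never produces negated
mentions.  The packaged lexicon embeds only terms of ≥5 characters (short
forms like "peur" remain matchable variants), so single-edit typos can
never push an embedded term outside its tolerance; flag recovery is by
construction near-perfect in sensitivity and specificity, which the test
suite verifies empirically (≥0.95 / ≥0.99 at a 10% typo rate).

## The typology

`gower_dissimilarity()` computes pairwise Gower dissimilarity over the
situation variables: binary features contribute 0/1 mismatches, numeric
features |difference|/range, missing values are skipped with
renormalization.  Gower is the natural choice for mixed binary/numeric
records; no alternative metric is offered.  The clustering variables are
the situation blocks (patient demographics, assault type, physical trauma,
assailant, location, assault characteristics) — the scales are *excluded*,
since they are subsequently evaluated against the profiles and letting them
define the profiles would be circular.  TIW is likewise excluded by
default but can be added through the feature spec, since impairment can be
read as part of the "assault outcome" describing a situation.

`pam_medoids()` wraps the classical partitioning-around-medoids algorithm
(BUILD seeding, then best-improvement SWAP).  SWAP is a local search: on
random small instances it misses the exhaustive-search optimum a few
percent of the time.  The default therefore adds nine random-initialization
SWAP runs and keeps the lowest-cost solution, which empirically restores
agreement with exhaustive enumeration on all instances small enough to
enumerate, at a known 10× cost.  Inside the consensus loop a single
deterministic BUILD+SWAP per resample is used instead: the resampling
itself averages out local-search variability, and the 5× price would be
paid hundreds of times.

`consensus_clustering()` follows the consensus-resampling idea: for each
candidate k it subsamples the cohort without replacement (the same
subsample plan is reused across k, so candidates are compared on identical
draws), clusters each subsample, and records how often each co-sampled pair
is co-clustered.  Four metrics summarize stability per k:

* **PAC**, the proportion of defined off-diagonal consensus entries in
  (0.1, 0.9) — the standard operationalization of "ambiguous"
  co-clustering (lower is better);
* **mean within-cluster consensus** under a full-data PAM reference
  partition at the same k;
* **Jaccard stability**, the mean Jaccard similarity between each run's
  co-clustered pair set and the reference partition restricted to the
  subsample;
* **consensus silhouette**, the mean silhouette width of the reference
  partition on 1 − consensus, averaging over defined entries only.

Pairs never co-sampled are flagged undefined and excluded from all metrics
(at the default 20% subsamples and 50 runs, roughly 13% of pairs).
`select_n_profiles()` ranks candidates on each metric and selects the best
mean rank, breaking ties toward the smaller k.  A rank combination was
chosen over any weighted score because the four metrics live on different
scales; ties toward smaller k express a mild parsimony preference.  The
default scan is k = 2–10, comfortably bracketing the five planted profiles.
At full study scale (n = 4180, 50 resamples of 20%) the procedure selects
k = 5, with PAC dipping sharply at 5; the acceptance script reruns exactly
this experiment.

## Concordance

`kendall_w()` implements the tie-corrected coefficient of concordance

$$W = \frac{12\,S}{m^2(n^3-n) - m\sum_j T_j}, \qquad
  S = \sum_i \Big(R_i - \tfrac{m(n+1)}{2}\Big)^2,$$

with mid-ranks within each rater column and tie terms
$T_j = \sum (t^3 - t)$.  For two raters without ties, $W = (\rho_S + 1)/2$;
the test suite uses this identity, plus a worked tie example ($W = 0.75$),
as independent oracles.  A denominator that is not positive (all columns
constant) yields `NA` rather than a number.

The matching designs mirror the study: `match_interrater()` draws, per
shared profile, equal-size subsamples of two physicians' patients and a
uniform-random bijection between them; `match_intrarater()` partitions one
physician's patients per profile into uniform-random disjoint pairs.  Both
are deterministic given a seed, and the test suite checks uniformity over
the enumerable micro-cases.  `concordance_analysis()` repeats the matching
(default R = 100 repetitions) and reports the mean and 2.5/97.5 percentiles
of W over repetitions — single matchings leave a matching-lottery
component in W; the repetition is a deliberate extension and both
per-profile and pooled (pairs concatenated across profiles) values are
emitted because either aggregation level is defensible.  Patients with a
missing value on the analysed scale are excluded pairwise; cells with fewer
than two usable pairs are reported as undefined rather than dropped.

`sensitivity_fine_profiles()` reruns the matching after re-profiling at a
much larger k (default n/5, mirroring a ~800-profile analysis at full
scale, implemented as a direct PAM at that k).  Base and fine runs share
the master seed so differences are attributable to granularity alone.  If
residual within-profile specificities depressed W, finer profiles should
raise it; on synthetic cohorts the effect is approximately neutral to
slightly positive, consistent with profiles already capturing the
structured heterogeneity.

## Scale characterization

`describe_by_profile()` reports median and Q1–Q3 (linear-interpolation
quantiles, matching the usual "median (IQR)" presentation).
`kruskal_wallis()` delegates to the tie-corrected Kruskal–Wallis test;
`conover_posthoc()` implements the Conover–Iman pairwise statistic on the
same pooled mid-ranking,

$$t = \frac{\bar R_i - \bar R_j}
  {\sqrt{S^2\,\frac{N-1-H}{N-k}\left(\frac1{n_i}+\frac1{n_j}\right)}},$$

with Student-t reference on N − k degrees of freedom and Bonferroni
adjustment over pairs.  The tie-corrected H is used inside $N-1-H$ (the
uncorrected variant differs only in heavily tied degenerate cases; using
the corrected H keeps the post hoc consistent with the global test it is
conditional on).  `ols_univariate()` fits the univariate least-squares
regression of TIW days on one scale with a normal-theory 95% CI.
`physician_rating_comparison()` runs the global and pairwise tests across
physicians, overall and within profiles: with differing case mixes the
overall comparison flags many pairs that vanish within profiles — the
case-mix confounding the typology exists to remove.

## Numerical choices and degenerate inputs

* All randomness flows through explicit integer seeds; stage seeds are
  derived from one master seed by a documented label hash, and the caller's
  RNG state is never disturbed.
* Ties are broken deterministically (lowest index / smaller k) everywhere.
* Degenerate inputs signal rather than guess: zero-range numeric clustering
  variables, pairs with no commonly observed variable, non-positive W
  denominators, `N−1−H ≤ 0` in the post hoc, and empty lexicon concepts
  all raise errors or return `NA` with the reason documented.
* Problem sizes in the test suite: full study scale (n = 4180, 50
  resamples at 20%, k = 2–10) for the profile-count experiment and the
  regression-recovery experiment (500 replicates); desk scale (n = 250–500,
  15–20 resamples) for the remaining properties, chosen so each run
  measures its property with comfortable Monte-Carlo margin.

## What passing tests do and do not show

The generator emulates marginal profile-conditional frequencies, rater
effects and a linear TIW link — not feature dependence within profiles, not
temporal symptom dynamics, not informative missingness, and not the
linguistic variety of real certificates.  Recovery of the planted profile
count, planted regression coefficients and planted symptom flags therefore
demonstrates that the pipeline is correct and well calibrated *under its
own assumptions*; it does not validate the clinical findings obtainable
from real records, which remain private.
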