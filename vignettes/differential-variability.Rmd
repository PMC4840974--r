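---
title: "Differential variability analysis of DNA methylation: models, tests, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential variability analysis of DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvmeth)
```

## Why differential variability

A CpG site's methylation state in a sample is summarized by its beta
value β ∈ [0, 1], the fraction of methylated signal. In precursor
lesions and normal tissue at risk of neoplastic transformation ("field
defects"), epigenetic deregulation typically affects only a subset of
samples at any given CpG: a few samples drift away from the tight
baseline distribution while the rest stay put. The phenotype means then
barely differ and mean-based tests find nothing, but the *variances*
differ strongly. `dvmeth` provides tests for this differential
variability (DV), organized around one central trade-off: tests that
are powerful for outlier-driven DV (Bartlett-type) have inflated
type-1 error on real, non-Gaussian methylation data, while robust
tests (Levene/deviation-based, robust score tests) control their error
rates by discounting exactly the outlier signal that is biologically
interesting here.

## Data model and scales

A `methylation_dataset` is a features × samples beta matrix with a
binary phenotype (0 = reference, 1 = disease/at-risk). Direction labels
("hyper"/"hypo") always describe group 1 relative to group 0. Two tests
operate directly on beta values (Bartlett/iEVORA and the moderated-t
baseline, following the convention that their statistics are defined on
the measurement scale); the Levene-type, joint score and location-scale
tests operate on M-values, M = log₂ β/(1−β), the variance-stabilized
logit scale on which Gaussian working models are more defensible.

Beta values are clipped into [ε, 1−ε] before the M-transform, with
ε = 0.001 by default. This bounds M-values to roughly ±9.97 and keeps
saturated probes (β exactly 0 or 1, which occur in real arrays) finite;
ε is well below the measurement noise of array betas, so the clip is
inert for all but fully saturated entries. Missing entries are dropped
per feature per group; a feature with fewer than 3 usable values in
either group yields a missing test result rather than an error, 3 being
the smallest group size for which a variance comparison is meaningful.

## The tests

**Bartlett (BT).** Two-group Bartlett statistic per CpG on beta values,
referred to χ²(1). Degenerate features — zero variance in one or both
groups — get missing results: a zero-variance group makes the statistic
infinite and its P-value carries no usable information, and a missing
result keeps such features out of the FDR estimation instead of letting
±Inf propagate.

**iEVORA.** BT decides significance (q < 0.05 on Storey q-values);
the significant set is then re-ranked by ascending t-test P-value.
The re-ranking t is Welch by default because differentially variable
sites have unequal group variances by construction; a pooled variant is
available. Ranking by t P-value rather than |t| makes the order
invariant to the per-feature degrees of freedom. The selected set is
identical to BT's at the same threshold — the two differ only in
ranking — and the code asserts this by construction (one Bartlett pass
feeds both).

**DiffVar-type Levene test.** Per feature, absolute deviations of each
sample's M-value from its group mean; the two groups' deviations are
compared by a moderated two-sample t. The per-feature deviation
variances are squeezed towards an empirical-Bayes prior fitted across
all features by method of moments (`fit_variance_prior`): solve
trigamma(d₀/2) = var(e) − trigamma(df/2) for the prior degrees of
freedom d₀, where e_j is the bias-corrected log sample variance, with
d₀ = ∞ when the observed dispersion does not exceed chi-square sampling
noise. Absolute (not squared) deviations are the default: they are less
outlier-sensitive and are the convention of the moderated-Levene
framework this test follows. Group-mean deviations use the plain group
mean without a leave-one-out correction; at the benchmark's group size
(n = 50) the resulting within-group dependence is O(1/n) and the null
calibration test confirms uniform P-values.

**Joint mean/variance score test.** On M-values, the heteroscedastic
regression y = μ + βx + ε, Var(ε) = σ²·exp(γx), x ∈ {0,1}, tested at
H₀: β = γ = 0 with a 2-df score statistic T = T_mean + T_var, where
T_mean = (n₀n₁/N)(ȳ₁−ȳ₀)²/σ̂² and T_var = (n₀n₁/N)(d̄₁−d̄₀)²/v with
d_i = (y_i − ȳ)² the squared residuals. The choice of v is the test's
one genuinely open design point:

* `information = "expected"` uses the Gaussian value v = 2σ̂⁴. This is
  the textbook expected-information score test, but it inherits the
  Gaussian fourth-moment assumption — exactly the assumption whose
  failure inflates Bartlett's test — and in our benchmark it detects
  outlier-driven DV nearly as well as Bartlett does.
* `information = "robust"` (default) uses the empirical variance of d
  (a Koenker-type studentization). This keeps the score test calibrated
  under non-Gaussian data, which is how joint score tests in this
  literature are built and why they are reported to have tight type-1
  error control — and it is precisely what makes them insensitive to
  type-2 (few-outlier) DV: the outliers inflate the empirical variance
  of d as much as its group contrast.

We default to the robust form because it reproduces the documented
operating characteristics of this family of tests; the expected-
information form is retained for comparison. The two 1-df components
are summed without a cross term: under the symmetric null their
asymptotic covariance (a third-moment term) vanishes, and the additive
form guarantees the joint statistic dominates each component.

**Location-scale LRT scheme.** On M-values, three nested Gaussian fits
with closed-form MLEs: common mean/common variance; group means/common
variance; group means/group variances. Two 1-df LRTs follow: a mean
test (model 2 vs 1) and a DV test (model 3 vs 2). Each P-value vector
gets its own q-values; a feature is significant if *either* q < 0.05,
and selected features are ranked by the DV P-value. There is
deliberately no variance-only-versus-null comparison: the scheme asks
whether variance adds signal over the mean. We use closed-form Gaussian
location-scale fits rather than iterative additive smoothers because
with a single binary covariate the additive model degenerates to
exactly this closed form.

**Moderated-t baseline.** The standard differential-mean test (same
empirical-Bayes machinery, applied to beta values), included to make
the DV-versus-DM contrast measurable.

## Multiple testing

Storey q-values: π̂₀(λ) = #{p > λ}/(n(1−λ)) on λ = 0.05, …, 0.95,
smoothed by a cubic polynomial in λ and evaluated at λ = 0.95, clamped
to [1/n, 1]. The cubic polynomial stands in for the original spline
smoother; at these feature counts the difference is second order. The
1/n floor prevents a degenerate π̂₀ → 0 collapse on dense-signal
inputs. With fewer than 100 P-values the estimator returns π₀ = 1,
reducing q-values to Benjamini–Hochberg. Features with missing P-values
are excluded from n and receive missing q-values.

## The simulator

`simulate_dataset` draws the two-phenotype beta-mixture design the
benchmark runs on: 6000 CpGs × 100 samples (50 per phenotype), null
CpGs iid Beta(10, 90) — mean 0.1, sd ≈ 0.03, a typical unmethylated
CpG — and 600 true DVCs (200 per type) whose altered disease samples
come from Beta(6, 4) — mean 0.6, sd ≈ 0.15, an average methylation gain
of ≈ 0.5. Type-1a alters all 50 disease samples (mean-dominated DV),
type-1b alters 20 (substantial-subset DV), type-2 alters 3 (pure
outlier DV, no significant mean difference). Only hypermethylation is
generated by default; β → 1−β symmetry makes this lossless, and a
`direction = "hypo"` flag mirrors the whole design for testing
direction handling. Altered-sample subsets are redrawn independently
per feature — the neutral choice where nothing forces outlier samples
to coincide across CpGs. Truth labels sit at fixed feature indices,
which is statistically inert (all tests are feature-exchangeable; a
permutation test in the suite confirms it) and lets two simulations
with matching counts share their ground truth, the basis of the
two-stage discovery/validation PPV design. A type-3 pattern
(discoordinated bidirectional outliers) exists in the taxonomy but is
not generated by default, since no benchmarked test targets it.

What the generator does *not* emulate: probe-type chemistry differences
and array noise, batch effects, cell-type composition, spatial CpG
correlation, and genuinely heavy-tailed biological nulls. Passing the
benchmark therefore demonstrates correct operating characteristics
under an idealized beta-mixture world — in particular, realized FDRs of
Bartlett-type tests on real arrays will be worse than simulated,
because real nulls deviate from beta-distributed sampling more than
simulated ones do.

## Taxonomy of significant DVCs

Among Bartlett-significant sites (q < 0.05), a site is **type-2** if
its t-test P-value is not significant (t_p > 0.05), **type-1a** if the
t-test P-value is significant and strictly smaller than the Bartlett
P-value (mean-dominated), and **type-1b** otherwise. Boundary
conventions: t_p exactly 0.05 counts as significant (the type-2 rule
reads "not significant", a strict inequality), and t_p exactly equal to
bt_p falls to type-1b ("more significant" read strictly). The four
labels exhaust the input space.

## Evaluation frameworks

**Monte-Carlo benchmark.** `run_benchmark` repeats the simulation with
consecutive seeds and records five measures per algorithm and run:
overall sensitivity at estimated FDR < 0.05, the realized ("true") FDR
at that threshold, and the three per-type sensitivities. FDR rather
than FPR is reported because FDR = 1 − PPV is what tells a user whether
a call is trustworthy. An empty call set contributes a true FDR of 0 —
the convention that keeps runs averageable (an NaN would poison the
Monte-Carlo mean). The acceptance checks run 25 Monte-Carlo runs at the
default 6000 × 100 configuration, a size at which the across-run
standard deviations of all five measures are well below the effect
sizes being asserted; the package-level checks complete in tens of
seconds on one CPU.

**Progression PPV.** `progression_ppv` takes the top-k ranked discovery
features (optionally one direction only; direction is the sign of the
discovery mean difference), computes Welch t-statistics in an
independent validation dataset representing a more advanced disease
stage, and reports the fraction exceeding ±1.96 with preserved
direction. The 1.96 threshold is deliberately uncorrected for multiple
testing: in a validation context the false *negative* rate is the
greater danger, and the same criterion is applied to every algorithm
being compared. Features absent from the validation matrix are excluded
from numerator and denominator.

## Numerical and degenerate-input conventions

* All ranking rules are deterministic; ties break by input feature
  order.
* Bartlett and LRT statistics are floored at 0 (they are likelihood
  gains; tiny negative values can only arise from floating-point
  cancellation).
* Zero within-group variance: missing result for variance tests; for
  the t-test, two constant equal groups give t = 0, p = 1, and constant
  unequal groups give a missing (flagged) result.
* Score-test denominators of exactly 0 with a zero numerator give a 0
  component; with a nonzero numerator, a missing result.
* Prior fitting failures fall back to d₀ = ∞ (all posterior variances
  equal s₀²) with a warning; forcing d₀ = 0 recovers the ordinary
  unmoderated t, which the test suite uses as a limit-case check.

## Known limitations

Two-group designs only — no covariates, continuous phenotypes,
multi-group comparisons, or batch/surrogate-variable correction. The
joint score test and location-scale LRT are this package's concrete
instantiations of their test families; published implementations differ
in detail (e.g. additive variance links, iterative GAMLSS fitting), so
numerical agreement with them is not claimed, only the family's
operating characteristics. The q-value smoother is polynomial rather
than spline, which can shift borderline calls at FDR ≈ 0.05
marginally. Bartlett-based significance inherits type-1 inflation on
heavy-tailed data; that is not a defect to be fixed but the documented
cost of sensitivity to outlier-driven DV, and the benchmark quantifies
it.
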