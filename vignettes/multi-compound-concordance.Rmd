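---
title: "Methods: multi-compound transcriptomic concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-compound transcriptomic concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txconcord)
```

# The question and the model

When several structurally related compounds — here bisphenol A, F and S in
stem-cell-derived hepatocyte-like cells — are profiled on the same
expression platform against a common control, two complementary questions
arise: *which* genes respond to each compound, and *how similar* the
responses are to one another. `txconcord` answers the first with standard
thresholded differential-expression calling and the second with two
statistics on different scales: the overlap ratio of the deregulated gene
sets (a set-level enrichment against an independence null) and the
genome-wide Spearman correlation of log2 fold-change profiles (a
probe-level concordance that uses every gene, significant or not).

## Differential expression

For each probe the log2 fold change is the difference of treated and
control group means on the log2 intensity scale. Significance comes from a
pooled-variance two-sample t statistic with $n_t + n_c - 2$ degrees of
freedom and Benjamini–Hochberg FDR adjustment across probes; a probe is
called up when its linear fold change strictly exceeds 1.5 with adjusted
p strictly below 0.05, down in the mirrored case, and not-significant
otherwise. The classical pooled t is used deliberately: the package's
contribution — the overlap and concordance statistics — is agnostic to the
upstream test, and the test function is a separate, pluggable stage, so a
variance-moderated alternative can be substituted without touching anything
downstream. Probes, not collapsed gene symbols, are the analysis unit, and
both thresholds are strict inequalities. Degenerate probes follow a fixed
convention: zero pooled variance with zero mean difference gives p = 1, with
a nonzero difference p = 0.

## The overlap ratio

Let $N$ be the number of probes on the array, $n_1, \dots, n_k$ the sizes of
the deregulated sets under $k$ conditions, and $O$ the size of their
intersection. If the sets were drawn uniformly and independently from the
universe, the expected intersection would be

$$E_2 = \frac{n_1 n_2}{N}, \qquad E_3 = \frac{n_1 n_2 n_3}{N^2},$$

and the overlap ratio is $O/E$ — algebraically $O N/(n_1 n_2)$ pairwise and
$O N^2/(n_1 n_2 n_3)$ three-way. A value of 1.0 means the overlap is exactly
what chance predicts; values far above 1 mean concordant deregulation. The
identity $\text{ratio} \times E = O$ holds exactly and is enforced by a
property test, as is symmetry in the set arguments. $O = 0$ gives a defined
ratio of 0, while an empty set makes the ratio undefined; the low-level
constructors raise an error for that case and the report-level
`overlap_table()` instead flags the row as undefined so whole-study reports
degrade gracefully (a null study with zero calls is a legitimate outcome,
not a crash).

Two choices here were genuinely open. First, the universe: $N$ is taken
from the supplied matrix — all probe identifiers — because deregulated sets
are reported at the probe level; an "expressed-only" universe (mean log2
intensity above a cutoff) is available as a configuration option since the
right choice depends on how the platform was filtered upstream. Second, the
Monte-Carlo machinery: each null replicate draws each set uniformly
*without* replacement within the set and independently *between* sets,
which is the literal independence model behind $E$. Its empirical mean is
checked against $E$ (within three standard errors) and against an exact
hypergeometric/enumeration oracle for small universes. The one-sided
exceedance probability $(\#\{O_{rep} \ge O_{obs}\}+1)/(\text{reps}+1)$ is
an extension beyond the analytic statistic — the ratio itself carries no
p-value — and is labelled as such in output.

## Concordance of fold-change profiles

The Spearman coefficient is computed as the Pearson correlation of
average-ranked values, with a two-sided p from the t approximation at
$n - 2$ degrees of freedom and the conventional `< 2.2e-16` display floor.
Correlations are computed over *all* probes on the common universe, not
only the significant ones: fold-change concordance is a genome-wide
property, and restricting to called probes would condition on the
thresholds. This default is a documented assumption and any probe subset
can be supplied. One consequence worth knowing: when all compounds are
contrasted against the *same* control samples, control-group noise is
shared between profiles and contributes positive correlation on top of any
true effect correlation. That coupling is a property of the design (and is
present in any study that reuses one control), not an artifact of the
implementation.

## IC50 from the linear segment

Concentration-response readouts are first normalized to the vehicle-control
mean (percent mode; fold mode for induction-style readouts such as caspase
activity). The IC50 is solved from the straight line $f(x) = ax + b$
through the first consecutive concentration pair whose mean responses
bracket 50% of control. This interpolation reading of the linear model is
the default because it reproduces two desiderata naturally: the estimate
always lies inside its bracketing interval, and it equals a tested
concentration exactly when that concentration's mean response is exactly
50. Replicates at a concentration are averaged before crossing detection;
responses above 100% are permitted and only the downward crossing is
sought, with a first-crossing rule resolving non-monotone curves. When the
mean response never falls to 50% in the tested range the result is an
explicit `not_reached` status rather than an extrapolated number. A
whole-curve least-squares line (`mode = "global"`) is provided as the
alternative reading for users who prefer a single fitted line; it refuses
to extrapolate outside the tested range.

## PCA

Sample-level PCA runs on the 1000 highest-variance probes (deterministic
tie-break by probe order), mean-centered without unit-variance scaling —
the standard treatment for log2 expression data, where scaling would
up-weight near-constant probes. Percent variance per component is
$100\,\sigma_i^2/\sum_j \sigma_j^2$.

# The synthetic-data generator

The generator emulates the study design so every stage can be validated
against known truth: a ~20,000-probe array, one control plus three compound
groups, four replicates each. Each probe draws a baseline log2 intensity
(default mean 7, sd 2, a typical normalized microarray scale); a core of
`shared_de_count` probes is perturbed by *every* compound, each compound
additionally perturbs `private_de_count` probes of its own, and the rest
are null. Measurement noise is i.i.d. Gaussian on the log2 scale, the
standard post-normalization approximation.

Shared-probe effects are jointly Gaussian across compounds with a
single-factor exchangeable correlation (`effect_correlation` is the one
tunable concordance parameter), and each shared probe draws one fair-coin
sign applied to all compounds, so the shared core moves concordantly up or
down. These two choices interact: with a nonzero `effect_mean` $\mu$ and
effect sd $\sigma$, the sign mixture makes the unconditional correlation of
two compounds' effects $(\mu^2 + \rho\sigma^2)/(\mu^2 + \sigma^2)$, which
exceeds the nominal $\rho$. The correlation parameter is therefore
interpreted — and tested — at $\mu = 0$, where it is exact; with strong
asymmetric effects the generator intentionally produces *more* concordance
than $\rho$, which is the right qualitative behaviour for a concordantly
deregulated core.

What the generator does not emulate: probe-level raw intensities and
normalization artifacts, batch or spatial effects, heavy-tailed or
intensity-dependent noise, and correlated nulls. Passing tests therefore
demonstrate that the statistics recover the structure they define under a
clean Gaussian design — they do not certify behaviour under normalization
failure or confounded designs.

Dose-response curves use a monotone logistic mean
$\text{floor} + (100-\text{floor})/(1 + (c/\mathrm{IC}_{50})^h)$ expressed
as percent of the zero-concentration value, on a 6-point 0–500 µM grid with
5 replicate wells per point (Hill slope 1 and floor 0 by default, so the
mean crosses 50% exactly at the nominal IC50). A compound configured
without an IC50 declines linearly to 60% at the top concentration, staying
above the 50% line everywhere — the "not reached" phenotype.

# Study conditions used by the tests and the acceptance script

These problem sizes are the package's validation conditions, chosen once
from the design they emulate:

* **Shared-core recovery**: 100 shared probes, no private probes, effect
  mean 1.5 log2 units with sd 0.25, noise 0.1, n = 4, N = 20,000. The sd
  is small relative to the mean so that essentially every planted effect
  clears the 1.5-fold threshold; the three-way overlap of the called
  deregulated sets then recovers ≥95 of the 100 shared probes and yields
  ratios in the tens of thousands.
* **Genome-wide concordance**: every probe carries a correlated,
  zero-mean effect (sd 0.5) at `effect_correlation` 0.5, noise 0.25,
  n = 4. A rank-correlation calculation for bivariate Gaussians
  ($\rho_s = \frac{6}{\pi}\arcsin(r/2)$, with $r$ attenuated by
  fold-change noise and augmented by the shared control group) predicts a
  pairwise Spearman near 0.45–0.48, and the measured mean over 10 seeds
  falls in the 0.4–0.6 band — the qualitative regime reported for
  real bisphenol-response profiles.
* **DE operating characteristics**: 100 shared + 50 private probes among
  4,000, effect mean 1.5, noise 0.15, n = 4, averaged over 10 seeds. With
  only ~200 true signals among 4,000 probes, the BH gate at 5% FDR
  requires raw p below roughly $0.05 \cdot 200/4000 = 0.0025$; a power
  calculation at 6 degrees of freedom shows boundary-strength effects
  (mean 1.0, noise 0.25) cannot reach 90% sensitivity under that gate,
  while the chosen interior point can. Measured sensitivity is ≈0.99 with
  empirical FDR ≈0.
* **Permutation calibration**: with 4v4 groups the exact permutation
  distribution has only 35 distinct splits, so per-probe permutation
  p-values are quantized and condition on the observed data; calibration
  of the pooled-t p is asserted on the mean absolute discrepancy
  (measured ≈0.034) and rank agreement (≈0.99) rather than a
  max-over-probes bound, which Gaussian nulls violate routinely.
* **Monte-Carlo budgets**: 4,000–20,000 replicates per configuration,
  sized so three-standard-error bands are decisive at well under a minute
  of runtime.

Numerical conventions collected in one place: strict threshold
inequalities; BH ties broken by input order (ties cannot change the
cumulative-minimum result); probe-order tie-break in top-variance
selection; first-crossing rule for non-monotone dose-response curves;
p-value display floor `< 2.2e-16`; every generator and Monte-Carlo
function takes an explicit seed and restores the caller's RNG state, and
identical (config, seed) pairs produce byte-identical serialized output.

# Interpreting reported worked examples

Published three-way overlap reports of the form "O observed against E
expected" can be reproduced with `ratio_from_observed_expected()`. Because
printed expected counts are rounded, recomputed ratios differ from printed
ratios at the 0.01–1% level (e.g. 12/0.02218 = 541.03 against a printed
540.9); one published Man12 example (12 observed, 0.00410 expected, printed
ratio 5355.6) is internally inconsistent as printed — the division gives
≈2927 — and the package documents rather than reproduces it. Headline
dataset-level results (compound-specific IC50s, DE counts, observed
Spearman coefficients) depend on unpublished per-well data and frozen
normalization parameters and are validated here only in the
property-based, synthetic-design sense described above.

# Presentation and limitations

The repository is organized as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the exported functions,
and `run_pipeline()` is the one-call orchestration with a checksummed
manifest; there is no separate shell CLI. Known limitations: no
variance moderation in the default test (by design, see above); the
overlap null assumes exchangeable, independent sets and a fixed universe;
the linear-segment IC50 ignores curvature between grid points (bounded by
half the local grid spacing on logistic truth); and the generator's
Gaussian assumptions understate the tails of real array data.
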