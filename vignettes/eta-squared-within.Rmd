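---
title: "Eta squared within: standardized effect sizes for pairwise designs and mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eta squared within: standardized effect sizes for pairwise designs and mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eta2w)
```

## The problem

Behavioral experiments overwhelmingly use pairwise comparisons: two groups
of participants, two related conditions, or a 2 x 2 repeated-measures
design, often with both participants and stimuli sampled from larger
populations. Reporting a standardized effect size alongside the test
statistic is standard practice, but in repeated-measures and mixed-model
settings the popular measures disagree about what "variance explained"
means:

* **eta squared** ($\eta^2$ = SS~effect~ / SS~total~) measures an effect
  against *all* variance, including stable level differences between
  participants -- exactly the variance a repeated-measures design was
  chosen to set aside. It is the analogue of Cohen's $d$ (or $d_{av}$ for
  paired data).
* **partial eta squared** ($\eta^2_p$ = SS~effect~ / (SS~effect~ +
  SS~error(effect)~)) uses a different denominator for every effect. It is
  a monotone transform of the $F$ (or $t$) statistic: informative about
  significance, not about the share of variance an effect explains. In
  multifactorial repeated-measures designs the $\eta^2_p$ values of the
  effects routinely sum to more than 1, and in mixed models the value
  additionally depends on the estimated degrees of freedom, so the same
  effect can change $\eta^2_p$ drastically when a random slope is added or
  dropped. Only in the special case of one within factor with a single
  observation per cell does $\eta^2_p$ carry the same information as
  $d_z$.
* **eta squared within** ($\eta^2_w$) -- the measure this package is built
  around -- is an effect's share of the *within-unit* variance: the
  variance that remains after stable differences between participants (or
  stimuli) are removed. It answers the question a repeated-measures design
  actually asks, sums to at most 1 across effects, and is comparable
  across studies with different numbers of observations per condition.

## Definitions and computation

### In repeated-measures ANOVA

For a balanced fully-within design, `anova_rm()` decomposes the total sum
of squares about the grand mean into a between-subjects stratum and a
within-subjects stratum in which every effect has its own
effect-by-subject error stratum. Then

$$\eta^2_w(\text{effect}) =
  \frac{SS_{\text{effect}}}{\sum_{\text{within stratum}} SS}$$

where the denominator is the sum of *every* within-stratum row -- all
effects plus all their error strata. Equivalently (and this is how the
mixed-model route works), $\eta^2_w$ is the ordinary total $\eta^2$ of the
same analysis run on **unit-centered** data: subtract from every
observation the plain mean of its unit's observations
(`center_by_unit()`). Centering annihilates the between-subjects sum of
squares and leaves every within-stratum statistic (SS, df, MS, F, p)
unchanged -- a property the test suite verifies exactly.

### In linear mixed models

Mixed models are fit by REML through `lme4`/`lmerTest`
(`fit_lmm()`). On top of the fit the package computes the
Nakagawa--Schielzeth variance decomposition with Johnson's extension for
random slopes: with $\hat\sigma^2_f$ the sample variance of the
fixed-effects fitted contribution $X\hat\beta$ over the observed rows,
$\hat\sigma^2_l = \frac1n\sum_i z_i^\top \hat\Sigma_l z_i$ the variance
contributed by grouping factor $l$ (its full estimated covariance
$\hat\Sigma_l$, so intercept-slope correlations are included), and
$\hat\sigma^2_\varepsilon$ the residual variance:

$$R^2_{\text{marginal}} =
  \frac{\hat\sigma^2_f}
       {\hat\sigma^2_f + \sum_l \hat\sigma^2_l + \hat\sigma^2_\varepsilon}$$

The per-effect (semi-partial) $\eta^2$ of term $j$ replaces the numerator
by the variance of that term's own contribution $X_j\hat\beta_j$, and its
denominator counts that term's fixed variance plus the random and residual
variance:

$$\eta^2_j = \frac{v_j}{v_j + \sum_l \hat\sigma^2_l +
  \hat\sigma^2_\varepsilon}, \qquad v_j = \widehat{\mathrm{Var}}(X_j\hat\beta_j).$$

Each effect is thus measured against the variance not already claimed by
the other fixed effects; with a single fixed term this equals the marginal
$R^2$. In balanced designs the coded columns are orthogonal, so the
distinction only matters for the denominators. Both quantities are
invariant to the contrast coding, because fitted contributions are.

$\eta^2_w$ from a mixed model (`eta2w_lmm()`) is the same semi-partial
computation run on the unit-centered response. The model is refit
unchanged -- the random intercept of the centered unit is retained, because
the measure depends only on the total variance, not on how the fit
allocates it over components (the suite checks that dropping the intercept
moves the values by less than 0.02 on these data). An effect that is
constant within every centering unit (a between-participants factor under
participant centering, say) has no within-unit variance to explain; it is
returned as `NA` with a flag rather than a number.

When a design has two random factors, an effect can be "within" one and
"between" the other -- the face-rating example has age between participants
but within stimuli. Both centerings are therefore exposed via
`center_unit`, and the natural choice is the random factor for which the
effect is a repeated measure (stimuli, in that example). This is also why
no $d$-type measure is offered for mixed models: a single effect would
need a different $d$ per random factor.

### The d family and conversions

For two independent groups, `cohens_d_independent()` uses the average-SD
denominator $\sqrt{(SD_1^2 + SD_2^2)/2}$; for paired data `d_paired()`
returns both $d_z = M_{diff}/SD_{diff}$ and $d_{av}$. Confidence intervals
invert the noncentral-$t$ pivot of the associated statistic (root-finding
tolerance 1e-8), which reproduces published intervals to the two decimals
they are printed at; no small-sample (Hedges) correction is applied.
`convert_eta_d()` implements the approximate closed forms
$d_{av} \approx 2\sqrt{\eta^2/(1-\eta^2)}$ and
$d_z \approx \sqrt{\eta^2_p/(1-\eta^2_p)}$ and their exact inverses
(round-trip accurate to 1e-12). The factor 2 reflects that two independent
distributions are compared in the between-groups case.

## Contrast coding

All factors in scope have exactly two levels. Three codings are available
(`coding_scheme()`): dummy (0/1), sum (-1/+1) and deviation (-0.5/+0.5).
**Deviation is the default**: in a balanced 2 x 2 it makes every
main-effect coefficient the marginal mean difference and the interaction
coefficient the difference of simple effects, so estimates read directly
in response units. Dummy coding is kept because it is the default of
`lme4` and of R generally -- and because the package deliberately
reproduces its pitfall: with an interaction present, dummy-coded "main
effects" are simple effects at the other factor's reference level and can
look significant when the marginal effects are null. Level order is
lexicographic, so the sign convention is always "second-sorted level minus
first"; the reported cell means make the direction unambiguous.

## Degrees of freedom and p-values

Fixed-effect t statistics get Satterthwaite denominator degrees of freedom
(via `lmerTest`); in balanced single-random-factor designs these reduce to
the classical values (18 for the two-group example, 9 for the paired one),
which the suite asserts. All p-values are two-sided. ANOVA p-values come
from the F distribution with the term's own error stratum; no sphericity
correction is applied because two-level factors satisfy sphericity
trivially.

Partial eta squared from a mixed model is computed only on request
(`effect_report(..., eta2p = TRUE)`) as $t^2/(t^2 + df)$ and always warns:
its df-dependence makes it unstable across random-effect structures.

## Replicate averaging is never silent

Averaging replicates before an ANOVA changes $\eta^2$ (averaging removes
within-condition variance, so effect sizes inflate as more observations
are averaged). `anova_rm()` and `anova_between()` therefore refuse
replicated data unless `collapse_replicates = TRUE` is passed explicitly;
the mixed-model path analyzes the raw rows and needs no averaging. For the
same reason the mixed-model effect sizes are the more comparable ones
across studies.

## The synthetic-data generator

`simulate_crossed()` draws from exactly the generative model the mixed
machinery assumes: deviation-coded fixed effects, independent Gaussian
random intercepts/slopes per participant (and optionally per stimulus),
Gaussian residuals, optional completely-at-random missingness, and a
mandatory seed (same spec, bit-identical data).
`expected_effect_sizes()` gives the closed forms: a deviation-coded main
effect with coefficient $\beta$ contributes variance $\beta^2/4$
($\beta^2/16$ for a two-way interaction), a random term $\sigma^2 E[z^2]$,
and participant centering removes the participant intercept variance and
any purely between-participant fixed variance from the $\eta^2_w$
denominator.

What the generator emulates: balanced crossed designs, boundary
(zero-variance) components, missing data. What it does not: correlated
random effects (generation uses independent components, although
estimation fits the full covariance), non-Gaussian or heteroscedastic
noise, unbalanced designs by construction, more than two levels per
factor. Passing recovery tests therefore demonstrate correctness of the
estimators under the model's own assumptions, not robustness to their
violation.

Parameter-recovery checks in the suite use 200 participants x 4
observations for the between-groups design and 500 participants x 8
stimuli for the crossed design -- sizes at which REML components land
within 10% of truth and empirical $\eta^2$/$\eta^2_w$ within 0.02 of the
closed forms, while the whole suite still runs in well under a minute.

## Numerical choices

* REML throughout (matching the reference outputs the package reproduces);
  variance parameters bounded at zero; up to two restarts from perturbed
  starting values before a convergence complaint is surfaced. Singular
  fits are returned with `singular = TRUE`, never hidden -- boundary
  estimates are informative (the 2 x 2 example itself has a near-zero
  stimulus-type slope variance).
* Agreement with published mixed-model output is asserted to the 3--4
  significant figures such output is printed at, not bit-exactly: the
  optimizer behind a printed table is rarely known, and singular fits in
  particular admit slightly different stationary points.
* The fixed-contribution variances in the R^2 measures use the sample
  (n - 1) variance over the observed rows, matching the reference
  implementation of the Nakagawa--Schielzeth method.
* The noncentral-t interval uses `uniroot` on `pt(t, df, ncp)` with
  tolerance 1e-8 over an interval widened by 4|t| + 10.
* Centering uses the plain mean of all of a unit's observations, including
  unbalanced units, matching the worked centering table the package
  reproduces.
* Degenerate inputs: identical samples give t = 0, p = 1; zero-variance
  denominators for d-type measures are errors, not NaNs; empty cells in
  RM-ANOVA raise an error that points to the mixed-model path.
* The ICC printed with the variance components is the grouping factor's
  intercept variance over the total random-plus-residual variance; this is
  one common reading of an ICC in the presence of random slopes and is
  documented as an interpretation, not a canonical definition.

## Worked example

```{r twobytwo}
tb <- load_fixture("twobytwo")
tab <- anova_rm(tb, c("day", "stimtype"), collapse_replicates = TRUE)
tab
eta_squared(tab, "within")
```

```{r lmm}
rep <- effect_report(
  tb, fixed = c("day", "stimtype", "day:stimtype"),
  random = random_spec("participant",
                       slopes = c("day", "stimtype", "day:stimtype")),
  center_unit = "participant")
rep
```

The ANOVA route (on day/stimulus-type cell means) and the mixed-model
route (on the raw 80 observations) agree on the structure -- a crossed
interaction, no main effects -- while the mixed-model $\eta^2_w$ values are
smaller because the averaging step of the ANOVA removed genuine
within-condition variance. That contrast is the reason to prefer the
mixed-model effect sizes when more than one observation per condition is
available.

## Known limitations

Only two-level factors and at most 2 x 2 fixed designs are supported, with
at most two crossed random factors; no continuous covariates, nesting,
generalized (non-Gaussian) models, Helmert/polynomial contrasts, or
model-selection tooling. Unbalanced ANOVA is deliberately not implemented:
incomplete repeated-measures data are routed to the mixed-model path,
which handles randomly-missing observations natively.
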