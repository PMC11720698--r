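# eta2w

Standardized effect sizes for pairwise-comparison designs — t-tests,
repeated-measures ANOVA, and linear mixed-effects (LME) models with
crossed participant and stimulus random effects — built around **eta
squared within** (η²_w): an effect's share of the *within-unit* variance.

## Why

Researchers running repeated-measures or mixed-model analyses need a
variance-explained effect size that matches their design. The common
choices both miss:

- **η² = SS_effect / SS_total** counts stable between-participant level
  differences in its denominator — precisely the variance a
  repeated-measures design was chosen to set aside.
- **η²_p = SS_effect / (SS_effect + SS_error(effect))** uses a different
  denominator per effect; it is a transform of the test statistic, sums
  to more than 1 across effects in multifactorial designs, and in mixed
  models additionally depends on the estimated degrees of freedom.

**η²_w** measures each effect against the total within-unit variance:

    η²_w(effect) = SS_effect / Σ (all within-stratum SS)

in a repeated-measures ANOVA, or equivalently the (semi-partial) marginal
R² of a mixed model refit on **unit-centered** data (each observation
minus its unit's mean). Centering removes all between-unit variance while
leaving every within-stratum statistic unchanged, so η²_w is an honest
"share of the variance that matters" and is comparable across studies.

The package also provides the classical layer around the measure: Student
and Welch t-tests, Cohen's d / d_z / d_av with noncentral-t confidence
intervals, the d↔η conversion formulas, a from-scratch repeated-measures
sum-of-squares engine, dummy/sum/deviation contrast coding (deviation
±0.5 by default, so main effects stay marginal when interactions are
present), Satterthwaite degrees of freedom, Nakagawa–Schielzeth–Johnson
marginal and per-effect R² for REML fits (via lme4/lmerTest), five
embedded toy datasets, a synthetic-data generator with known variance
components, and a small CLI.

## Worked example

A 2 × 2 fully-within design (10 participants × Day × StimulusType, two
measurements per cell), analyzed as a mixed model with by-participant
random intercept and slopes:

```r
library(eta2w)
tb <- load_fixture("twobytwo")
effect_report(tb, fixed = c("day", "stimtype", "day:stimtype"),
              random = random_spec("participant",
                                   slopes = c("day", "stimtype",
                                              "day:stimtype")),
              center_unit = "participant")
```

```
Effect-size report (R2 marginal = 0.0725 )
eta2_w centered by: participant
         term estimate     SE     df      t         p     eta2   eta2_w
  (Intercept)    5.275 0.4927  8.996 10.705 2.030e-06       NA       NA
          day    0.400 0.3568  9.171  1.121 2.908e-01 0.010466 0.027896
     stimtype    0.150 0.2913 14.095  0.515 6.145e-01 0.001485 0.004019
 day:stimtype   -2.000 0.6871  8.999 -2.911 1.729e-02 0.062005 0.152078

Cell means and SDs:
  day stimtype  n mean    sd
 day1       s1 20 4.50 1.792
 day1       s2 20 5.65 1.755
 day2       s1 20 5.90 1.651
 day2       s2 20 5.05 2.395
```

Reading the output: under deviation coding the interaction estimate
−2.000 is the difference of simple effects in response units — the
crossed interaction visible in the cell means ((5.05 − 5.90) −
(5.65 − 4.50)). It is the only significant effect (t(9.0) = −2.91,
p = .017). The fixed effects jointly explain 7.25% of the total variance
(marginal R²); the interaction alone explains 6.2% of total variance
(η²) but 15.2% of the variance *within* participants (η²_w), the figure
that reflects what the repeated-measures design was built to detect.

The same quantities are available from the ANOVA route
(`anova_rm()` + `eta_squared(tab, "within")`), from the classical layer
(`t_paired()`, `d_paired()`, `convert_eta_d()`), and from the command
line:

```sh
inst/cli/eta2w anova --fixture twobytwo --within day stimtype \
    --collapse-replicates --effect-size within --out anova.csv
```

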