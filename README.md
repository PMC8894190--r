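# ebmc

Sufficient-component-cause modelling of aging-related disease incidence and
intrinsic mortality, built on the statistical theory of extreme values.

Aging-related diseases (ischemic heart disease, most cancers,
neurodegeneration) have complex etiologies: many *sufficient causes*, each a
minimal set of genetic and environmental *component causes* that expresses
at a random age. A sufficient cause completes at the **maximum** age of
expression of its components; the population sees disease (or intrinsic
death) at the **minimum** completion age across sufficient causes. For many
causes, extreme-value theory leaves only two limiting laws, and the split is
evolutionary: causes whose timing was molded by the declining force of
natural selection (late-onset genetic effects without recent environmental
factors) have initial cdfs *flat* at the earliest reproduction age and lead
to the **Gompertz** hazard `h(x) = λ·exp(θ(x−a))`; causes containing
evolutionarily recent environmental factors are *regularly varying* at the
terminus and lead to the **Weibull** hazard `h(x) = αγ(x−a)^(γ−1)`.
Population mortality then mixes the two survival curves:
`S(x) = p·S_G(x) + (1−p)·S_W(x)`.

The package is for biostatisticians and epidemiological modellers who want
these constructions executable: exact max/min survival algebra, seeded
simulation honouring shared components, numerical domain-of-attraction
diagnostics, censored maximum-likelihood fitting of the
Gompertz/Weibull/Makeham/mixture families, and healthy-aging scenario
projection (health promotion vs. postponed aging) with life-expectancy and
unhealthy-years summaries.

## Worked example

```r
library(ebmc)

# the 15 sufficient-cause types; 12 retained for the aging phase
types <- enumerate_cause_types()
dplyr::count(types, retained, molding)
#> # A tibble: 3 × 3
#>   retained molding        n
#>   <lgl>    <chr>      <int>
#> 1 FALSE    excluded       3
#> 2 TRUE     molded         4
#> 3 TRUE     not_molded     8

# which limit law does an initial timing distribution lead to?
classify_domain(dist_flat(b = 2, terminus = 10))$domain
#> [1] "gompertz_domain"
classify_domain(dist_weibull(0.5, 3))[c("domain", "rho")]
#> $domain
#> [1] "weibull_domain"
#> $rho
#> [1] 3

# simulate a censored cohort from a 70/30 Gompertz-Weibull mixture and refit
mp  <- mixture_params(0.7, dist_gompertz(0.01, 0.11, 10),
                      dist_weibull(4e-6, 3, 10))
coh <- generate_cohort(mp, 2e4, admin_censor_age = 75, seed = 11)
fit <- fit_mortality(coh, "mixture", terminus = 10, seed = 1)
tidy(fit)
#> # A tibble: 5 × 3
#>   term    estimate  std.error
#>   <chr>      <dbl>      <dbl>
#> 1 p     0.692      0.00725
#> 2 lam   0.00988    0.000225
#> 3 theta 0.111      0.00132
#> 4 alpha 0.00000505 0.00000273
#> 5 gamma 2.95       0.126
```

The mixture weight `p` is the fraction of the population dying through
evolutionarily molded (Gompertz) sufficient causes; `theta` is the rate of
aging; `gamma` is the Weibull shape picked up from the regular-variation
index of the recent-exposure causes. The generating values here were
`p = 0.7`, `theta = 0.11`, `gamma = 3`.

```r
# healthy-aging scenarios on the shipped default configuration
cs <- apply_scenario(default_scenario(intervention_health_promotion(0.5)))
cs$summaries
#> # A tibble: 2 × 7
#>   when     LE   HLE unhealthy_years rect_iqr rect_slope_at_median valid
#>   <chr> <dbl> <dbl>           <dbl>    <dbl>                <dbl> <lgl>
#> 1 pre    80.4  73.2            7.16     17.8               0.0304 TRUE
#> 2 post   81.4  74.9            6.57     16.8               0.0325 TRUE
autoplot(cs)
```

Halving the contribution of evolutionarily recent exposures lengthens life
(+1.1 y) while *shrinking* years lived with disease (−0.6 y) — compression
of morbidity. A pure postponed-aging shift lengthens life but leaves
unhealthy years unchanged; `intervention_combined()` composes the two.

A thin command-line wrapper over the same functions ships at
`inst/cli/ebmc.R` (subcommands `enumerate`, `simulate`, `classify-domain`,
`converge`, `fit`, `scenario`, `make-cohort`; YAML configs documented in
`inst/extdata/config-schema.md`).

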