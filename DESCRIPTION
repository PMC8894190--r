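Package: ebmc
Title: Evolution-Based Sufficient-Component-Cause Modelling of Aging-Related
    Disease and Intrinsic Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the evolution-based model of causation (EBMC) applied to
    aging-related diseases and intrinsic mortality. Represents causal systems of
    component causes (early-/late-onset genetic effects, evolutionarily
    conserved/recent environmental factors) with parametric time-to-event
    distributions; enumerates and classifies sufficient-cause types; builds
    exact maximum-over-components and minimum-over-sufficient-causes survival
    constructions and Monte-Carlo simulations honouring shared components;
    diagnoses lower-terminus behaviour (flatness, Karamata regular variation)
    to predict Gompertz or Weibull minimum domains of attraction; fits
    Gompertz, Weibull, Makeham and Gompertz-Weibull survival-mixture models to
    right-censored, left-truncated event data by multi-start maximum
    likelihood; and projects healthy-aging scenarios (health promotion,
    postponed aging) with life-expectancy, unhealthy-years and
    rectangularization summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    flexsurv,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
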