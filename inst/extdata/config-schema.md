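# Structured-config schema

All configs are YAML. One dialect is shared by causal systems, distribution
specs, mixtures and scenarios.

## Distribution spec

```yaml
family: gompertz | weibull | makeham | flat | regvar |
        lognormal_shifted | gamma_shifted | fixed | threshold
params: {...}   # per-family fields, below
```

Per-family `params` fields (ages in years):

| family            | fields                                              |
|-------------------|-----------------------------------------------------|
| gompertz          | `lam` (>0), `theta` (>=0), `terminus` (>=0)         |
| weibull           | `alpha` (>0), `gamma` (>0), `terminus`              |
| makeham           | `lam`, `theta`, `c` (>=0), `terminus`               |
| flat              | `b` (>0), `terminus`                                |
| regvar            | `c` (>0), `rho` (>0), `terminus`, `cap_age` (opt.)  |
| lognormal_shifted | `meanlog`, `sdlog` (>0), `terminus`                 |
| gamma_shifted     | `shape` (>0), `rate` (>0), `terminus`               |
| fixed             | `value`                                             |
| threshold         | `onset`, `rate`, `threshold` (each a nested spec), `n_grid` (opt.) |

## Causal system

```yaml
earliest_reproduction_age: 10
components:
  - id: loge_1
    category: LOGE        # EOGE | LOGE | ECEF | EREF
    distribution: {family: lognormal_shifted, params: {meanlog: 3.8, sdlog: 0.35, terminus: 10}}
sufficient_causes:
  - id: sc_1
    components: [loge_1]
```

Component ids must be unique; a component may appear in several sufficient
causes (sharing). LOGE timing laws must be unimodal with support at or above
`earliest_reproduction_age`.

## Mixture

```yaml
p: 0.8                                    # weight on the Gompertz component
gompertz: {lam: 4.0e-5, theta: 0.1, terminus: 10}
weibull:  {alpha: 7.2e-10, gamma: 5, terminus: 10}
```

## Scenario (command `scenario`)

```yaml
morbidity:  <mixture>
mortality:  <mixture>
intervention:
  type: none | health_promotion | postponed_aging | combined
  eref_reduction: 0.5         # health_promotion / combined; scalar or [morb, mort]
  theta_scale: 1.0            # postponed_aging / combined
  shift_years: 5              # postponed_aging / combined
horizon: 110
step: 0.1
```

## Other commands

* `simulate`: `system` (path to a causal-system YAML, or inline), `n`.
* `classify-domain`: `distribution` (a distribution spec).
* `converge`: `distribution`, `n_causes`, `n_reps`.
* `fit`: `data` (CSV with `time,event[,entry]`), `family`, `terminus`,
  `n_starts`.
* `make-cohort`: `source` (a mixture, or `{system: path}`), `n`,
  `admin_censor_age`, `censor_rate`, `extrinsic_hazard`.
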