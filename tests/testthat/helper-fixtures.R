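# Shared fixtures built in code: tiny causal systems and reference laws.

# two LOGE components, no sharing: analytic product formula is exact
two_cause_system <- function() {
  causal_system(
    list(component_cause("g1", "LOGE", dist_lognormal(3.5, 0.4, 10)),
         component_cause("g2", "LOGE", dist_lognormal(3.9, 0.3, 10))),
    list(sufficient_cause("s1", "g1"), sufficient_cause("s2", "g2")))
}

# one molded, one shared-component, one EREF threshold cause
shared_system <- function() {
  causal_system(
    list(component_cause("g1", "LOGE", dist_lognormal(3.5, 0.4, 10)),
         component_cause("e1", "EOGE", dist_gamma(2, 1, 0)),
         component_cause("r1", "EREF",
                         dist_threshold(dist_fixed(15), dist_gamma(4, 4),
                                        dist_lognormal(3.4, 0.5)))),
    list(sufficient_cause("s1", "g1"),
         sufficient_cause("s2", c("g1", "e1")),
         sufficient_cause("s3", "r1")))
}

# exponential law with rate r starting at age a (Gompertz theta = 0)
exp_dist <- function(r, a = 0) dist_gompertz(r, 0, a)

spec_mixture <- function() {
  mixture_params(0.7, dist_gompertz(0.01, 0.11, 10), dist_weibull(4e-6, 3, 10))
}
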