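# A small aging-phase causal system: one molded sufficient cause (LOGE only),
# one molded two-component cause sharing the LOGE, and one not-molded cause
# containing a threshold-exposure EREF.
earliest_reproduction_age: 10.0
components:
- id: loge_1
  category: LOGE
  distribution:
    family: lognormal_shifted
    params:
      meanlog: 3.8
      sdlog: 0.35
      terminus: 10.0
- id: eoge_1
  category: EOGE
  distribution:
    family: gamma_shifted
    params:
      shape: 2.0
      rate: 1.0
      terminus: 0.0
- id: eref_1
  category: EREF
  distribution:
    family: threshold
    params:
      onset:
        family: lognormal_shifted
        params:
          meanlog: 3.0
          sdlog: 0.3
          terminus: 0.0
      rate:
        family: gamma_shifted
        params:
          shape: 4.0
          rate: 4.0
          terminus: 0.0
      threshold:
        family: lognormal_shifted
        params:
          meanlog: 3.5
          sdlog: 0.5
          terminus: 0.0
sufficient_causes:
- id: sc_1
  components: [loge_1]
- id: sc_2
  components: [loge_1, eoge_1]
- id: sc_3
  components: [eref_1]
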