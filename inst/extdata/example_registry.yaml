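# Example user-supplied ALM prediction equations.
# Coefficients below are synthetic illustrations of the registry schema,
# not published values.
- name: synthetic-50khz
  intercept: -4.10
  terms:
    RI@50kHz: 0.27
    weight: 0.095
    sex: 1.10
  population: synthetic illustration, standing single-frequency device
  posture: standing
  citation: "synthetic example shipped with leanmass"
- name: synthetic-250khz
  intercept: -2.85
  terms:
    ZI@250kHz: 0.22
    Xc@50kHz: 0.04
    sex: 1.30
  population: synthetic illustration
  posture: supine
  citation: "synthetic example shipped with leanmass"
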