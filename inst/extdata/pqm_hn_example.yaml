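# Example plan-quality scoring template (illustrative limits, not a protocol).
# serial organs: near-maximum dose caps; parallel organs: mean-dose caps;
# targets: mean dose at least 98% of prescription.
id: hn-example
objectives:
  - {structure: SpinalCord, statistic: D0.03cc, direction: '<=', threshold: 45}
  - {structure: Brainstem, statistic: D0.03cc, direction: '<=', threshold: 54}
  - {structure: Parotid_L, statistic: Dmean, direction: '<=', threshold: 26}
  - {structure: Parotid_R, statistic: Dmean, direction: '<=', threshold: 26}
  - {structure: Larynx, statistic: Dmean, direction: '<=', threshold: 40, zero_threshold: 50}
  - {structure: CTV1, statistic: Dmean, direction: '>=', threshold: 64.7, points: 4, target: true}
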