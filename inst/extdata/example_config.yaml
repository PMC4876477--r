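# Example pipeline configuration: simulate the default preterm-lamb design
# and analyse the three cohorts the study reports (non-dependent,
# gravity-dependent, pooled), all methods.
input:
  design: default
cohorts:
  - name: NI_nondep
    groups: [NI]
    locations: [non-dependent]
  - name: NI_gravdep
    groups: [NI]
    locations: [gravity-dependent]
  - name: all_samples
methods: [delta_ct, genorm, normfinder, bestkeeper]
seed: 1
output_dir: refstab-output
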