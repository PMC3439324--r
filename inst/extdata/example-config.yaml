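# Example run configuration: PDED mode under a proportional threshold.
mode: pded
threshold_kind: proportional
threshold: 0.35
truncation_length: 5
lmer_length: 3
algorithm: ids
seed: 1
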