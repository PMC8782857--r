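# demo pipeline configuration: simulated cetacean-like gene-loss scenario
# (12-tip cetacean clade pseudogenized on its stem branch, 3 intact
# terrestrial outgroups)
gene: EPPK1
reference_species: human
simulate:
  seed: 1
  repeatUnitLengthAa: 20
  repeatCopies: 30
thresholds:
  truncation_fraction: 0.5
  shared_tolerance_nt: 9
  dotplot_window: 10
  dotplot_threshold: 23
  synteny_k: 2
calibrations:
  - tipA: hippo
    tipB: blue_whale
    ageMya: 54
  - tipA: blue_whale
    tipB: bottlenose_dolphin
    ageMya: 33
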