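# Demonstration pipeline configuration: five-sugar mixture, 25 mM each.
# Equivalent to hilicraman::default_config().
seed: 1
simulate:
  analytes: [Fru, Glu, Suc, Mal, Tre]
  concentrations_mM: [25, 25, 25, 25, 25]
  noise_sigma: 5
preprocess:
  crop: [30, 55]
  subtract_solvent: true
decompose:
  rank: 9
  targets: [Fru, Glu, Suc, Mal, Tre, ACN, H2O, baseline, ACN-shift]
quantify:
  windows: default
  standards:
    Fru: 200
    Glu: 160
    Suc: 100
    Mal: 100
    Tre: 100
  injected_mL: 1
  dilution:
    mass_g: 1
    volume_mL: 20
    injected_mL: 1
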