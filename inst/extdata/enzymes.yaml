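# Default lyase specificity definitions.  Fields: mode (endo|exo),
# cleaves (list of uronate classes), blocks_on_3S, min_substrate_dp.
HepI:
  mode: endo
  cleaves: [2S-uronate]
  blocks_on_3S: true
  min_substrate_dp: 3
HepII:
  mode: endo
  cleaves: [2S-uronate, unsulfated-uronate]
  blocks_on_3S: true
  min_substrate_dp: 3
HepIII:
  mode: endo
  cleaves: [unsulfated-uronate]
  blocks_on_3S: true
  min_substrate_dp: 3
exoHep:
  mode: exo
  cleaves: [2S-uronate, unsulfated-uronate]
  blocks_on_3S: true
  min_substrate_dp: 4
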