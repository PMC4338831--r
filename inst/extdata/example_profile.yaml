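# Example toxicity profile for the `xenodyn cytotox` and `xenodyn fitness`
# subcommands: a drug whose unmodified form is the dominant toxic species.
criticals:
  X_c: 0.5 nM
  Xp_c: 1 uM
  Xpp_c: 100 uM
capacity: 1
h: 1
kd: 2e-6
kr: 2e-6
wd: 1
wr: 1
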