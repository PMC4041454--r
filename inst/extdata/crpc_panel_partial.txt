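# crpc_panel_partial: the 9 published members of the 16-gene core CRPC
# panel reported as directly regulated (binding < 25 kb + concordant DE);
# the remaining 7 panel members were not printed, so this fixture is
# deliberately PARTIAL and the full panel must be supplied by the user.
SLC26A2
SEC61A1
TRMT12
TNFSF10
PECI
MAD1L1
STIL
TSPAN13
AGR2
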