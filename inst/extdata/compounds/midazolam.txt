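# Midazolam (sensitive CYP3A4 probe substrate) record, assembled from
# published summaries (Thummel 1996, Gertz 2010 Fg/Fh decomposition).
# CYP3A4 recombinant kinetics sized so hepatic fm,CYP3A4 ~ 0.96 and
# Fg ~ 0.6 against the healthy-volunteer physiology fixture.
name midazolam
mw 325.8 g/mol
logp 3.13 -
compound_type monoprotic_base
pka1 6.0 -
bp_ratio 0.66 -
fu_plasma 0.032 fraction
fa 1 fraction
ka 3 1/h
fu_gut 1 fraction
q_gut 14.6 L/h
vss_target 1.0 L/kg
kp_scalar 1 -
cyp3a4.vmax 5.73 pmol/min/pmol
cyp3a4.km 2.5 uM
cyp3a4.fu_mic 1 fraction
cl_additional 52 L/h
cl_renal 0 L/h
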