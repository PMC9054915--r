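# Diltiazem (moderate CYP3A4 inhibitor, mechanism-based) record from
# published summaries (high-extraction, CL ~ 48 L/h, fu 0.22, Vss 5 L/kg).
# Inactivation parameters are effective (parent + N-desmethyl) values tuned
# within the moderate-inhibitor qualification envelope, sized below
# erythromycin's net effect.
name diltiazem
mw 414.5 g/mol
logp 2.8 -
compound_type monoprotic_base
pka1 7.7 -
bp_ratio 1.0 -
fu_plasma 0.22 fraction
fa 0.9 fraction
ka 0.8 1/h
fu_gut 1 fraction
q_gut 16 L/h
vss_target 5.0 L/kg
kp_scalar 1 -
cl_additional 387 L/h
cl_renal 3 L/h
interaction.kapp 2.77 uM
interaction.kinact 1.5 1/h
interaction.fu_mic 1 fraction
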