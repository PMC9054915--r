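# Erythromycin (moderate CYP3A4 inhibitor, mechanism-based) record from
# published summaries (CL ~ 30 L/h, fu 0.16, Vss 0.7 L/kg). Inactivation
# parameters are effective values tuned within the moderate-inhibitor
# qualification envelope (midazolam AUC ratio 2-5).
name erythromycin
mw 733.9 g/mol
logp 3.06 -
compound_type monoprotic_base
pka1 8.9 -
bp_ratio 0.9 -
fu_plasma 0.16 fraction
fa 0.6 fraction
ka 0.6 1/h
fu_gut 1 fraction
q_gut 12 L/h
vss_target 0.7 L/kg
kp_scalar 1 -
cl_additional 220 L/h
cl_renal 7 L/h
interaction.kapp 15 uM
interaction.kinact 2.5 1/h
interaction.fu_mic 1 fraction
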