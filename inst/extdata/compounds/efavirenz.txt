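# Efavirenz (moderate CYP3A4 inducer) record from published summaries
# (CL ~ 9 L/h, fu 0.01, Vss 3.5 L/kg, 600 mg QD Cmax ~ 4 mg/L). Induction
# parameters are effective unbound values tuned to a moderate-inducer effect
# (sensitive-substrate exposure reduced but > 0.2-fold). Enterocyte binding
# (fu_gut 0.05) limits gut induction, consistent with high protein binding.
name efavirenz
mw 315.7 g/mol
logp 4.6 -
compound_type neutral
bp_ratio 0.74 -
fu_plasma 0.01 fraction
fa 0.95 fraction
ka 0.4 1/h
fu_gut 0.018 fraction
q_gut 15 L/h
vss_target 3.5 L/kg
kp_scalar 1 -
cl_additional 1036 L/h
cl_renal 0 L/h
interaction.ind_max 12 fold
interaction.ind_c50 0.3 uM
interaction.fu_mic 1 fraction
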