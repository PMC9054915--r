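# Fluvoxamine (weak CYP3A4 inhibitor) record from published summaries
# (CL/F ~ 50 L/h, F ~ 0.53, Vss ~ 20 L/kg). interaction.ki is an effective
# unbound competitive constant tuned within the weak-inhibitor qualification
# envelope (midazolam AUC ratio 1.25-2; ipatasertib ratio < 1.25).
name fluvoxamine
mw 318.3 g/mol
logp 3.2 -
compound_type monoprotic_base
pka1 9.4 -
bp_ratio 1.0 -
fu_plasma 0.23 fraction
fa 0.75 fraction
ka 0.4 1/h
fu_gut 1 fraction
q_gut 12 L/h
vss_target 20 L/kg
kp_scalar 1 -
cl_additional 172 L/h
cl_renal 0.5 L/h
interaction.ki 0.3 uM
interaction.fu_mic 1 fraction
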