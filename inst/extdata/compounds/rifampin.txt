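# Rifampin (strong CYP3A4 inducer) record from published summaries
# (CL ~ 7 L/h, fu 0.15, Vss 0.7 L/kg). Induction Emax/EC50 (unbound) tuned
# within the strong-inducer qualification envelope (sensitive-substrate AUC
# ratio <= 0.2). Weak competitive inhibition included for completeness.
# Zwitterion approximated as neutral for tissue partitioning; the Kp scalar
# (matched to Vss) absorbs the approximation.
name rifampin
mw 822.9 g/mol
logp 2.7 -
compound_type neutral
bp_ratio 0.9 -
fu_plasma 0.15 fraction
fa 0.95 fraction
ka 1.0 1/h
fu_gut 1 fraction
q_gut 20 L/h
vss_target 0.7 L/kg
kp_scalar 1 -
cl_additional 39 L/h
cl_renal 1.5 L/h
interaction.ki 20 uM
interaction.ind_max 8 fold
interaction.ind_c50 0.32 uM
interaction.fu_mic 1 fraction
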