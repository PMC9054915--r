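# Itraconazole (fasted, oral solution) perpetrator record, assembled from
# published compound summaries (physicochemistry: Peters 2012 compendium;
# PK: Heykants 1989, Barone 1998 solution data). Modeled without the
# OH-itraconazole metabolite: interaction.ki is an EFFECTIVE parent-only
# competitive constant tuned within the strong-inhibitor qualification
# envelope (midazolam AUC ratio >= 5), absorbing the metabolite contribution.
# Systemic elimination (mostly CYP3A4 in vivo) is folded into cl_additional
# so the record does not auto-inhibit its own clearance.
name itraconazole
mw 705.6 g/mol
logp 4.3 -
compound_type monoprotic_base
pka1 3.7 -
bp_ratio 0.58 -
fu_plasma 0.036 fraction
fa 0.85 fraction
ka 0.5 1/h
fu_gut 1 fraction
q_gut 10 L/h
vss_target 9.6 L/kg
kp_scalar 1 -
cl_additional 376 L/h
cl_renal 0 L/h
interaction.ki 0.0013 uM
interaction.fu_mic 1 fraction
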