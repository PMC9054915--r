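# Ipatasertib final-model parameter record.
# Enzyme kinetics are recombinant-CYP3A4 units (pmol/min/pmol isoform);
# cl_additional is an intrinsic hepatic clearance acting on unbound liver
# water concentration; cl_renal acts on venous plasma.
name ipatasertib
mw 458 g/mol
logp 3 -
compound_type diprotic_base
pka1 9 -
pka2 4.9 -
bp_ratio 1.43 -
fu_plasma 0.63 fraction
fa 0.76 fraction
ka 0.76 1/h
fu_gut 1 fraction
q_gut 9.28 L/h
papp_mdck 3.55 1e-6cm/s
perm_scalar 3.89 -
peff 1.74 1e-4cm/s
vss_target 39.13 L/kg
kp_scalar 4.47 -
cyp3a4.vmax 0.135 pmol/min/pmol
cyp3a4.km 0.195 uM
cyp3a4.fu_mic 1 fraction
cl_additional 2.7 L/h
cl_renal 19.3 L/h
interaction.ki 4.4 uM
interaction.kapp 9.66 uM
interaction.kinact 0.17 1/h
interaction.fu_mic 1 fraction
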