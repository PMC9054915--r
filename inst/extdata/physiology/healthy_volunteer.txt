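# Healthy-volunteer system physiology (population-simulator style defaults,
# 70 kg reference adult). One "key value unit" triple per line.
# Flows: tissue_blood_flow.liver is the hepatic ARTERY only; gut and spleen
# outflows drain through the liver (portal vein). Systemic tissue inflows
# (adipose..spleen + hepatic artery) sum exactly to cardiac_output.
body_weight 70 kg
cardiac_output 390 L/h
hematocrit 0.45 fraction

tissue_volume.lung 0.53 L
tissue_volume.adipose 13.5 L
tissue_volume.bone 8.5 L
tissue_volume.brain 1.45 L
tissue_volume.gut 1.65 L
tissue_volume.heart 0.33 L
tissue_volume.kidney 0.31 L
tissue_volume.liver 1.65 L
tissue_volume.muscle 29.0 L
tissue_volume.skin 3.4 L
tissue_volume.spleen 0.19 L
tissue_volume.arterial_blood 1.7 L
tissue_volume.venous_blood 3.9 L

tissue_blood_flow.adipose 19.5 L/h
tissue_blood_flow.bone 19.5 L/h
tissue_blood_flow.brain 46.8 L/h
tissue_blood_flow.gut 58.5 L/h
tissue_blood_flow.heart 15.6 L/h
tissue_blood_flow.kidney 74.1 L/h
tissue_blood_flow.liver 25.35 L/h
tissue_blood_flow.muscle 99.45 L/h
tissue_blood_flow.skin 19.5 L/h
tissue_blood_flow.spleen 11.7 L/h

liver_weight 1650 g
mppgl 40 mg/g
cyp3a4_hepatic_abundance 137 pmol/mg
cyp3a4_gut_total 66.2 nmol
kdeg_hepatic 0.0193 1/h
kdeg_gut 0.03 1/h
q_villi 18 L/h
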