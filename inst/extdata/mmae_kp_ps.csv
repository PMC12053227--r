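# MMAE tissue-to-plasma partition coefficients (Kp) and permeability-
# surface-area products (PS, L/h) for cellular and blood-cell exchange.
# SYNTHETIC assumed defaults (the mouse-biodistribution-derived table is
# not printed in the source literature); species-independent by default.
# Kp on the blood row is unused (blood-cell partitioning uses Kp_BC from
# the species parameter file).
tissue,Kp,PS_cell,PS_BC
lung,10,0.01834,0.189
heart,8,0.0146125,0.04725
kidney,15,0.011781,0.05544
muscle,5,1.183,1.26
skin,8,0.0874125,0.11655
liver,30,0.06461,0.4914
brain,0.5,0.06405,0.0945
fat,10,0.2975,0.1575
thymus,8,0.00256725,0.0042525
bone,5,0.2422,0.378
small_intestine,15,0.0247275,0.02835
large_intestine,15,0.016485,0.0189
spleen,20,0.0058695,0.0819
pancreas,10,0.0040425,0.011025
other,8,0.541975,0.89775
blood,NA,0,6.615
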