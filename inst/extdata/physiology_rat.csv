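# Species physiology for the whole-body ADC PBPK model: rat
# SYNTHETIC parameterization: organ volumes and plasma flows assembled
# from standard physiology compilations (fraction-of-body-weight organ
# masses, fraction-of-cardiac-output plasma flows, cardiac output
# 14.1*BW^0.75 L/h blood); not transcribed from any single source.
# Liver Q_plasma is hepatic-artery flow; splanchnic organs (spleen,
# small/large intestine, pancreas) drain into the liver inflow.
# Lymph flow = 0.2% of tissue plasma flow. Units: volumes L, flows L/h.
# species: rat
# body_weight_kg: 0.28
# hematocrit: 0.45
# fcrn_nM: 91400
# lymph_fraction: 0.002
name,V_plasma,V_bloodcell,V_endosomal,V_interstitial,V_cellular,Q_plasma,L_lymph,sigma_v,sigma_i
lung,0.0001848,0.0001512,1.12e-05,0.0004256,0.0014672,2.985041172,0.005970082,0.95,0.2
heart,4.62e-05,3.78e-05,7e-06,0.00014,0.001169,0.119401647,0.0002388033,0.95,0.2
kidney,5.4208e-05,4.4352e-05,6.16e-06,0.0001848,0.00094248,0.507456999,0.001014914,0.9,0.2
muscle,0.001232,0.001008,0.00056,0.01456,0.09464,0.507456999,0.001014914,0.95,0.2
skin,0.00011396,9.324e-05,5.18e-05,0.003108,0.006993,0.173132388,0.0003462648,0.95,0.2
liver,0.00048048,0.00039312,3.64e-05,0.0012012,0.0051688,0.194027676,0.0003880554,0.85,0.2
brain,9.24e-05,7.56e-05,2.8e-05,0.00028,0.005124,0.328354529,0.0006567091,0.99,0.2
fat,0.000154,0.000126,0.00014,0.00378,0.0238,0.149252059,0.0002985041,0.95,0.2
thymus,4.158e-06,3.402e-06,1.26e-06,3.78e-05,0.00020538,0.004477562,8.955124e-06,0.9,0.2
bone,0.0003696,0.0003024,0.000112,0.00224,0.019376,0.149252059,0.0002985041,0.85,0.2
small_intestine,2.772e-05,2.268e-05,1.26e-05,0.0004788,0.0019782,0.298504117,0.0005970082,0.9,0.2
large_intestine,1.848e-05,1.512e-05,8.4e-06,0.0003192,0.0013188,0.119401647,0.0002388033,0.9,0.2
spleen,8.008e-05,6.552e-05,3.64e-06,0.0001092,0.00046956,0.059700823,0.0001194016,0.85,0.2
pancreas,1.078e-05,8.82e-06,1.96e-06,4.704e-05,0.0003234,0.029850412,5.970082e-05,0.9,0.2
other,0.0008778,0.0007182,0.000266,0.00798,0.043358,0.344772255,0.0006895445,0.95,0.2
blood,0.006468,0.005292,0,0,0,2.985041172,0,0,0
lymph_node,0.00056,0,0,0,0,0.011940165,0,0,0
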