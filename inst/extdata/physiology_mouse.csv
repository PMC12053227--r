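# Species physiology for the whole-body ADC PBPK model: mouse
# SYNTHETIC parameterization: organ volumes and plasma flows assembled
# from standard physiology compilations (fraction-of-body-weight organ
# masses, fraction-of-cardiac-output plasma flows, cardiac output
# 14.1*BW^0.75 L/h blood); not transcribed from any single source.
# Liver Q_plasma is hepatic-artery flow; splanchnic organs (spleen,
# small/large intestine, pancreas) drain into the liver inflow.
# Lymph flow = 0.2% of tissue plasma flow. Units: volumes L, flows L/h.
# species: mouse
# body_weight_kg: 0.028
# hematocrit: 0.45
# fcrn_nM: 29900
# lymph_fraction: 0.002
name,V_plasma,V_bloodcell,V_endosomal,V_interstitial,V_cellular,Q_plasma,L_lymph,sigma_v,sigma_i
lung,1.848e-05,1.512e-05,1.12e-06,4.256e-05,0.00014672,0.5308237255,0.001061647,0.95,0.2
heart,4.62e-06,3.78e-06,7e-07,1.4e-05,0.0001169,0.021232949,4.24659e-05,0.95,0.2
kidney,5.4208e-06,4.4352e-06,6.16e-07,1.848e-05,9.4248e-05,0.0902400333,0.0001804801,0.9,0.2
muscle,0.0001232,0.0001008,5.6e-05,0.001456,0.009464,0.0902400333,0.0001804801,0.95,0.2
skin,1.1396e-05,9.324e-06,5.18e-06,0.0003108,0.0006993,0.0307877761,6.157555e-05,0.95,0.2
liver,4.8048e-05,3.9312e-05,3.64e-06,0.00012012,0.00051688,0.0345035422,6.900708e-05,0.85,0.2
brain,9.24e-06,7.56e-06,2.8e-06,2.8e-05,0.0005124,0.0583906098,0.0001167812,0.99,0.2
fat,1.54e-05,1.26e-05,1.4e-05,0.000378,0.00238,0.0265411863,5.308237e-05,0.95,0.2
thymus,4.158e-07,3.402e-07,1.26e-07,3.78e-06,2.0538e-05,0.0007962356,1.592471e-06,0.9,0.2
bone,3.696e-05,3.024e-05,1.12e-05,0.000224,0.0019376,0.0265411863,5.308237e-05,0.85,0.2
small_intestine,2.772e-06,2.268e-06,1.26e-06,4.788e-05,0.00019782,0.0530823725,0.0001061647,0.9,0.2
large_intestine,1.848e-06,1.512e-06,8.4e-07,3.192e-05,0.00013188,0.021232949,4.24659e-05,0.9,0.2
spleen,8.008e-06,6.552e-06,3.64e-07,1.092e-05,4.6956e-05,0.0106164745,2.123295e-05,0.85,0.2
pancreas,1.078e-06,8.82e-07,1.96e-07,4.704e-06,3.234e-05,0.0053082373,1.061647e-05,0.9,0.2
other,8.778e-05,7.182e-05,2.66e-05,0.000798,0.0043358,0.0613101403,0.0001226203,0.95,0.2
blood,0.0006468,0.0005292,0,0,0,0.5308237255,0,0,0
lymph_node,5.6e-05,0,0,0,0,0.0021232949,0,0,0
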