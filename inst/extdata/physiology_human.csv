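# Species physiology for the whole-body ADC PBPK model: human
# SYNTHETIC parameterization: organ volumes and plasma flows assembled
# from standard physiology compilations (fraction-of-body-weight organ
# masses, fraction-of-cardiac-output plasma flows, cardiac output
# 14.1*BW^0.75 L/h blood); not transcribed from any single source.
# Liver Q_plasma is hepatic-artery flow; splanchnic organs (spleen,
# small/large intestine, pancreas) drain into the liver inflow.
# Lymph flow = 0.2% of tissue plasma flow. Units: volumes L, flows L/h.
# species: human
# body_weight_kg: 70
# hematocrit: 0.45
# fcrn_nM: 33800
# lymph_fraction: 0.002
name,V_plasma,V_bloodcell,V_endosomal,V_interstitial,V_cellular,Q_plasma,L_lymph,sigma_v,sigma_i
lung,0.0462,0.0378,0.0028,0.1064,0.3668,187.6745279,0.3753490559,0.95,0.2
heart,0.01155,0.00945,0.00175,0.035,0.29225,7.5069811,0.0150139622,0.95,0.2
kidney,0.013552,0.011088,0.00154,0.0462,0.23562,31.9046698,0.0638093395,0.9,0.2
muscle,0.308,0.252,0.14,3.64,23.66,31.9046698,0.0638093395,0.95,0.2
skin,0.02849,0.02331,0.01295,0.777,1.74825,10.8851226,0.0217702452,0.95,0.2
liver,0.12012,0.09828,0.0091,0.3003,1.2922,12.1988443,0.0243976886,0.85,0.2
brain,0.0231,0.0189,0.007,0.07,1.281,20.6441981,0.0412883961,0.99,0.2
fat,0.0385,0.0315,0.035,0.945,5.95,9.3837264,0.0187674528,0.95,0.2
thymus,0.0010395,0.0008505,0.000315,0.00945,0.051345,0.2815118,0.0005630236,0.9,0.2
bone,0.0924,0.0756,0.028,0.56,4.844,9.3837264,0.0187674528,0.85,0.2
small_intestine,0.00693,0.00567,0.00315,0.1197,0.49455,18.7674528,0.0375349056,0.9,0.2
large_intestine,0.00462,0.00378,0.0021,0.0798,0.3297,7.5069811,0.0150139622,0.9,0.2
spleen,0.02002,0.01638,0.00091,0.0273,0.11739,3.7534906,0.0075069811,0.85,0.2
pancreas,0.002695,0.002205,0.00049,0.01176,0.08085,1.8767453,0.0037534906,0.9,0.2
other,0.21945,0.17955,0.0665,1.995,10.8395,21.676408,0.043352816,0.95,0.2
blood,1.617,1.323,0,0,0,187.6745279,0,0,0
lymph_node,0.14,0,0,0,0,0.7506981,0,0,0
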