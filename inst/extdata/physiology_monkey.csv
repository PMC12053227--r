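# Species physiology for the whole-body ADC PBPK model: monkey
# SYNTHETIC parameterization: organ volumes and plasma flows assembled
# from standard physiology compilations (fraction-of-body-weight organ
# masses, fraction-of-cardiac-output plasma flows, cardiac output
# 14.1*BW^0.75 L/h blood); not transcribed from any single source.
# Liver Q_plasma is hepatic-artery flow; splanchnic organs (spleen,
# small/large intestine, pancreas) drain into the liver inflow.
# Lymph flow = 0.2% of tissue plasma flow. Units: volumes L, flows L/h.
# species: monkey
# body_weight_kg: 6.2
# hematocrit: 0.45
# fcrn_nM: 30000
# lymph_fraction: 0.002
name,V_plasma,V_bloodcell,V_endosomal,V_interstitial,V_cellular,Q_plasma,L_lymph,sigma_v,sigma_i
lung,0.004092,0.003348,0.000248,0.009424,0.032488,30.47021855,0.06094044,0.95,0.2
heart,0.001023,0.000837,0.000155,0.0031,0.025885,1.21880874,0.002437617,0.95,0.2
kidney,0.00120032,0.00098208,0.0001364,0.004092,0.0208692,5.17993715,0.01035987,0.9,0.2
muscle,0.02728,0.02232,0.0124,0.3224,2.0956,5.17993715,0.01035987,0.95,0.2
skin,0.0025234,0.0020646,0.001147,0.06882,0.154845,1.76727268,0.003534545,0.95,0.2
liver,0.0106392,0.0087048,0.000806,0.026598,0.114452,1.98056421,0.003961128,0.85,0.2
brain,0.002046,0.001674,0.00062,0.0062,0.11346,3.35172404,0.006703448,0.99,0.2
fat,0.00341,0.00279,0.0031,0.0837,0.527,1.52351093,0.003047022,0.95,0.2
thymus,9.207e-05,7.533e-05,2.79e-05,0.000837,0.0045477,0.04570533,9.141066e-05,0.9,0.2
bone,0.008184,0.006696,0.00248,0.0496,0.42904,1.52351093,0.003047022,0.85,0.2
small_intestine,0.0006138,0.0005022,0.000279,0.010602,0.043803,3.04702186,0.006094044,0.9,0.2
large_intestine,0.0004092,0.0003348,0.000186,0.007068,0.029202,1.21880874,0.002437617,0.9,0.2
spleen,0.0017732,0.0014508,8.06e-05,0.002418,0.0103974,0.60940437,0.001218809,0.85,0.2
pancreas,0.0002387,0.0001953,4.34e-05,0.0010416,0.007161,0.30470219,0.0006094044,0.9,0.2
other,0.019437,0.015903,0.00589,0.1767,0.96007,3.51931024,0.00703862,0.95,0.2
blood,0.14322,0.11718,0,0,0,30.47021855,0,0,0
lymph_node,0.0124,0,0,0,0,0.12188087,0,0,0
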