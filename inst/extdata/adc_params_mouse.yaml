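# ADC parameter set (mouse) for the MMAE ADC PBPK model.
# mab: FcRn binding kinetics (1/nM/h, 1/h), pinocytosis rate per unit
#   endosomal volume (1/h), recycled fraction, lysosomal degradation of
#   FcRn-unbound antibody (1/h, naked-mAb base; multiplied by
#   coupling$f_Kdeg for the conjugate).
# payload: unbound plasma fraction, blood-cell partition, hepatic
#   intrinsic clearance (mL/min/kg).
# deconjugation: empirical DAR-dependent rate (1/day) and species
#   scaling factor.
mab:
  kon_FcRn: 0.0806
  koff_FcRn: 6.55
  CL_up: 0.55
  FR: 0.715
  kdeg_base: 30
payload:
  fup: 0.2
  Kp_BC: 5.46
  CLint: 67.7
  ps_scaling: none
deconjugation:
  alpha: 0.0806
  beta: 0.0102
  F: 0.282
  tau: 5.68
  SF: 1
coupling:
  DAR0: 4
  f_Kdeg: 1
  MW_mAb: 150000
  MW_MMAE: 717.98
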