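# Illustrative parameter sets for the formin constructs handled by the
# model.  Rates per second, working distances in nm, concentrations in uM.
# These are qualitative calibrations, not fitted constants.
constructs:
  mDia1_FH1_FH2_DAD:
    k_on: 22
    K_co: 1
    k_offO0: 2.0e-4
    k_offT0: 3
    k_decay: 1.0e5
    delta_O: 2.7
    delta_T: 0.8
    K_PB: 30
    K_ring: 0.05
    fh1_boost_max: 8
    K_boost: 0.5
    has_FH1: yes
  mDia1_FH1_2PP_FH2_DAD:
    k_on: 22
    K_co: 1
    k_offO0: 2.0e-4
    k_offT0: 3
    k_decay: 1.0e5
    delta_O: 2.7
    delta_T: 0.8
    K_PB: 30
    K_ring: 0.2
    fh1_boost_max: 5
    K_boost: 0.5
    has_FH1: yes
  mDia1_FH2_DAD:
    k_on: 22
    K_co: 1
    k_offO0: 2.0e-4
    k_offT0: 3
    k_decay: 1.0e5
    delta_O: 2.7
    delta_T: 0.8
    K_PB: 30
    has_FH1: no
    fh1_boost_max: 0
  mDia2_FH1_FH2_DAD:
    k_on: 6
    K_co: 1
    k_offO0: 2.0e-5
    k_offT0: 0.4
    k_decay: 1.0e5
    delta_O: 2.7
    delta_T: 0.8
    K_PB: 30
    K_ring: 0.05
    fh1_boost_max: 8
    K_boost: 0.5
    has_FH1: yes
conditions:
  standard:
    actin: 1
    profilin: 0
    kcl: 100
    kBT: 4.11
  with_profilin:
    actin: 1
    profilin: 5
    kcl: 100
    kBT: 4.11
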