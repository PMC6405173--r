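provenance:
  geometry: paper
  medulla: paper
  pt_split: fixture
  depth_map: fixture
medulla_cm: 1.7
outer_medulla_cm: 0.5
viscosity_mmHg_s: 6.4e-06
SNGFR_nlmin: 100.0
inflow_pressure_mmHg: 21.0
interstitial_pressure_mmHg: 5.0
nephrons_per_kidney: 1000000.0
segments:
- name: PT-S1S2
  length_cm: 1.2
  diameter_um: 37.0
  compliant: yes
  nu_per_mmHg: 0.03
  r0_um: 14.0
  P0_mmHg: 20.0
  torque_s: 1.5
  lmv_um: 2.5
  dmv_um: 0.15
  population_rule: constant
  omega0: 1.0
  depth0: 0.0
  depth1: 0.0
- name: PT-S3
  length_cm: 0.5
  diameter_um: 37.0
  compliant: yes
  nu_per_mmHg: 0.03
  r0_um: 14.0
  P0_mmHg: 20.0
  torque_s: 0.75
  lmv_um: 2.5
  dmv_um: 0.15
  population_rule: constant
  omega0: 1.0
  depth0: 0.0
  depth1: 0.18
- name: DL
  length_cm: 0.32
  diameter_um: 26.0
  compliant: no
  nu_per_mmHg: 0.0
  r0_um: .na.real
  P0_mmHg: .na.real
  torque_s: 0.0
  lmv_um: .na.real
  dmv_um: .na.real
  population_rule: constant
  omega0: 1.0
  depth0: 0.18
  depth1: 0.5
- name: mTAL
  length_cm: 0.5
  diameter_um: 26.0
  compliant: no
  nu_per_mmHg: 0.0
  r0_um: .na.real
  P0_mmHg: .na.real
  torque_s: 0.0
  lmv_um: .na.real
  dmv_um: .na.real
  population_rule: constant
  omega0: 1.0
  depth0: 0.5
  depth1: 0.0
- name: cTAL
  length_cm: 0.5
  diameter_um: 26.0
  compliant: no
  nu_per_mmHg: 0.0
  r0_um: .na.real
  P0_mmHg: .na.real
  torque_s: 0.0
  lmv_um: .na.real
  dmv_um: .na.real
  population_rule: constant
  omega0: 1.0
  depth0: 0.0
  depth1: 0.0
- name: DCT
  length_cm: 0.2
  diameter_um: 20.0
  compliant: no
  nu_per_mmHg: 0.0
  r0_um: .na.real
  P0_mmHg: .na.real
  torque_s: 0.0
  lmv_um: .na.real
  dmv_um: .na.real
  population_rule: constant
  omega0: 1.0
  depth0: 0.0
  depth1: 0.0
- name: CNT
  length_cm: 0.4
  diameter_um: 24.0
  compliant: no
  nu_per_mmHg: 0.0
  r0_um: .na.real
  P0_mmHg: .na.real
  torque_s: 0.0
  lmv_um: .na.real
  dmv_um: .na.real
  population_rule: CNT-exponential
  omega0: 1.0
  depth0: 0.0
  depth1: 0.0
- name: CCD
  length_cm: 0.4
  diameter_um: 45.0
  compliant: no
  nu_per_mmHg: 0.0
  r0_um: .na.real
  P0_mmHg: .na.real
  torque_s: 0.0
  lmv_um: .na.real
  dmv_um: .na.real
  population_rule: constant
  omega0: 0.1
  depth0: 0.0
  depth1: 0.0
- name: OMCD
  length_cm: 0.5
  diameter_um: 45.0
  compliant: no
  nu_per_mmHg: 0.0
  r0_um: .na.real
  P0_mmHg: .na.real
  torque_s: 0.0
  lmv_um: .na.real
  dmv_um: .na.real
  population_rule: constant
  omega0: 0.1
  depth0: 0.0
  depth1: 0.5
- name: IMCD
  length_cm: 1.2
  diameter_um: 50.0
  compliant: no
  nu_per_mmHg: 0.0
  r0_um: .na.real
  P0_mmHg: .na.real
  torque_s: 0.0
  lmv_um: .na.real
  dmv_um: .na.real
  population_rule: IMCD-profile
  omega0: 0.1
  depth0: 0.5
  depth1: 1.7
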