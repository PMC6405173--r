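provenance:
  descriptors: paper
experiments:
- name: baseline
  sngfr_scale: 1.0
  inhibit: ~
  washout: no
  torque_off: no
- name: sngfr+10
  sngfr_scale: 1.1
  inhibit: ~
  washout: no
  torque_off: no
- name: sngfr-10
  sngfr_scale: 0.9
  inhibit: ~
  washout: no
  torque_off: no
- name: sglt2
  sngfr_scale: 0.97
  inhibit: 0.9
  washout: no
  torque_off: no
- name: nkcc2
  sngfr_scale: 1.0
  inhibit: 0.8
  washout: yes
  torque_off: no
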