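circulation:
  E_la:
    value: 0.165
    unit: mmHg/mL
  V0_la:
    value: 4.0
    unit: mL
  Emax_lv:
    value: 2.6
    unit: mmHg/mL
  Emin_lv:
    value: 0.1
    unit: mmHg/mL
  V0_lv:
    value: 5.0
    unit: mL
  E_ra:
    value: 0.12
    unit: mmHg/mL
  V0_ra:
    value: 4.0
    unit: mL
  Emax_rv:
    value: 0.55
    unit: mmHg/mL
  Emin_rv:
    value: 0.045
    unit: mmHg/mL
  V0_rv:
    value: 10.0
    unit: mL
  R_mi:
    value: 0.006
    unit: mmHg.s/mL
  L_mi:
    value: 0.0005
    unit: mmHg.s2/mL
  R_ao:
    value: 0.01
    unit: mmHg.s/mL
  R_ti:
    value: 0.011
    unit: mmHg.s/mL
  R_po:
    value: 0.008
    unit: mmHg.s/mL
  C_sas:
    value: 1.75
    unit: mL/mmHg
  V0_sas:
    value: 600.0
    unit: mL
  R_sys:
    value: 1.08
    unit: mmHg.s/mL
  L_sys:
    value: 0.0025
    unit: mmHg.s2/mL
  C_svn:
    value: 70.0
    unit: mL/mmHg
  V0_svn:
    value: 3400.0
    unit: mL
  R_svn:
    value: 0.05
    unit: mmHg.s/mL
  C_pas:
    value: 5.0
    unit: mL/mmHg
  V0_pas:
    value: 120.0
    unit: mL
  R_pul:
    value: 0.13
    unit: mmHg.s/mL
  L_pul:
    value: 0.0008
    unit: mmHg.s2/mL
  C_pvn:
    value: 15.0
    unit: mL/mmHg
  V0_pvn:
    value: 150.0
    unit: mL
  R_pvn:
    value: 0.008
    unit: mmHg.s/mL
  k_sys:
    value: 0.4726
    unit: s^(1-alpha)
  alpha_sys:
    value: 0.4
    unit: dimensionless
  sys_split:
    value: 0.5
    unit: dimensionless
  total_volume:
    value: 5740.0
    unit: mL
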