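# Same series with potential-energy barriers; no value is reported for water.
barrier_kind: potential_energy
environments:
- label: '3'
  ts_xyz: ts_3.xyz
  rc_charges: rc_3_charges.csv
  ts_charges: ts_3_charges.csv
  c1: 2
  cl1: 3
  o1: 1
  nucleophile_indices: [7]
  barrier_kcal_mol: 13.4
- label: '2'
  ts_xyz: ts_2.xyz
  rc_charges: rc_2_charges.csv
  ts_charges: ts_2_charges.csv
  c1: 2
  cl1: 3
  o1: 1
  nucleophile_indices: [7]
  barrier_kcal_mol: 15.4
- label: '1'
  ts_xyz: ts_1.xyz
  rc_charges: rc_1_charges.csv
  ts_charges: ts_1_charges.csv
  c1: 2
  cl1: 3
  o1: 1
  nucleophile_indices: [7]
  barrier_kcal_mol: 18.1
- label: '0'
  rc_charges: rc_0_charges.csv
  ts_charges: ts_0_charges.csv
  c1: 2
  cl1: 3
  o1: 1
  nucleophile_indices: [7]
  barrier_kcal_mol: 22.2
- label: water
  role: predict
  ts_xyz: ts_water.xyz
  rc_charges: rc_water_charges.csv
  ts_charges: ts_water_charges.csv
  c1: 2
  cl1: 3
  o1: 1
  nucleophile_indices: [7]
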