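parameters:
- rho_C0
- rho_C1
- rho_C2
- rho_C3
- rho_C4
- rho_C5
- rho_C6
- rho_C7
- rho_C8
- rho_C9
- delta_C0
- delta_C1
- delta_C2
- delta_C3
- delta_C4
- delta_C5
- delta_C6
- delta_C7
- delta_C8
- delta_C9
- tau_C
- rho_S0
- rho_S1
- rho_S2
- rho_S3
- rho_S4
- rho_S5
- rho_S6
- rho_S7
- rho_S8
- rho_S9
- delta_S0
- delta_S1
- delta_S2
- delta_S3
- delta_S4
- delta_S5
- delta_S6
- delta_S7
- delta_S8
- delta_S9
- tau_S
- sigma_tilde
critical_sets:
- - rho_C0
  - delta_C0
- - sigma_tilde
swap_sets:
- - rho_C0
  - rho_C1
  - rho_C2
  - rho_C3
  - rho_C4
  - rho_C5
  - rho_C6
  - rho_C7
  - rho_C8
  - rho_C9
  - delta_C0
  - delta_C1
  - delta_C2
  - delta_C3
  - delta_C4
  - delta_C5
  - delta_C6
  - delta_C7
  - delta_C8
  - delta_C9
  - tau_C
  - rho_S0
  - rho_S1
  - rho_S2
  - rho_S3
  - rho_S4
  - rho_S5
  - rho_S6
  - rho_S7
  - rho_S8
  - rho_S9
  - delta_S0
  - delta_S1
  - delta_S2
  - delta_S3
  - delta_S4
  - delta_S5
  - delta_S6
  - delta_S7
  - delta_S8
  - delta_S9
  - tau_S
fixed: []
default_rules:
  rho_C1:
  - ref: rho_C0
  delta_C1:
  - ref: delta_C0
  rho_C2:
  - ref: rho_C1
  delta_C2:
  - ref: delta_C1
  rho_C3:
  - ref: rho_C2
  delta_C3:
  - ref: delta_C2
  rho_C4:
  - ref: rho_C3
  delta_C4:
  - ref: delta_C3
  rho_C5:
  - ref: rho_C4
  delta_C5:
  - ref: delta_C4
  rho_C6:
  - ref: rho_C5
  delta_C6:
  - ref: delta_C5
  rho_C7:
  - ref: rho_C6
  delta_C7:
  - ref: delta_C6
  rho_C8:
  - ref: rho_C7
  delta_C8:
  - ref: delta_C7
  rho_C9:
  - ref: rho_C8
  delta_C9:
  - ref: delta_C8
  rho_S0:
  - ref: rho_C0
  delta_S0:
  - ref: delta_C0
  rho_S1:
  - ref: rho_S0
    guard:
    - rho_S0
    - rho_S1
  - ref: rho_C1
  delta_S1:
  - ref: delta_S0
    guard:
    - delta_S0
    - delta_S1
  - ref: delta_C1
  rho_S2:
  - ref: rho_S1
    guard:
    - rho_S0
    - rho_S1
    - rho_S2
  - ref: rho_C2
  delta_S2:
  - ref: delta_S1
    guard:
    - delta_S0
    - delta_S1
    - delta_S2
  - ref: delta_C2
  rho_S3:
  - ref: rho_S2
    guard:
    - rho_S0
    - rho_S1
    - rho_S2
    - rho_S3
  - ref: rho_C3
  delta_S3:
  - ref: delta_S2
    guard:
    - delta_S0
    - delta_S1
    - delta_S2
    - delta_S3
  - ref: delta_C3
  rho_S4:
  - ref: rho_S3
    guard:
    - rho_S0
    - rho_S1
    - rho_S2
    - rho_S3
    - rho_S4
  - ref: rho_C4
  delta_S4:
  - ref: delta_S3
    guard:
    - delta_S0
    - delta_S1
    - delta_S2
    - delta_S3
    - delta_S4
  - ref: delta_C4
  rho_S5:
  - ref: rho_S4
    guard:
    - rho_S0
    - rho_S1
    - rho_S2
    - rho_S3
    - rho_S4
    - rho_S5
  - ref: rho_C5
  delta_S5:
  - ref: delta_S4
    guard:
    - delta_S0
    - delta_S1
    - delta_S2
    - delta_S3
    - delta_S4
    - delta_S5
  - ref: delta_C5
  rho_S6:
  - ref: rho_S5
    guard:
    - rho_S0
    - rho_S1
    - rho_S2
    - rho_S3
    - rho_S4
    - rho_S5
    - rho_S6
  - ref: rho_C6
  delta_S6:
  - ref: delta_S5
    guard:
    - delta_S0
    - delta_S1
    - delta_S2
    - delta_S3
    - delta_S4
    - delta_S5
    - delta_S6
  - ref: delta_C6
  rho_S7:
  - ref: rho_S6
    guard:
    - rho_S0
    - rho_S1
    - rho_S2
    - rho_S3
    - rho_S4
    - rho_S5
    - rho_S6
    - rho_S7
  - ref: rho_C7
  delta_S7:
  - ref: delta_S6
    guard:
    - delta_S0
    - delta_S1
    - delta_S2
    - delta_S3
    - delta_S4
    - delta_S5
    - delta_S6
    - delta_S7
  - ref: delta_C7
  rho_S8:
  - ref: rho_S7
    guard:
    - rho_S0
    - rho_S1
    - rho_S2
    - rho_S3
    - rho_S4
    - rho_S5
    - rho_S6
    - rho_S7
    - rho_S8
  - ref: rho_C8
  delta_S8:
  - ref: delta_S7
    guard:
    - delta_S0
    - delta_S1
    - delta_S2
    - delta_S3
    - delta_S4
    - delta_S5
    - delta_S6
    - delta_S7
    - delta_S8
  - ref: delta_C8
  rho_S9:
  - ref: rho_S8
    guard:
    - rho_S0
    - rho_S1
    - rho_S2
    - rho_S3
    - rho_S4
    - rho_S5
    - rho_S6
    - rho_S7
    - rho_S8
    - rho_S9
  - ref: rho_C9
  delta_S9:
  - ref: delta_S8
    guard:
    - delta_S0
    - delta_S1
    - delta_S2
    - delta_S3
    - delta_S4
    - delta_S5
    - delta_S6
    - delta_S7
    - delta_S8
    - delta_S9
  - ref: delta_C9
  tau_S:
  - ref: tau_C
bounds:
  rho_C0:
    lower: 0.0
    upper: 1.0
  rho_C1:
    lower: 0.0
    upper: 1.0
  rho_C2:
    lower: 0.0
    upper: 1.0
  rho_C3:
    lower: 0.0
    upper: 1.0
  rho_C4:
    lower: 0.0
    upper: 1.0
  rho_C5:
    lower: 0.0
    upper: 1.0
  rho_C6:
    lower: 0.0
    upper: 1.0
  rho_C7:
    lower: 0.0
    upper: 1.0
  rho_C8:
    lower: 0.0
    upper: 1.0
  rho_C9:
    lower: 0.0
    upper: 1.0
  delta_C0:
    lower: 0.0
    upper: 1.0
  delta_C1:
    lower: 0.0
    upper: 1.0
  delta_C2:
    lower: 0.0
    upper: 1.0
  delta_C3:
    lower: 0.0
    upper: 1.0
  delta_C4:
    lower: 0.0
    upper: 1.0
  delta_C5:
    lower: 0.0
    upper: 1.0
  delta_C6:
    lower: 0.0
    upper: 1.0
  delta_C7:
    lower: 0.0
    upper: 1.0
  delta_C8:
    lower: 0.0
    upper: 1.0
  delta_C9:
    lower: 0.0
    upper: 1.0
  tau_C:
    lower: 0.0
    upper: 48.0
  rho_S0:
    lower: 0.0
    upper: 1.0
  rho_S1:
    lower: 0.0
    upper: 1.0
  rho_S2:
    lower: 0.0
    upper: 1.0
  rho_S3:
    lower: 0.0
    upper: 1.0
  rho_S4:
    lower: 0.0
    upper: 1.0
  rho_S5:
    lower: 0.0
    upper: 1.0
  rho_S6:
    lower: 0.0
    upper: 1.0
  rho_S7:
    lower: 0.0
    upper: 1.0
  rho_S8:
    lower: 0.0
    upper: 1.0
  rho_S9:
    lower: 0.0
    upper: 1.0
  delta_S0:
    lower: 0.0
    upper: 1.0
  delta_S1:
    lower: 0.0
    upper: 1.0
  delta_S2:
    lower: 0.0
    upper: 1.0
  delta_S3:
    lower: 0.0
    upper: 1.0
  delta_S4:
    lower: 0.0
    upper: 1.0
  delta_S5:
    lower: 0.0
    upper: 1.0
  delta_S6:
    lower: 0.0
    upper: 1.0
  delta_S7:
    lower: 0.0
    upper: 1.0
  delta_S8:
    lower: 0.0
    upper: 1.0
  delta_S9:
    lower: 0.0
    upper: 1.0
  tau_S:
    lower: 0.0
    upper: 48.0
  sigma_tilde:
    lower: 9.99999999999999955e-07
    upper: 1.0
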