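parameters:
- rho_A
- rho_B
- rho_C
- rho_D
- mu_AB
- mu_AC
- mu_AD
- mu_BA
- mu_BC
- mu_BD
- mu_CA
- mu_CB
- mu_CD
- mu_DA
- mu_DB
- mu_DC
critical_sets: []
swap_sets:
- - rho_A
  - mu_BA
  - mu_CA
  - mu_DA
- - rho_B
  - mu_AB
  - mu_CB
  - mu_DB
- - rho_C
  - mu_AC
  - mu_BC
  - mu_DC
- - rho_D
  - mu_AD
  - mu_BD
  - mu_CD
fixed: []
default_rules: []
bounds:
  rho_A:
    lower: 0.0
    upper: 10.0
  rho_B:
    lower: 0.0
    upper: 10.0
  rho_C:
    lower: 0.0
    upper: 10.0
  rho_D:
    lower: 0.0
    upper: 10.0
  mu_AB:
    lower: 0.0
    upper: 10.0
  mu_AC:
    lower: 0.0
    upper: 10.0
  mu_AD:
    lower: 0.0
    upper: 10.0
  mu_BA:
    lower: 0.0
    upper: 10.0
  mu_BC:
    lower: 0.0
    upper: 10.0
  mu_BD:
    lower: 0.0
    upper: 10.0
  mu_CA:
    lower: 0.0
    upper: 10.0
  mu_CB:
    lower: 0.0
    upper: 10.0
  mu_CD:
    lower: 0.0
    upper: 10.0
  mu_DA:
    lower: 0.0
    upper: 10.0
  mu_DB:
    lower: 0.0
    upper: 10.0
  mu_DC:
    lower: 0.0
    upper: 10.0
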