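entry_age: 58.0
horizon: 30
perspective: healthcare
tpA2D: 0.008
tpB2C: 0.165
tpB2F: 0.065
tpC2D: 0.23
tpD2E: 0.375
tpD2F: 0.178
irr_mastectomy: 1.27
tpA2B_multiplier: 1.0
recurrence_mastectomy:
- 56.456692913386
- 26.771653543307
- 7.086614173228
recurrence_lumpectomy_no_rt:
- 71.7
- 34.0
- 9.0
recurrence_lumpectomy_rt:
- 36.9
- 24.3
- 8.3
cam: 87670.0
cal_wo: 27655.0
cal_w: 50352.0
cbm: 17680.0
cbl: 87670.0
cd: 499343.0
infocare: 10003.0
infocare_lump_no_rt: 5002.0
prod: 4104.0
prod_years: 10.0
drg_reference: 36439.0
uam: 0.84
ual: 0.87
ub: 0.78
uc: 0.81
ud: 0.69
ue: 0.76
uf: 0.0
cDR: 0.03
oDR: 0.03
options:
  count_cycle0: yes
  state_a_cost: per_cycle
  informal_care_scope: all_alive
  informal_care_discounted: no
  productivity_survival_weighted: no
  bg_mortality_additive: yes
  half_cycle_correction: no
psa:
- parameter: age
  family: normal
  alpha: 58.0
  beta: 11.8
- parameter: tpA2B
  family: beta
  alpha: 54.84
  beta: 944.16
- parameter: tpA2D
  family: beta
  alpha: 7.7
  beta: 991.3
- parameter: tpB2C
  family: beta
  alpha: 164.52
  beta: 834.48
- parameter: tpB2F
  family: beta
  alpha: 65.05
  beta: 933.95
- parameter: tpC2D
  family: beta
  alpha: 230.16
  beta: 768.84
- parameter: tpD2E
  family: beta
  alpha: 374.33
  beta: 624.67
- parameter: tpD2F
  family: beta
  alpha: 178.31
  beta: 820.69
- parameter: cam
  family: gamma
  alpha: 656.5
  beta: 133.54
- parameter: cal_wo
  family: gamma
  alpha: 4253.8
  beta: 6.5
- parameter: cal_w
  family: gamma
  alpha: 6217.04
  beta: 8.1
- parameter: cbm
  family: gamma
  alpha: 26.7
  beta: 662.2
- parameter: cbl
  family: gamma
  alpha: 42749.589999999997
  beta: 2.05
- parameter: cd
  family: gamma
  alpha: 1386844.909999999916
  beta: 0.36
- parameter: uam
  family: beta
  alpha: 839.16
  beta: 159.84
- parameter: ual
  family: beta
  alpha: 869.13
  beta: 129.87
- parameter: ub
  family: beta
  alpha: 778.22
  beta: 220.78
- parameter: uc
  family: beta
  alpha: 808.69
  beta: 190.31
- parameter: ud
  family: beta
  alpha: 684.32
  beta: 314.69
- parameter: ue
  family: beta
  alpha: 761.74
  beta: 237.26

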