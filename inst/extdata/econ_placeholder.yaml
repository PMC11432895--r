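# PLACEHOLDER health-economic parameter set (synthetic).
# Plausible values chosen to satisfy every structural invariant of the model
# (row-stochastic transitions, absorbing death, undiagnosed progression at
# least as fast as diagnosed). They are NOT the study's supplementary
# parameter tables; transcribe those here to reproduce published base-case
# numbers.
#
# Units: transition probabilities per year; costs GBP/year (states) or GBP
# one-off (referral); utilities QALY-weight/year in [0,1].
transitions:
  MLD:
    SLD_fn: 0.020
    DEAD: 0.015
  SLD_dx:
    CC_dx: 0.025
    DEAD: 0.017
  SLD_fn:
    CC_fn: 0.055
    DEAD: 0.019
  CC_dx:
    DC: 0.035
    HCC: 0.015
    DEAD: 0.025
  CC_fn:
    DC: 0.070
    HCC: 0.025
    DEAD: 0.040
  DC:
    HCC: 0.020
    LT: 0.020
    DEAD: 0.140
  HCC:
    LT: 0.030
    DEAD: 0.250
  LT:
    DEAD: 0.050
costs:
  MLD: 40
  SLD_dx: 900
  SLD_fn: 40
  CC_dx: 4000
  CC_fn: 250
  DC: 11500
  HCC: 14000
  LT: 21000
  DEAD: 0
utilities:
  MLD: 0.85
  SLD_dx: 0.82
  SLD_fn: 0.80
  CC_dx: 0.74
  CC_fn: 0.72
  DC: 0.52
  HCC: 0.45
  LT: 0.67
  DEAD: 0.0
referral_cost: 250
discount_rate: 0.035
horizon: 40
cohort_size: 287
cet: 20000
entry_prevalence:
  MLD: 0.83
  SLD: 0.14
  CC: 0.03
soc_lfts_share: 0.5
half_cycle_correction: false
psa:
  n_eff_probabilities: 100
  n_eff_utilities: 50
  cost_cv: 0.2
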