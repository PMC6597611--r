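# Parameters of the four synthetic dynamic archetypes used by gen_population().
# Levels are in arbitrary intensity units, times in minutes.  The archetypes
# echo the four dynamic classes seen in neural-progenitor tissue: stable high
# expression, stable lower expression with a gentle drift, early decline and
# delayed decline.  Declining (differentiation-like) archetypes carry
# oscillatory (damped-cosine) fluctuations with an ultradian period; stable
# ones carry aperiodic OU fluctuations.
- name: stable_high
  trend_kind: stable
  level: 130
  onset: ~
  duration: ~
  drop_frac: ~
  fluct_sd_frac: 0.08
  gp_kind: OU
  gp_lengthscale: 0.01     # 1/min
  period_min: ~
  y_range: [5, 45]         # um from ventricle analogue
- name: stable_low_drift
  trend_kind: declining
  level: 80
  onset: 30
  duration: 900
  drop_frac: 0.25
  fluct_sd_frac: 0.08
  gp_kind: OU
  gp_lengthscale: 0.01
  period_min: ~
  y_range: [5, 50]
- name: early_decline
  trend_kind: declining
  level: 110
  onset: 60
  duration: 330
  drop_frac: 0.65
  fluct_sd_frac: 0.06
  gp_kind: OUosc
  gp_lengthscale: 0.003
  period_min: 180
  y_range: [20, 70]
- name: late_decline
  trend_kind: declining
  level: 110
  onset: 390
  duration: 330
  drop_frac: 0.65
  fluct_sd_frac: 0.06
  gp_kind: OUosc
  gp_lengthscale: 0.003
  period_min: 180
  y_range: [25, 90]
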