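transitions:
  p_dialysis_annual_lpd:
    value: 0.244
    provenance: paper
    low: 0.2196
    high: 0.2684
  hr_dialysis_svlpd:
    value: 0.237
    provenance: paper
    low: 0.22
    high: 0.26
  p_death_pre_annual:
    value: 0.111
    provenance: paper
    low: 0.0999
    high: 0.1221
  p_death_dialysis_annual:
    value: 0.138
    provenance: paper
    low: 0.1242
    high: 0.1518
  p_death_dialysis_annual_scenario:
    value: 0.108
    provenance: paper
demographics:
  fraction_male:
    value: 0.558
    provenance: paper
  age_male:
    value: 70.0
    provenance: paper
  age_female:
    value: 72.0
    provenance: paper
dialysis_mix:
  share_hd:
    value: 0.838
    provenance: paper
    low: 0.6704
    high: 1.0
  share_capd:
    value: 0.077
    provenance: paper
  share_apd:
    value: 0.085
    provenance: paper
unit_costs:
  ketoanalogue_per_tablet:
    value: 0.4
    provenance: supplementary_placeholder
    low: 0.32
    high: 0.48
  tablets_per_day_keto:
    value: 18.0
    provenance: paper
  monitoring_visit:
    value: 20.0
    provenance: supplementary_placeholder
    low: 16.0
    high: 24.0
  monitoring_interval_svlpd_months:
    value: 1.0
    provenance: paper
  monitoring_interval_lpd_months:
    value: 2.0
    provenance: paper
  tariff_hd_monthly:
    value: 1600.0
    provenance: supplementary_placeholder
    low: 1280.0
    high: 1920.0
  tariff_capd_monthly:
    value: 1200.0
    provenance: supplementary_placeholder
    low: 960.0
    high: 1440.0
  tariff_apd_monthly:
    value: 1200.0
    provenance: supplementary_placeholder
    low: 960.0
    high: 1440.0
  pd_catheter_placement:
    value: 1500.0
    provenance: supplementary_placeholder
    low: 1200.0
    high: 1800.0
  pd_annual_maintenance:
    value: 500.0
    provenance: supplementary_placeholder
    low: 400.0
    high: 600.0
  price_bicarbonate:
    value: 0.05
    provenance: supplementary_placeholder
    low: 0.04
    high: 0.06
  price_vitamin_d:
    value: 0.15
    provenance: supplementary_placeholder
    low: 0.12
    high: 0.18
  price_calcium:
    value: 0.1
    provenance: supplementary_placeholder
    low: 0.08
    high: 0.12
supplements:
  lpd:
    bicarbonate:
      usage:
        value: 0.51
        provenance: paper
      dose:
        value: 6.4
        provenance: paper
      period:
        value: day
        provenance: paper
    vitamin_d:
      usage:
        value: 0.54
        provenance: paper
      dose:
        value: 1.0
        provenance: paper
      period:
        value: week
        provenance: paper
    calcium:
      usage:
        value: 0.5
        provenance: paper
      dose:
        value: 6.9
        provenance: paper
      period:
        value: day
        provenance: paper
  svlpd:
    bicarbonate:
      usage:
        value: 0.29
        provenance: paper
      dose:
        value: 4.4
        provenance: paper
      period:
        value: day
        provenance: paper
    vitamin_d:
      usage:
        value: 0.22
        provenance: paper
      dose:
        value: 1.0
        provenance: paper
      period:
        value: week
        provenance: paper
    calcium:
      usage:
        value: 0.5
        provenance: paper
      dose:
        value: 6.3
        provenance: paper
      period:
        value: day
        provenance: paper
utilities:
  u_pre:
    value: 0.8
    provenance: supplementary_placeholder
    low: 0.7
    high: 0.9
  u_hd:
    value: 0.58
    provenance: supplementary_placeholder
    low: 0.5
    high: 0.66
  u_capd:
    value: 0.62
    provenance: supplementary_placeholder
    low: 0.54
    high: 0.7
  u_apd:
    value: 0.64
    provenance: supplementary_placeholder
    low: 0.56
    high: 0.72
indirect:
  work_value:
    value:
    - gender: male
      age_min: 0.0
      age_max: 65.0
      value: 1800.0
    - gender: male
      age_min: 65.0
      age_max: 75.0
      value: 1100.0
    - gender: male
      age_min: 75.0
      age_max: 200.0
      value: 700.0
    - gender: female
      age_min: 0.0
      age_max: 65.0
      value: 1500.0
    - gender: female
      age_min: 65.0
      age_max: 75.0
      value: 1000.0
    - gender: female
      age_min: 75.0
      age_max: 200.0
      value: 650.0
    provenance: supplementary_placeholder
    table: yes
  time_lost_hd:
    value: 0.5
    provenance: paper
  time_lost_capd:
    value: 0.3
    provenance: paper
  time_lost_apd:
    value: 0.2
    provenance: paper
  caregiver_need_fraction:
    value: 0.245
    provenance: paper
  caregiver_hours_week_hd:
    value: 12.0
    provenance: paper
  caregiver_hours_week_pd:
    value: 2.0
    provenance: paper
  caregiver_employed_fraction:
    value: 0.633
    provenance: paper
  caregiver_fraction_male:
    value: 0.58
    provenance: paper
  caregiver_age:
    value: 51.700000000000003
    provenance: paper
  reference_weekly_hours:
    value: 40.0
    provenance: assumption
settings:
  cycle_length_months:
    value: 1.0
    provenance: paper
  discount_rate_annual:
    value: 0.03
    provenance: paper
  horizon_max_cycles:
    value: 1440.0
    provenance: assumption
  stop_threshold_alive:
    value: 0.0001
    provenance: assumption
  half_cycle_correction:
    value: yes
    provenance: assumption
  perspective:
    value: nhs
    provenance: assumption
  discount_life_years:
    value: no
    provenance: assumption
adherence:
  switch_fraction:
    value: 0.42
    provenance: paper
  switch_window_months:
    value: 6.0
    provenance: paper

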