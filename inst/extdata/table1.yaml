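# Model parameter registry: pediatric brain-MRI sedation in Japan.
# All money in 2024 USD (converted at 1 JPY = 0.0065 USD).
# Gamma spreads: sd = (high - low)/(2 * 1.96) when a one-way range exists,
# else sd = default_cv * mean.
settings:
  exchange_rate_usd_per_jpy: 0.0065
  discount_rate: 0.0
  default_cv: 0.2
parameters:
  # --- procedure fees ---
  - name: fee_iv_sedation_nonanesth
    label: IV sedation by non-anesthesiologists
    unit: USD
    currency: USD
    value: 39.00
    distribution: gamma
    role: fee
  - name: fee_iv_sedation_anesth
    label: IV sedation by anesthesiologists
    unit: USD
    currency: USD
    value: 71.50
    low: 52.00
    high: 195.00
    distribution: gamma
    role: fee
  - name: fee_general_anesthesia
    label: General anesthesia
    unit: USD
    currency: USD
    value: 390.00
    distribution: gamma
    role: fee
  - name: fee_iv_infusion
    label: Peripheral IV infusion
    unit: USD
    currency: USD
    value: 6.83
    distribution: gamma
    role: fee
  - name: fee_mri
    label: MRI fee
    unit: USD
    currency: USD
    value: 105.30
    low: 58.50
    high: 105.30
    distribution: gamma
    role: fee
  # --- drug and apparatus prices ---
  - name: price_triclofos
    label: Triclofos sodium oral solution (100 mg/mL)
    unit: USD per mL
    currency: USD
    value: 0.066
    distribution: gamma
    role: drug_price
  - name: price_midazolam
    label: Midazolam vial (10 mg/2 mL)
    unit: USD per vial
    currency: USD
    value: 0.748
    low: 0.598
    high: 0.748
    distribution: gamma
    role: drug_price
  - name: price_dexmedetomidine
    label: Dexmedetomidine vial (200 ug/2 mL)
    unit: USD per vial
    currency: USD
    value: 17.303
    low: 7.514
    high: 17.303
    distribution: gamma
    role: drug_price
  - name: price_propofol
    label: Propofol vial (200 mg/20 mL)
    unit: USD per vial
    currency: USD
    value: 4.888
    low: 3.861
    high: 4.888
    distribution: gamma
    role: drug_price
  # Price per mL taken from the published worked example (24.75 mL x 0.177 $/mL
  # = 4.381 $); the table's per-mL figure is inconsistent with that arithmetic.
  - name: price_sevoflurane_ml
    label: Sevoflurane liquid
    unit: USD per mL
    currency: USD
    value: 0.177
    distribution: gamma
    role: drug_price
  - name: price_iv_fluid
    label: IV fluid bag (500 mL)
    unit: USD per bag
    currency: USD
    value: 1.378
    distribution: gamma
    role: drug_price
  - name: price_airway_device
    label: Supraglottic airway device (i-gel)
    unit: USD
    currency: USD
    value: 4.004
    distribution: gamma
    role: drug_price
  # --- dosing regimens ---
  - name: dose_triclofos
    label: Triclofos sodium oral dose
    unit: mg/kg
    value: 60
    low: 30
    high: 105
    distribution: gamma
    role: dose
  - name: dose_midazolam_load
    label: Midazolam loading dose
    unit: mg/kg
    value: 0.2
    low: 0.1
    high: 0.2
    distribution: gamma
    role: dose
  - name: dose_midazolam_maint
    label: Midazolam maintenance rate
    unit: mg/kg/h
    value: 0.36
    low: 0.18
    high: 0.36
    distribution: gamma
    role: dose
  - name: dose_dexmedetomidine_load
    label: Dexmedetomidine loading dose
    unit: ug/kg
    value: 2.8
    low: 2.3
    high: 3.3
    distribution: gamma
    role: dose
  - name: dose_dexmedetomidine_maint
    label: Dexmedetomidine maintenance rate
    unit: ug/kg/h
    value: 1.8
    low: 1.4
    high: 2.2
    distribution: gamma
    role: dose
  - name: dose_propofol_load
    label: Propofol loading dose
    unit: mg/kg
    value: 2.0
    low: 1.0
    high: 2.0
    distribution: gamma
    role: dose
  - name: dose_propofol_maint
    label: Propofol maintenance rate
    unit: mg/kg/h
    value: 6.0
    low: 6.0
    high: 12.0
    distribution: gamma
    role: dose
  # --- patient profile ---
  - name: mri_duration_min
    label: Brain MRI duration
    unit: minutes
    value: 38.0
    sd: 14.0
    low: 24.0
    high: 52.0
    floor: 5.0
    distribution: normal
    role: duration
  - name: weight_kg
    label: Body weight, 3-year-old male
    unit: kg
    value: 13.5
    sd: 1.53
    low: 11.97
    high: 15.03
    floor: 5.0
    distribution: normal
    role: weight
  # --- first-attempt sedation success rates (pooled) ---
  - name: p_triclofos
    label: Success rate, oral triclofos sodium (non-anesthesiologist)
    unit: probability
    value: 0.940
    ci_low: 0.910
    ci_high: 0.960
    distribution: beta
    role: probability
  - name: p_midazolam
    label: Success rate, IV midazolam (non-anesthesiologist)
    unit: probability
    value: 0.792
    ci_low: 0.206
    ci_high: 0.982
    distribution: beta
    role: probability
  # The published CI (0.946-0.964) does not bracket the published mean 0.933;
  # the CI width is retained, recentred on the mean.
  - name: p_dexmedetomidine
    label: Success rate, IV dexmedetomidine (non-anesthesiologist)
    unit: probability
    value: 0.933
    ci_low: 0.924
    ci_high: 0.942
    distribution: beta
    role: probability
  - name: p_propofol
    label: Success rate, IV propofol (anesthesiologist)
    unit: probability
    value: 0.983
    ci_low: 0.974
    ci_high: 0.993
    distribution: beta
    role: probability
  - name: p_general_anesthesia
    label: Success rate, general anesthesia (anesthesiologist)
    unit: probability
    value: 1.000
    distribution: beta
    role: probability
  # --- pediatric outpatient consultation (opportunity cost on failure) ---
  - name: fee_consultation
    label: Pediatric outpatient consultation fee per patient
    unit: USD
    currency: USD
    value: 46.800
    low: 26.650
    high: 46.800
    distribution: gamma
    role: fee
  - name: visits_per_hour
    label: Outpatient visits per hour
    unit: per hour
    value: 2.5
    low: 2.5
    high: 2.8
    distribution: gamma
    role: rate
  # --- general-anesthesia circuit settings (worked-example values) ---
  - name: sevo_concentration_pct
    label: Sevoflurane concentration
    unit: percent
    value: 2.5
    distribution: fixed
    role: other
  - name: sevo_flow_lpm
    label: Fresh gas flow
    unit: L/min
    value: 3.0
    distribution: fixed
    role: other
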