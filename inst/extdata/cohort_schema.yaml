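schema_version: '1.0'
columns:
  subject_id:
    kind: character
  source_ref:
    kind: character
  diagnosis:
    kind: character
    values:
    - EA1
    - EA2
  sex:
    kind: character
    values:
    - female
    - male
  age_onset:
    kind: numeric
    unit: years
  age_at_report:
    kind: numeric
    unit: years
  attack_duration_minutes:
    kind: numeric
    unit: minutes
  attack_frequency_per_month:
    kind: numeric
    unit: attacks per 30-day month
  duration_category:
    kind: character
    values:
    - brief
    - intermediate
    - prolonged
    - protracted
  frequency_category:
    kind: character
    values:
    - rare_sporadic
    - monthly
    - weekly
    - daily
  trigger_data_available:
    kind: logical
  trigger_any_reported:
    kind: tristate
  trigger_kinesigenic:
    kind: tristate
  trigger_exercise_induced:
    kind: tristate
  trigger_non_kinesigenic:
    kind: tristate
  trigger_alcohol:
    kind: tristate
  trigger_tobacco:
    kind: tristate
  trigger_sleep_deprivation:
    kind: tristate
  trigger_physiological_stress:
    kind: tristate
  trigger_fatigue:
    kind: tristate
  trigger_fasting:
    kind: tristate
  trigger_caffeine:
    kind: tristate
  trigger_startle:
    kind: tristate
  trigger_heat:
    kind: tristate
  trigger_anxiety:
    kind: tristate
  trigger_menstruation:
    kind: tristate
  trigger_excitement:
    kind: tristate
  trigger_emotional_stress:
    kind: tristate
  trigger_other:
    kind: tristate
  ictal_limb_ataxia:
    kind: tristate
  ictal_axial_ataxia:
    kind: tristate
  ictal_rigidity:
    kind: tristate
  ictal_myokymia:
    kind: tristate
  ictal_vertigo:
    kind: tristate
  ictal_headache:
    kind: tristate
  ictal_gi_symptoms:
    kind: tristate
  ictal_autonomic:
    kind: tristate
  ictal_aura:
    kind: tristate
  ictal_fatigue:
    kind: tristate
  interictal_ataxia:
    kind: tristate
  interictal_nystagmus:
    kind: tristate
  interictal_clinical_myokymia:
    kind: tristate
  interictal_neuromyotonia:
    kind: tristate
  interictal_emg_myokymia:
    kind: tristate
  interictal_peripheral_other:
    kind: tristate
  interictal_tremor:
    kind: tristate
  interictal_headache:
    kind: tristate
  progressive_ataxia:
    kind: tristate
  cerebellar_atrophy:
    kind: tristate
  drug_acetazolamide:
    kind: drug
    values:
    - complete
    - partial
    - none
  drug_aminopyridine_4:
    kind: drug
    values:
    - complete
    - partial
    - none
  drug_phenytoin:
    kind: drug
    values:
    - complete
    - partial
    - none
  drug_carbamazepine:
    kind: drug
    values:
    - complete
    - partial
    - none
  drug_valproic_acid:
    kind: drug
    values:
    - complete
    - partial
    - none
  drug_topiramate:
    kind: drug
    values:
    - complete
    - partial
    - none
  drug_flunarizine:
    kind: drug
    values:
    - complete
    - partial
    - none
  drug_pyridostigmine:
    kind: drug
    values:
    - complete
    - partial
    - none
  variant_gene:
    kind: character
    values:
    - KCNA1
    - CACNA1A
  variant_transcript:
    kind: character
  variant_hgvs_c:
    kind: character
  variant_hgvs_p:
    kind: character
  variant_effect:
    kind: character
    values:
    - missense
    - nonsense
    - frameshift
    - splice
    - inframe_deletion
    - outofframe_deletion
    - other
    - repeat_expansion
  variant_acmg:
    kind: character
    values:
    - pathogenic
    - likely_pathogenic
    - vus
    - likely_benign
    - benign
    - unmappable
  variant_nmd_predicted:
    kind: tristate
  variant_functional_study:
    kind: character
    values:
    - decreased_function
    - increased_function
    - none
  variant_dominant_negative:
    kind: logical
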