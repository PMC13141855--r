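# Column registry and closed enumerations for the cohort table.
#
# A cohort is a tibble with one row per published subject. Symptom, trigger
# and sign columns are tri-state: 1 = present, 0 = absent, NA = unknown
# ("unknown" never counts as absent; it drops the case from that feature's
# denominator).

DIAGNOSES <- c("EA1", "EA2")
SEXES <- c("female", "male")

DURATION_LEVELS <- c("brief", "intermediate", "prolonged", "protracted")
FREQUENCY_LEVELS <- c("rare_sporadic", "monthly", "weekly", "daily") # low -> high

TRIGGER_FEATURES <- paste0("trigger_", c(
  "any_reported", "kinesigenic", "exercise_induced", "non_kinesigenic",
  "alcohol", "tobacco", "sleep_deprivation", "physiological_stress",
  "fatigue", "fasting", "caffeine", "startle", "heat", "anxiety",
  "menstruation", "excitement", "emotional_stress", "other"
))

ICTAL_FEATURES <- paste0("ictal_", c(
  "limb_ataxia", "axial_ataxia", "rigidity", "myokymia", "vertigo",
  "headache", "gi_symptoms", "autonomic", "aura", "fatigue"
))

INTERICTAL_FEATURES <- paste0("interictal_", c(
  "ataxia", "nystagmus", "clinical_myokymia", "neuromyotonia",
  "emg_myokymia", "peripheral_other", "tremor", "headache"
))

# components of the composite interictal peripheral-muscular feature
PERIPHERAL_COMPONENTS <- c(
  "interictal_clinical_myokymia", "interictal_neuromyotonia",
  "interictal_emg_myokymia", "interictal_peripheral_other"
)

OTHER_TRISTATE <- c("progressive_ataxia", "cerebellar_atrophy")

DRUGS <- paste0("drug_", c(
  "acetazolamide", "aminopyridine_4", "phenytoin", "carbamazepine",
  "valproic_acid", "topiramate", "flunarizine", "pyridostigmine"
))
DRUG_LEVELS <- c("complete", "partial", "none")

GENES <- c("KCNA1", "CACNA1A")
VARIANT_EFFECTS <- c(
  "missense", "nonsense", "frameshift", "splice", "inframe_deletion",
  "outofframe_deletion", "other", "repeat_expansion"
)
ACMG_CLASSES <- c(
  "pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign",
  "unmappable"
)
FUNCTIONAL_STUDIES <- c("decreased_function", "increased_function", "none")
TRUNCATING_EFFECTS <- c("nonsense", "frameshift", "outofframe_deletion", "splice")

VARIANT_COLUMNS <- c(
  "variant_gene", "variant_transcript", "variant_hgvs_c", "variant_hgvs_p",
  "variant_effect", "variant_acmg", "variant_nmd_predicted",
  "variant_functional_study", "variant_dominant_negative"
)

TRISTATE_COLUMNS <- c(TRIGGER_FEATURES, ICTAL_FEATURES, INTERICTAL_FEATURES,
                      OTHER_TRISTATE, "variant_nmd_predicted")

cohort_columns <- function() {
  c("subject_id", "source_ref", "diagnosis", "sex", "age_onset",
    "age_at_report", "attack_duration_minutes", "attack_frequency_per_month",
    "duration_category", "frequency_category", "trigger_data_available",
    TRIGGER_FEATURES, ICTAL_FEATURES, INTERICTAL_FEATURES, OTHER_TRISTATE,
    DRUGS, VARIANT_COLUMNS)
}

column_kind <- function(col) {
  if (col %in% TRISTATE_COLUMNS) return("tristate")
  if (col %in% DRUGS) return("drug")
  if (col %in% c("age_onset", "age_at_report", "attack_duration_minutes",
                 "attack_frequency_per_month")) return("numeric")
  if (col %in% c("trigger_data_available", "variant_dominant_negative")) return("logical")
  "character"
}

#' Cohort file schema
#'
#' Returns the machine-readable schema for the flat cohort table: one entry
#' per column with its kind (tri-state, numeric, logical, enumerated string),
#' admissible values, and units. The same schema is shipped as a YAML
#' descriptor in `inst/extdata/cohort_schema.yaml`.
#'
#' Units: `attack_duration_minutes` is in minutes (a reported range is
#' collapsed to its maximum beforehand, see [collapse_range()]);
#' `attack_frequency_per_month` uses a 30-day month and 7-day week.
#'
#' @return A named list describing every cohort column.
#' @export
ea_schema <- function() {
  cols <- cohort_columns()
  spec <- lapply(cols, function(col) {
    kind <- column_kind(col)
    values <- switch(col,
      diagnosis = DIAGNOSES,
      sex = SEXES,
      duration_category = DURATION_LEVELS,
      frequency_category = FREQUENCY_LEVELS,
      variant_gene = GENES,
      variant_effect = VARIANT_EFFECTS,
      variant_acmg = ACMG_CLASSES,
      variant_functional_study = FUNCTIONAL_STUDIES,
      NULL
    )
    if (kind == "drug") values <- DRUG_LEVELS
    out <- list(kind = kind)
    if (!is.null(values)) out$values <- values
    if (col == "attack_duration_minutes") out$unit <- "minutes"
    if (col == "attack_frequency_per_month") out$unit <- "attacks per 30-day month"
    if (col %in% c("age_onset", "age_at_report")) out$unit <- "years"
    out
  })
  names(spec) <- cols
  list(schema_version = "1.0", columns = spec)
}
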