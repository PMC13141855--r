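# Random case-record generator for serialisation round-trip and invariance
# properties. Raw numerics are rounded so the CSV round trip is exact.
random_cases <- function(n, seed) {
  set.seed(seed)
  tri <- function(n) sample(c(1L, 0L, NA_integer_), n, replace = TRUE)
  x <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    source_ref = sample(c("paperA", "paperB", NA), n, replace = TRUE),
    diagnosis = sample(c("EA1", "EA2", NA), n, replace = TRUE),
    sex = sample(c("female", "male", NA), n, replace = TRUE),
    age_onset = round(stats::rlnorm(n, log(8), 0.7), 3),
    attack_duration_minutes = ifelse(runif(n) < 0.3, NA,
                                     round(stats::rlnorm(n, log(30), 1.5), 3)),
    attack_frequency_per_month = ifelse(runif(n) < 0.3, NA,
                                        round(stats::rlnorm(n, log(4), 1), 3)),
    trigger_data_available = runif(n) < 0.7
  )
  x$age_at_report <- round(x$age_onset + runif(n, 0, 50), 3)
  for (col in c(eadiag:::TRIGGER_FEATURES, eadiag:::ICTAL_FEATURES,
                eadiag:::INTERICTAL_FEATURES, "progressive_ataxia",
                "cerebellar_atrophy")) {
    v <- tri(n)
    if (col %in% eadiag:::TRIGGER_FEATURES) v[!x$trigger_data_available] <- NA
    x[[col]] <- v
  }
  x$drug_acetazolamide <- sample(c("complete", "partial", "none", NA), n,
                                 replace = TRUE)
  has_var <- runif(n) < 0.8
  x$variant_gene <- ifelse(has_var, sample(c("KCNA1", "CACNA1A"), n, TRUE), NA)
  x$variant_transcript <- ifelse(has_var, "NM_000000.0", NA)
  x$variant_hgvs_c <- ifelse(has_var, sprintf("c.%dA>G", seq_len(n)), NA)
  x$variant_effect <- ifelse(has_var,
                             sample(eadiag:::VARIANT_EFFECTS, n, TRUE), NA)
  x$variant_acmg <- ifelse(has_var, sample(eadiag:::ACMG_CLASSES, n, TRUE), NA)
  x$variant_nmd_predicted <- ifelse(has_var, tri(n), NA_integer_)
  x$variant_functional_study <- ifelse(has_var,
                                       sample(eadiag:::FUNCTIONAL_STUDIES, n, TRUE),
                                       NA)
  x$variant_dominant_negative <- has_var & runif(n) < 0.2
  x
}

random_cohort <- function(n, seed) cohort(random_cases(n, seed), label = "prop")

# published accuracy table rows (variable, gene, sensitivity %, specificity %,
# AUC, CI, p) used as the known input to feature selection
published_accuracy_rows <- function() {
  tibble::tribble(
    ~feature, ~target_gene, ~sensitivity, ~specificity, ~auc, ~ci_low, ~ci_high, ~p_value,
    "trigger_kinesigenic", "KCNA1", .684, .947, .815, .748, .883, 1e-4,
    "trigger_startle", "KCNA1", .494, 1, .747, .669, .824, 1e-4,
    "trigger_non_kinesigenic", "KCNA1", .899, .272, .585, .505, .666, .006,
    "trigger_physiological_stress", "KCNA1", .479, .791, .635, .551, .719, 1e-4,
    "trigger_anxiety", "KCNA1", .260, .921, .590, .506, .675, 1e-4,
    "brief_attacks", "KCNA1", .753, .940, .846, .787, .906, 1e-4,
    "daily_attacks", "KCNA1", .379, .841, .610, .525, .696, 1e-4,
    "ictal_limb_ataxia", "KCNA1", .489, .887, .688, .619, .757, 1e-4,
    "ictal_axial_ataxia", "KCNA1", .681, .588, .635, .568, .701, 1e-4,
    "ictal_rigidity", "KCNA1", .266, .995, .631, .558, .703, 1e-4,
    "ictal_myokymia", "KCNA1", .234, .995, .615, .542, .688, 1e-4,
    "ictal_vertigo", "CACNA1A", .632, .763, .698, .635, .760, 1e-4,
    "ictal_headache", "CACNA1A", .250, .957, .604, .540, .668, 1e-4,
    "ictal_gi_symptoms", "CACNA1A", .445, .915, .680, .620, .740, 1e-4,
    "interictal_ataxia", "CACNA1A", .431, .912, .672, .610, .733, 1e-4,
    "interictal_nystagmus", "CACNA1A", .634, .988, .811, .765, .856, 1e-4,
    "interictal_clinical_myokymia", "KCNA1", .400, .996, .698, .622, .774, 1e-4,
    "interictal_neuromyotonia", "KCNA1", .200, 1, .600, .523, .677, 1e-4,
    "interictal_emg_myokymia", "KCNA1", .481, 1, .741, .666, .815, 1e-4,
    "peripheral_muscular_interictal", "KCNA1", .825, .992, .908, .858, .958, 1e-4
  )
}
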