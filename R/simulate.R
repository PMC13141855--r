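#' Group specification for the cohort simulator
#'
#' Describes one diagnostic group as the marginal structure the analysis
#' assumes: independent group-conditional Bernoulli presence/absence per
#' binary feature, categorical attack duration/frequency, a log-normal age
#' of onset parameterised by median and IQR, and per-feature missingness.
#' Trigger features are sampled conditionally on trigger data being
#' available (`trigger_available_prob`); their `feature_missingness`
#' entries are conditional on availability, all others are unconditional.
#'
#' @param diagnosis `"EA1"` or `"EA2"`.
#' @param n Group size (non-negative integer).
#' @param feature_prevalence Named probabilities of presence per tri-state
#'   feature (among evaluable cases).
#' @param feature_missingness Named probabilities of unknown per feature
#'   (defaults to 0 for features not named).
#' @param trigger_available_prob Probability that a case has any trigger
#'   data.
#' @param duration_probs Probabilities over `brief`, `intermediate`,
#'   `prolonged`, `protracted` (in that order; must sum to 1).
#' @param frequency_probs Probabilities over `rare_sporadic`, `monthly`,
#'   `weekly`, `daily` (must sum to 1).
#' @param duration_missing,frequency_missing Missingness of the attack
#'   metrics.
#' @param age_onset_median,age_onset_iqr Median and `c(q1, q3)` of age of
#'   onset in years.
#' @param sex_female_prob Probability of female sex.
#' @param acetazolamide_eval_prob,acetazolamide_response_prob Probability
#'   that acetazolamide response is reported, and of response (complete or
#'   partial) given reported.
#' @param haplo_prob Probability the case's variant is a haploinsufficient
#'   (truncating, NMD-predicted) one; otherwise a missense variant is
#'   assigned, with a decreased-function study with probability
#'   `missense_lof_prob`.
#' @param missense_lof_prob See above.
#' @return A list of class `ea_group_spec`.
#' @export
group_spec <- function(diagnosis, n, feature_prevalence,
                       feature_missingness = numeric(0),
                       trigger_available_prob = 1,
                       duration_probs, frequency_probs,
                       duration_missing = 0, frequency_missing = 0,
                       age_onset_median, age_onset_iqr,
                       sex_female_prob = 0.5,
                       acetazolamide_eval_prob = 0,
                       acetazolamide_response_prob = 0,
                       haplo_prob = 0, missense_lof_prob = 1) {
  if (!diagnosis %in% DIAGNOSES) ea_stop("diagnosis must be EA1 or EA2")
  if (length(n) != 1 || is.na(n) || n < 0 || n != round(n)) {
    ea_stop("group size n must be a non-negative integer",
            class = "eadiag_validation_error")
  }
  probs <- c(feature_prevalence, feature_missingness,
             trigger_available_prob, duration_probs, frequency_probs,
             duration_missing, frequency_missing, sex_female_prob,
             acetazolamide_eval_prob, acetazolamide_response_prob,
             haplo_prob, missense_lof_prob)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    ea_stop("all probabilities must lie in [0, 1]",
            class = "eadiag_validation_error")
  }
  if (abs(sum(duration_probs) - 1) > 1e-9 ||
      abs(sum(frequency_probs) - 1) > 1e-9) {
    ea_stop("category probability vectors must sum to 1",
            class = "eadiag_validation_error")
  }
  bad <- setdiff(names(feature_prevalence), TRISTATE_COLUMNS)
  if (length(bad) > 0) {
    ea_stop("unknown feature(s) in prevalence map: %s",
            paste(bad, collapse = ", "), class = "eadiag_validation_error")
  }
  structure(list(
    diagnosis = diagnosis, n = as.integer(n),
    feature_prevalence = feature_prevalence,
    feature_missingness = feature_missingness,
    trigger_available_prob = trigger_available_prob,
    duration_probs = stats::setNames(duration_probs, DURATION_LEVELS),
    frequency_probs = stats::setNames(frequency_probs, FREQUENCY_LEVELS),
    duration_missing = duration_missing,
    frequency_missing = frequency_missing,
    age_onset_median = age_onset_median, age_onset_iqr = age_onset_iqr,
    sex_female_prob = sex_female_prob,
    acetazolamide_eval_prob = acetazolamide_eval_prob,
    acetazolamide_response_prob = acetazolamide_response_prob,
    haplo_prob = haplo_prob, missense_lof_prob = missense_lof_prob
  ), class = "ea_group_spec")
}

#' Cohort specification
#'
#' @param groups List of [group_spec()]s with distinct diagnoses.
#' @param seed Integer seed making generation reproducible.
#' @param label Cohort label.
#' @param correlation_plan Optional list of pairwise feature dependencies,
#'   each `list(source, target, agreement)`: with probability `agreement`
#'   the target feature copies the source's sampled value (before
#'   missingness); features are otherwise independent within group.
#' @return A list of class `ea_cohort_spec`.
#' @export
cohort_spec <- function(groups, seed = 1L, label = "synthetic",
                        correlation_plan = NULL) {
  if (!all(vapply(groups, inherits, TRUE, "ea_group_spec"))) {
    ea_stop("groups must be a list of group_spec objects",
            class = "eadiag_validation_error")
  }
  dx <- vapply(groups, function(g) g$diagnosis, "")
  if (anyDuplicated(dx)) {
    ea_stop("group diagnoses must be distinct", class = "eadiag_validation_error")
  }
  structure(list(groups = groups, seed = as.integer(seed), label = label,
                 correlation_plan = correlation_plan),
            class = "ea_cohort_spec")
}

# printed-count marginals of the curated core dataset
ea1_marginals <- function(n = 94, missingness = TRUE) {
  m <- function(x) if (missingness) x else 0
  group_spec(
    diagnosis = "EA1", n = n,
    feature_prevalence = c(
      trigger_any_reported = 79 / 79, trigger_kinesigenic = 54 / 79,
      trigger_non_kinesigenic = 71 / 79, trigger_startle = 38 / 77,
      trigger_physiological_stress = 35 / 73, trigger_caffeine = 11 / 77,
      trigger_anxiety = 20 / 77, trigger_menstruation = 6 / 77,
      trigger_heat = 2 / 77,
      ictal_limb_ataxia = 46 / 94, ictal_axial_ataxia = 64 / 94,
      ictal_rigidity = 25 / 94, ictal_myokymia = 22 / 94,
      ictal_vertigo = 22 / 93, ictal_headache = 4 / 94,
      ictal_gi_symptoms = 8 / 94,
      interictal_ataxia = 7 / 80, interictal_nystagmus = 1 / 80,
      interictal_clinical_myokymia = 32 / 80,
      interictal_neuromyotonia = 16 / 80,
      interictal_emg_myokymia = 38 / 79,
      interictal_peripheral_other = 28 / 80
    ),
    feature_missingness = c(
      trigger_startle = m(2 / 79), trigger_physiological_stress = m(6 / 79),
      trigger_caffeine = m(2 / 79), trigger_anxiety = m(2 / 79),
      trigger_menstruation = m(2 / 79), trigger_heat = m(2 / 79),
      ictal_vertigo = m(1 / 94),
      interictal_ataxia = m(14 / 94), interictal_nystagmus = m(14 / 94),
      interictal_clinical_myokymia = m(14 / 94),
      interictal_neuromyotonia = m(14 / 94),
      interictal_emg_myokymia = m(15 / 94),
      interictal_peripheral_other = m(14 / 94)
    ),
    trigger_available_prob = if (missingness) 79 / 94 else 1,
    duration_probs = c(61, 9, 9, 2) / 81,
    frequency_probs = c(9, 7, 25, 25) / 66,
    duration_missing = m(13 / 94), frequency_missing = m(28 / 94),
    age_onset_median = 7, age_onset_iqr = c(4, 10),
    sex_female_prob = 58 / 94,
    acetazolamide_eval_prob = if (missingness) 33 / 94 else 1,
    acetazolamide_response_prob = 17 / 33,
    haplo_prob = 0, missense_lof_prob = 1
  )
}

ea2_marginals <- function(n = 276, missingness = TRUE) {
  m <- function(x) if (missingness) x else 0
  group_spec(
    diagnosis = "EA2", n = n,
    feature_prevalence = c(
      trigger_any_reported = 104 / 114, trigger_kinesigenic = 6 / 114,
      trigger_non_kinesigenic = 83 / 114, trigger_startle = 0,
      trigger_physiological_stress = 23 / 110, trigger_caffeine = 5 / 114,
      trigger_anxiety = 9 / 114, trigger_menstruation = 0,
      trigger_heat = 14 / 114,
      ictal_limb_ataxia = 25 / 221, ictal_axial_ataxia = 91 / 221,
      ictal_rigidity = 1 / 220, ictal_myokymia = 1 / 220,
      ictal_vertigo = 139 / 220, ictal_headache = 55 / 220,
      ictal_gi_symptoms = 98 / 220,
      interictal_ataxia = 106 / 246, interictal_nystagmus = 156 / 246,
      interictal_clinical_myokymia = 1 / 246,
      interictal_neuromyotonia = 0, interictal_emg_myokymia = 0,
      interictal_peripheral_other = 1 / 246
    ),
    feature_missingness = c(
      trigger_physiological_stress = m(4 / 114),
      ictal_limb_ataxia = m(55 / 276), ictal_axial_ataxia = m(55 / 276),
      ictal_rigidity = m(56 / 276), ictal_myokymia = m(56 / 276),
      ictal_vertigo = m(56 / 276), ictal_headache = m(56 / 276),
      ictal_gi_symptoms = m(56 / 276),
      interictal_ataxia = m(30 / 276), interictal_nystagmus = m(30 / 276),
      interictal_clinical_myokymia = m(30 / 276),
      interictal_neuromyotonia = m(30 / 276),
      interictal_emg_myokymia = m(30 / 276),
      interictal_peripheral_other = m(30 / 276)
    ),
    trigger_available_prob = if (missingness) 114 / 276 else 1,
    duration_probs = c(11, 33, 119, 20) / 183,
    frequency_probs = c(10, 34, 72, 22) / 138,
    duration_missing = m(93 / 276), frequency_missing = m(138 / 276),
    age_onset_median = 10, age_onset_iqr = c(5, 15),
    sex_female_prob = 111 / 276,
    acetazolamide_eval_prob = if (missingness) 162 / 276 else 1,
    acetazolamide_response_prob = 139 / 162,
    haplo_prob = 168 / 276, missense_lof_prob = 86 / 108
  )
}

#' Default cohort specification at the published core marginals
#'
#' Group sizes 94 (EA1) and 276 (EA2), feature prevalences and per-feature
#' missingness at the published core-dataset rates.
#'
#' @param n_ea1,n_ea2 Group sizes.
#' @param missingness Apply the published missing-data rates (`FALSE` gives
#'   fully observed cases, the operating-point condition used for
#'   classifier stress tests).
#' @param seed,label Passed to [cohort_spec()].
#' @return An `ea_cohort_spec`.
#' @export
default_cohort_spec <- function(n_ea1 = 94, n_ea2 = 276, missingness = TRUE,
                                seed = 1L, label = "synthetic-core") {
  cohort_spec(list(ea1_marginals(n_ea1, missingness),
                   ea2_marginals(n_ea2, missingness)),
              seed = seed, label = label)
}

sample_tristate <- function(n, p, miss) {
  v <- stats::rbinom(n, 1L, p)
  if (miss > 0) v[stats::runif(n) < miss] <- NA_integer_
  as.integer(v)
}

# raw-value intervals kept clear of the category boundaries so that a
# rounded sampled value always bins back into its drawn category
duration_interval <- function(cat) {
  switch(cat, brief = c(1, 10), intermediate = c(11, 60),
         prolonged = c(61, 1439), protracted = c(1440, 10080))
}
frequency_interval <- function(cat) {
  switch(cat, rare_sporadic = c(0.1, 0.9), monthly = c(1, 4.2),
         weekly = c(4.3, 29.9), daily = c(30, 90))
}

generate_group <- function(g, offset) {
  n <- g$n
  if (n == 0) return(NULL)
  x <- tibble::tibble(
    subject_id = sprintf("%s-SIM-%04d", g$diagnosis, offset + seq_len(n)),
    source_ref = "synthetic",
    diagnosis = g$diagnosis,
    sex = ifelse(stats::runif(n) < g$sex_female_prob, "female", "male")
  )
  x$age_onset <- round(stats::rlnorm(
    n, meanlog = log(g$age_onset_median),
    sdlog = lognormal_sdlog(g$age_onset_iqr[1], g$age_onset_iqr[2])), 2)
  x$age_at_report <- round(x$age_onset + stats::runif(n, 5, 40), 2)
  dur_cat <- sample(DURATION_LEVELS, n, replace = TRUE, prob = g$duration_probs)
  dur <- vapply(dur_cat, function(cat) {
    iv <- duration_interval(cat)
    round(stats::runif(1, iv[1], iv[2]), 1)
  }, 0)
  dur[stats::runif(n) < g$duration_missing] <- NA
  x$attack_duration_minutes <- dur
  freq_cat <- sample(FREQUENCY_LEVELS, n, replace = TRUE,
                     prob = g$frequency_probs)
  freq <- vapply(freq_cat, function(cat) {
    iv <- frequency_interval(cat)
    round(stats::runif(1, iv[1], iv[2]), 2)
  }, 0)
  freq[stats::runif(n) < g$frequency_missing] <- NA
  x$attack_frequency_per_month <- freq
  x$trigger_data_available <- stats::runif(n) < g$trigger_available_prob
  for (feat in names(g$feature_prevalence)) {
    p <- g$feature_prevalence[[feat]]
    miss <- g$feature_missingness[feat]
    miss <- if (is.na(miss)) 0 else miss
    v <- sample_tristate(n, p, miss)
    if (feat %in% TRIGGER_FEATURES) v[!x$trigger_data_available] <- NA_integer_
    x[[feat]] <- v
  }
  if (g$acetazolamide_eval_prob > 0) {
    evaluable <- stats::runif(n) < g$acetazolamide_eval_prob
    resp <- ifelse(stats::runif(n) < g$acetazolamide_response_prob,
                   "complete", "none")
    x$drug_acetazolamide <- ifelse(evaluable, resp, NA_character_)
  }
  gene <- if (g$diagnosis == "EA1") "KCNA1" else "CACNA1A"
  haplo <- stats::runif(n) < g$haplo_prob
  lof_ms <- stats::runif(n) < g$missense_lof_prob
  x$variant_gene <- gene
  x$variant_transcript <- if (gene == "KCNA1") "NM_000217.3" else "NM_001127221.2"
  x$variant_hgvs_c <- sprintf("c.%dN>N", offset + seq_len(n))
  x$variant_effect <- ifelse(haplo, "nonsense", "missense")
  x$variant_acmg <- "pathogenic"
  x$variant_nmd_predicted <- ifelse(haplo, 1L, NA_integer_)
  x$variant_functional_study <- ifelse(haplo, "none",
                                       ifelse(lof_ms, "decreased_function",
                                              "none"))
  x
}

apply_correlation_plan <- function(df, plan) {
  for (dep in plan) {
    src <- df[[dep$source]]
    tgt <- df[[dep$target]]
    copy <- stats::runif(nrow(df)) < dep$agreement & !is.na(src) & !is.na(tgt)
    tgt[copy] <- src[copy]
    df[[dep$target]] <- tgt
  }
  df
}

#' Generate a labeled synthetic cohort
#'
#' Samples cases group by group per the specification: independent
#' Bernoulli binary features (unless a `correlation_plan` links them),
#' categorical duration/frequency with a raw value drawn uniformly inside
#' the drawn category's interval (protracted capped at 7 days), log-normal
#' age of onset moment-matched to the stated median and IQR on the log
#' scale, and missingness applied after sampling. Output is identical for
#' identical spec and seed.
#'
#' @param spec An `ea_cohort_spec`.
#' @param seed Overrides `spec$seed` when given.
#' @return An `ea_cohort`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ea_cohort_spec"))
  set.seed(seed %||% spec$seed)
  parts <- list()
  offset <- 0
  for (g in spec$groups) {
    part <- generate_group(g, offset)
    if (!is.null(part)) {
      if (!is.null(spec$correlation_plan)) {
        part <- apply_correlation_plan(part, spec$correlation_plan)
      }
      parts[[length(parts) + 1]] <- part
    }
    offset <- offset + g$n
  }
  if (length(parts) == 0) {
    return(cohort(tibble::tibble(subject_id = character(0)),
                  label = spec$label))
  }
  all_cols <- Reduce(union, lapply(parts, names))
  parts <- lapply(parts, function(p) {
    for (col in setdiff(all_cols, names(p))) p[[col]] <- NA
    p[, all_cols]
  })
  cohort(do.call(rbind, parts), label = spec$label)
}

#' Recover empirical group parameters from a labeled cohort
#'
#' The inverse harness of [generate_cohort()]: per diagnostic group,
#' empirical feature prevalences (share present among evaluable cases),
#' per-feature missingness, trigger-data availability, duration/frequency
#' category proportions (among evaluable), acetazolamide evaluability and
#' response rate, sex ratio, and the median/IQR of age of onset.
#'
#' @param x A labeled `ea_cohort`.
#' @return A named list (one entry per diagnosis present) of parameter
#'   lists; empty groups are flagged with a warning and omitted.
#' @export
recover_parameters <- function(x) {
  stopifnot(inherits(x, "ea_cohort"))
  fm <- build_feature_matrix(x)
  out <- list()
  for (dx in DIAGNOSES) {
    sel <- !is.na(x$diagnosis) & x$diagnosis == dx
    if (!any(sel)) {
      ea_warn("group %s is empty", dx)
      next
    }
    sub <- x[sel, , drop = FALSE]
    fsub <- fm[sel, , drop = FALSE]
    prev <- vapply(c(TRIGGER_FEATURES, ICTAL_FEATURES, INTERICTAL_FEATURES,
                     OTHER_TRISTATE), function(col) {
      v <- sub[[col]]
      if (all(is.na(v))) NA_real_ else mean(v == 1L, na.rm = TRUE)
    }, 0)
    missingness <- vapply(names(prev), function(col) mean(is.na(sub[[col]])), 0)
    dur <- fsub$duration_category
    freq <- fsub$frequency_category
    dur_p <- if (all(is.na(dur))) rep(NA_real_, 4) else
      vapply(DURATION_LEVELS, function(l) mean(dur[!is.na(dur)] == l), 0)
    freq_p <- if (all(is.na(freq))) rep(NA_real_, 4) else
      vapply(FREQUENCY_LEVELS, function(l) mean(freq[!is.na(freq)] == l), 0)
    ages <- sub$age_onset[!is.na(sub$age_onset)]
    acet <- sub$drug_acetazolamide
    out[[dx]] <- list(
      n = nrow(sub),
      sex_female_prob = mean(sub$sex == "female", na.rm = TRUE),
      trigger_available_prob = mean(sub$trigger_data_available),
      feature_prevalence = prev,
      feature_missingness = missingness,
      duration_probs = stats::setNames(dur_p, DURATION_LEVELS),
      frequency_probs = stats::setNames(freq_p, FREQUENCY_LEVELS),
      duration_missing = mean(is.na(fsub$duration_category)),
      frequency_missing = mean(is.na(fsub$frequency_category)),
      age_onset_median = if (length(ages)) stats::median(ages) else NA_real_,
      age_onset_iqr = if (length(ages)) unname(stats::quantile(ages, c(0.25, 0.75)))
                      else c(NA_real_, NA_real_),
      acetazolamide_eval_prob = mean(!is.na(acet)),
      acetazolamide_response_prob = if (any(!is.na(acet)))
        mean(acet[!is.na(acet)] %in% c("complete", "partial")) else NA_real_
    )
  }
  out
}
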