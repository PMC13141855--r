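#' Default feature-to-target-gene map
#'
#' The binary features analysed for diagnostic accuracy, each mapped to the
#' gene whose carriers it flags: trigger features, brief/daily attacks and
#' EA1-typical signs target KCNA1; vertigo, headache, GI symptoms and the
#' interictal cerebellar signs target CACNA1A.
#'
#' @return Named character vector `feature -> target gene`.
#' @export
default_feature_targets <- function() {
  c(trigger_kinesigenic = "KCNA1", trigger_startle = "KCNA1",
    trigger_non_kinesigenic = "KCNA1",
    trigger_physiological_stress = "KCNA1", trigger_anxiety = "KCNA1",
    brief_attacks = "KCNA1", daily_attacks = "KCNA1",
    ictal_limb_ataxia = "KCNA1", ictal_axial_ataxia = "KCNA1",
    ictal_rigidity = "KCNA1", ictal_myokymia = "KCNA1",
    ictal_vertigo = "CACNA1A", ictal_headache = "CACNA1A",
    ictal_gi_symptoms = "CACNA1A",
    interictal_ataxia = "CACNA1A", interictal_nystagmus = "CACNA1A",
    interictal_clinical_myokymia = "KCNA1",
    interictal_neuromyotonia = "KCNA1", interictal_emg_myokymia = "KCNA1",
    peripheral_muscular_interictal = "KCNA1")
}

#' Per-group demographic and attack-metric summary
#'
#' Per diagnostic group: case count, female sex count and percent, age of
#' onset median/IQR/range, duration and frequency category counts and
#' percents (complete-case), and missing-data counts; plus group-comparison
#' p-values (sex via the 2x2 association test, age of onset via
#' [compare_continuous()], each category via its own 2x2 test).
#'
#' @param x A labeled `ea_cohort`.
#' @return A list of class `ea_cohort_summary` with elements `groups`
#'   (tibble of descriptives) and `tests` (tibble of comparisons, empty for
#'   a single-group cohort).
#' @export
cohort_summary <- function(x) {
  stopifnot(inherits(x, "ea_cohort"))
  if (nrow(x) == 0) ea_stop("empty cohort")
  labeled <- !is.na(x$diagnosis)
  if (!any(labeled)) ea_stop("cohort has no labeled cases")
  x <- x[labeled, , drop = FALSE]
  class(x) <- c("ea_cohort", class(tibble::tibble()))
  fm <- build_feature_matrix(x)
  present <- DIAGNOSES[DIAGNOSES %in% x$diagnosis]
  groups <- do.call(rbind, lapply(present, function(dx) {
    sel <- x$diagnosis == dx
    ages <- x$age_onset[sel & !is.na(x$age_onset)]
    dur <- fm$duration_category[sel]
    freq <- fm$frequency_category[sel]
    row <- tibble::tibble(
      diagnosis = dx, n = sum(sel),
      female = sum(x$sex[sel] == "female", na.rm = TRUE),
      female_pct = as_pct(mean(x$sex[sel] == "female", na.rm = TRUE)),
      age_onset_median = stats::median(ages),
      age_onset_q1 = unname(stats::quantile(ages, 0.25)),
      age_onset_q3 = unname(stats::quantile(ages, 0.75)),
      age_onset_min = min(ages), age_onset_max = max(ages),
      duration_missing = sum(is.na(dur)),
      frequency_missing = sum(is.na(freq))
    )
    for (lev in DURATION_LEVELS) {
      row[[paste0("duration_", lev)]] <- sum(dur == lev, na.rm = TRUE)
      row[[paste0("duration_", lev, "_pct")]] <-
        as_pct(sum(dur == lev, na.rm = TRUE) / sum(!is.na(dur)))
    }
    for (lev in FREQUENCY_LEVELS) {
      row[[paste0("frequency_", lev)]] <- sum(freq == lev, na.rm = TRUE)
      row[[paste0("frequency_", lev, "_pct")]] <-
        as_pct(sum(freq == lev, na.rm = TRUE) / sum(!is.na(freq)))
    }
    row
  }))
  tests <- tibble::tibble(variable = character(0), p_value = numeric(0),
                          test_used = character(0))
  if (length(present) == 2) {
    ea1 <- x$diagnosis == "EA1"
    sex_tab <- contingency_2x2(
      tp = sum(x$sex[ea1] == "female", na.rm = TRUE),
      fn = sum(x$sex[ea1] == "male", na.rm = TRUE),
      fp = sum(x$sex[!ea1] == "female", na.rm = TRUE),
      tn = sum(x$sex[!ea1] == "male", na.rm = TRUE),
      feature = "female_sex", target_gene = "KCNA1")
    sex_test <- association_test(sex_tab)
    age_test <- compare_continuous(x$age_onset[ea1], x$age_onset[!ea1])
    rows <- list(
      tibble::tibble(variable = "female_sex", p_value = sex_test$p_value,
                     test_used = sex_test$test_used),
      tibble::tibble(variable = "age_onset", p_value = age_test$p_value,
                     test_used = age_test$test_used))
    for (lev in DURATION_LEVELS) {
      dur <- fm$duration_category
      known <- !is.na(dur)
      tab <- contingency_2x2(
        tp = sum(known & ea1 & dur == lev), fn = sum(known & ea1 & dur != lev),
        fp = sum(known & !ea1 & dur == lev), tn = sum(known & !ea1 & dur != lev),
        feature = paste0("duration_", lev), target_gene = "KCNA1")
      tst <- association_test(tab)
      rows[[length(rows) + 1]] <-
        tibble::tibble(variable = paste0("duration_", lev),
                       p_value = tst$p_value, test_used = tst$test_used)
    }
    for (lev in FREQUENCY_LEVELS) {
      freq <- fm$frequency_category
      known <- !is.na(freq)
      tab <- contingency_2x2(
        tp = sum(known & ea1 & freq == lev), fn = sum(known & ea1 & freq != lev),
        fp = sum(known & !ea1 & freq == lev), tn = sum(known & !ea1 & freq != lev),
        feature = paste0("frequency_", lev), target_gene = "KCNA1")
      tst <- association_test(tab)
      rows[[length(rows) + 1]] <-
        tibble::tibble(variable = paste0("frequency_", lev),
                       p_value = tst$p_value, test_used = tst$test_used)
    }
    tests <- do.call(rbind, rows)
  }
  structure(list(groups = groups, tests = tests),
            class = "ea_cohort_summary")
}

#' @export
print.ea_cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s: n=%d, female %d (%.1f%%), onset median %.1fy IQR [%.1f-%.1f]\n",
                g$diagnosis[i], g$n[i], g$female[i], g$female_pct[i],
                g$age_onset_median[i], g$age_onset_q1[i], g$age_onset_q3[i]))
    cat(sprintf("    duration b/i/p/pr: %d/%d/%d/%d (missing %d); frequency d/w/m/r: %d/%d/%d/%d (missing %d)\n",
                g$duration_brief[i], g$duration_intermediate[i],
                g$duration_prolonged[i], g$duration_protracted[i],
                g$duration_missing[i],
                g$frequency_daily[i], g$frequency_weekly[i],
                g$frequency_monthly[i], g$frequency_rare_sporadic[i],
                g$frequency_missing[i]))
  }
  if (nrow(x$tests) > 0) {
    cat("  group comparisons:\n")
    for (i in seq_len(nrow(x$tests))) {
      cat(sprintf("    %-22s p=%.4g (%s)\n", x$tests$variable[i],
                  x$tests$p_value[i], x$tests$test_used[i]))
    }
  }
  invisible(x)
}

#' Diagnostic-accuracy table over the standard feature set
#'
#' One row per analysed feature: target gene, N (evaluable cases),
#' sensitivity, specificity, accuracy, AUC with 95% CI, association
#' p-value and test. Features with no evaluable cases are omitted with a
#' warning.
#'
#' @param x A labeled `ea_cohort` or an `ea_feature_matrix`.
#' @param features Named character vector `feature -> target gene`
#'   (default [default_feature_targets()]).
#' @return A tibble, one row per feature, in the input feature order.
#' @export
accuracy_table <- function(x, features = default_feature_targets()) {
  fm <- if (inherits(x, "ea_feature_matrix")) x else build_feature_matrix(x)
  rows <- lapply(names(features), function(feat) {
    tryCatch(diagnostic_accuracy(fm, feat, features[[feat]]),
             eadiag_degenerate_error = function(e) {
               ea_warn("feature `%s` omitted: %s", feat, conditionMessage(e))
               NULL
             })
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Round an accuracy table for presentation
#'
#' Percentages half-up to one decimal, AUC and CI to three decimals,
#' matching the reporting conventions of the published table.
#'
#' @param tbl Output of [accuracy_table()].
#' @return A tibble with formatted columns.
#' @export
format_accuracy_table <- function(tbl) {
  tibble::tibble(
    feature = tbl$feature, target_gene = tbl$target_gene, n = tbl$n,
    sensitivity_pct = as_pct(tbl$sensitivity),
    specificity_pct = as_pct(tbl$specificity),
    auc = round_half_up(tbl$auc, 3),
    ci = sprintf("%.3f-%.3f", round_half_up(tbl$ci_low, 3),
                 round_half_up(tbl$ci_high, 3)),
    p_value = ifelse(tbl$p_value < 0.001, "<0.001",
                     sprintf("%.3f", round_half_up(tbl$p_value, 3))),
    test_used = tbl$test_used
  )
}

#' Generate a cohort and write it with provenance
#'
#' Writes `cohort.csv` and `provenance.json` (spec hash, seed, package
#' version) into `out_dir`.
#'
#' @param spec An `ea_cohort_spec`.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `spec$seed` when given.
#' @return Invisibly, the paths written.
#' @export
simulate_cohort <- function(spec, out_dir, seed = NULL) {
  stopifnot(inherits(spec, "ea_cohort_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- seed %||% spec$seed
  x <- generate_cohort(spec, seed = seed)
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort(x, cohort_path, format = "csv")
  spec_json <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA,
                                force = TRUE)
  prov <- list(
    spec_hash = sprintf("%08x", sum(utf8ToInt(as.character(spec_json)) *
                                      (seq_along(utf8ToInt(as.character(spec_json))) %% 97 + 1)) %% .Machine$integer.max),
    seed = seed,
    n_cases = nrow(x),
    package = "eadiag",
    version = as.character(utils::packageVersion("eadiag"))
  )
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(cohort = cohort_path, provenance = prov_path))
}
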