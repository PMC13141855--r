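test_that("generation is deterministic under a fixed seed", {
  spec <- default_cohort_spec(n_ea1 = 50, n_ea2 = 50, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- generate_cohort(spec, seed = 10)
  expect_false(identical(as.data.frame(a), as.data.frame(c_)))
})

test_that("empty groups contribute no cases and invalid specs are rejected", {
  spec <- default_cohort_spec(n_ea1 = 0, n_ea2 = 25, seed = 2)
  x <- generate_cohort(spec)
  expect_equal(nrow(x), 25)
  expect_true(all(x$diagnosis == "EA2"))
  expect_error(default_cohort_spec(n_ea1 = -5),
               class = "eadiag_validation_error")
  expect_error(
    group_spec("EA1", 10, c(ictal_vertigo = 1.2), duration_probs = rep(.25, 4),
               frequency_probs = rep(.25, 4), age_onset_median = 7,
               age_onset_iqr = c(4, 10)),
    class = "eadiag_validation_error")
  expect_error(
    group_spec("EA1", 10, c(ictal_vertigo = .5), duration_probs = rep(.3, 4),
               frequency_probs = rep(.25, 4), age_onset_median = 7,
               age_onset_iqr = c(4, 10)),
    "sum to 1", class = "eadiag_validation_error")
  expect_error(
    cohort_spec(list(eadiag:::ea1_marginals(10), eadiag:::ea1_marginals(10))),
    "distinct", class = "eadiag_validation_error")
})

test_that("raw attack values always bin back into their drawn category", {
  x <- generate_cohort(default_cohort_spec(n_ea1 = 400, n_ea2 = 400,
                                           missingness = FALSE, seed = 21))
  fm <- build_feature_matrix(x)
  known <- !is.na(x$attack_duration_minutes)
  rebinned <- vapply(x$attack_duration_minutes[known], bin_duration, "")
  expect_identical(rebinned, fm$duration_category[known])
})

test_that("generate -> recover round trip stays within 3 SEs per parameter", {
  n <- 5000
  spec <- default_cohort_spec(n_ea1 = n, n_ea2 = n, missingness = TRUE,
                              seed = 123)
  rec <- recover_parameters(generate_cohort(spec))
  for (gi in 1:2) {
    g <- spec$groups[[gi]]
    r <- rec[[g$diagnosis]]
    # binary feature prevalences, conditional on evaluable cases
    for (feat in names(g$feature_prevalence)) {
      p <- g$feature_prevalence[[feat]]
      n_eval <- round(r$n * (1 - r$feature_missingness[feat]))
      se <- sqrt(p * (1 - p) / max(n_eval, 1))
      expect_lt(abs(r$feature_prevalence[feat] - p), 3 * se + 1e-9,
                label = sprintf("%s prevalence of %s", g$diagnosis, feat))
    }
    # category proportions
    n_dur <- round(r$n * (1 - r$duration_missing))
    for (k in seq_along(g$duration_probs)) {
      p <- g$duration_probs[k]
      se <- sqrt(p * (1 - p) / n_dur)
      expect_lt(abs(r$duration_probs[k] - p), 3 * se + 1e-9,
                label = sprintf("%s duration %s", g$diagnosis,
                                names(g$duration_probs)[k]))
    }
    n_freq <- round(r$n * (1 - r$frequency_missing))
    for (k in seq_along(g$frequency_probs)) {
      p <- g$frequency_probs[k]
      se <- sqrt(p * (1 - p) / n_freq)
      expect_lt(abs(r$frequency_probs[k] - p), 3 * se + 1e-9)
    }
    # sex, availability, acetazolamide
    for (pair in list(c(r$sex_female_prob, g$sex_female_prob, r$n),
                      c(r$trigger_available_prob, g$trigger_available_prob, r$n),
                      c(r$acetazolamide_response_prob,
                        g$acetazolamide_response_prob,
                        round(r$n * r$acetazolamide_eval_prob)))) {
      se <- sqrt(pair[2] * (1 - pair[2]) / pair[3])
      expect_lt(abs(pair[1] - pair[2]), 3 * se + 1e-9)
    }
    # age of onset median within 3 SEs (SE via the log-normal density)
    sdlog <- eadiag:::lognormal_sdlog(g$age_onset_iqr[1], g$age_onset_iqr[2])
    fmed <- stats::dlnorm(g$age_onset_median, log(g$age_onset_median), sdlog)
    se_med <- 1 / (2 * fmed * sqrt(r$n))
    expect_lt(abs(r$age_onset_median - g$age_onset_median), 3 * se_med)
  }
})

test_that("the correlation plan induces co-occurrence", {
  plan <- list(list(source = "interictal_clinical_myokymia",
                    target = "trigger_kinesigenic", agreement = 1))
  spec <- cohort_spec(list(eadiag:::ea1_marginals(2000, missingness = FALSE)),
                      seed = 3, correlation_plan = plan)
  x <- generate_cohort(spec)
  both <- !is.na(x$trigger_kinesigenic) & !is.na(x$interictal_clinical_myokymia)
  expect_identical(x$trigger_kinesigenic[both],
                   x$interictal_clinical_myokymia[both])
})

test_that("the core fixture is bit-stable and recovers printed proportions", {
  a <- core_prevalence_fixture()
  b <- core_prevalence_fixture()
  expect_identical(as.data.frame(a), as.data.frame(b))
  rec <- recover_parameters(a)
  expect_equal(unname(rec$EA1$feature_prevalence["trigger_kinesigenic"]), 54 / 79)
  expect_equal(unname(rec$EA2$feature_prevalence["trigger_kinesigenic"]), 6 / 114)
  expect_equal(unname(rec$EA1$feature_prevalence["trigger_startle"]), 38 / 77)
  expect_equal(unname(rec$EA2$feature_prevalence["interictal_nystagmus"]), 156 / 246)
  expect_equal(unname(rec$EA1$duration_probs),
               c(61, 9, 9, 2) / 81, tolerance = 1e-12)
  expect_equal(unname(rec$EA2$frequency_probs),
               c(10, 34, 72, 22) / 138, tolerance = 1e-12)
  expect_equal(rec$EA1$acetazolamide_response_prob, 17 / 33)
  expect_equal(rec$EA2$acetazolamide_response_prob, 139 / 162)
})

test_that("single-case groups give degenerate prevalences and empty groups warn", {
  x <- cohort(tibble::tibble(subject_id = "only", diagnosis = "EA1",
                             ictal_vertigo = 1L, sex = "female"))
  expect_warning(rec <- recover_parameters(x), "EA2")
  expect_equal(unname(rec$EA1$feature_prevalence["ictal_vertigo"]), 1)
})
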