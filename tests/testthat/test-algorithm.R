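test_that("feature selection keeps the high-specificity significant features", {
  sel <- select_features(published_accuracy_rows())
  expected <- c("trigger_startle", "interictal_neuromyotonia",
                "interictal_emg_myokymia", "interictal_clinical_myokymia",
                "ictal_rigidity", "ictal_myokymia",
                "peripheral_muscular_interictal", "interictal_nystagmus",
                "ictal_headache", "trigger_kinesigenic", "brief_attacks",
                "trigger_anxiety", "interictal_ataxia")
  expect_setequal(sel$feature, expected)
  # GI symptoms pass the statistical filters but are consensus-excluded
  expect_false("ictal_gi_symptoms" %in% sel$feature)
  # every dropped row either failed a filter or was excluded
  dropped <- setdiff(published_accuracy_rows()$feature, sel$feature)
  for (f in setdiff(dropped, "ictal_gi_symptoms")) {
    row <- published_accuracy_rows()
    row <- row[row$feature == f, ]
    expect_true(row$specificity <= 0.90 || row$ci_low <= 0.5 ||
                  row$p_value >= 0.05, label = f)
  }
  # ranked by descending specificity, ties by descending sensitivity
  expect_true(all(diff(sel$specificity) <= 0))
})

test_that("selection is invariant under input row permutation", {
  rows <- published_accuracy_rows()
  base <- select_features(rows)
  set.seed(8)
  for (i in 1:5) {
    perm <- select_features(rows[sample(nrow(rows)), ])
    expect_identical(perm$feature, base$feature)
  }
})

test_that("selection drops CI-overlapping and empty inputs cleanly", {
  row <- tibble::tibble(feature = "x", sensitivity = 0.6, specificity = 0.95,
                        auc = 0.6, ci_low = 0.49, ci_high = 0.7,
                        p_value = 0.01)
  expect_warning(out <- select_features(row), "no features")
  expect_equal(nrow(out), 0)
  expect_warning(out <- select_features(row[0, ]), "no features")
  expect_equal(nrow(out), 0)
})

test_that("the default rule set is valid and overridable from a file", {
  rs <- default_ruleset()
  expect_equal(nrow(rs$rules), 7)
  expect_setequal(unique(rs$rules$vote), c("EA1", "EA2"))
  expect_equal(rs$conflict_policy, "first_match")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "conflict_policy: first_match",
    "rules:",
    "  - {rank: 1, feature: brief_attacks, state: present, vote: EA1}",
    "  - {rank: 2, feature: interictal_nystagmus, state: present, vote: EA2}"
  ), path)
  rs2 <- read_ruleset(path)
  expect_equal(nrow(rs2$rules), 2)

  dup <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "rules:",
    "  - {rank: 1, feature: brief_attacks, state: present, vote: EA1}",
    "  - {rank: 1, feature: interictal_nystagmus, state: present, vote: EA2}"
  ), dup)
  expect_error(read_ruleset(dup), "duplicate",
               class = "eadiag_validation_error")
  # a one-sided rule set is rejected
  expect_error(ruleset(tibble::tibble(rank = 1, feature = "brief_attacks",
                                      state = "present", vote = "EA1")),
               class = "eadiag_validation_error")
})

test_that("sequential classification fires the first matching rule", {
  rs <- default_ruleset()
  case <- list(brief_attacks = 1L, peripheral_muscular_interictal = 1L,
               interictal_nystagmus = 0L, ictal_headache = NA_integer_,
               trigger_kinesigenic_or_startle = NA_integer_,
               interictal_ataxia = 0L,
               duration_prolonged_or_protracted = 0L)
  res <- classify_case(case, rs)
  expect_equal(res$label, "EA1")
  expect_equal(res$fired_rules, 1L)
  expect_equal(res$trace$status[1], "matched")
  expect_true(all(res$trace$status[-1] == "not_evaluated"))

  case2 <- list(brief_attacks = 0L, peripheral_muscular_interictal = 0L,
                interictal_nystagmus = 1L, ictal_headache = 1L,
                trigger_kinesigenic_or_startle = 0L, interictal_ataxia = 0L,
                duration_prolonged_or_protracted = 1L)
  res2 <- classify_case(case2, rs)
  expect_equal(res2$label, "EA2")
  expect_equal(res2$fired_rules, 3L)

  # unknown features are skipped and recorded; all-unknown is indeterminate
  all_na <- stats::setNames(rep(list(NA_integer_), 7),
                            rs$rules$feature)
  res3 <- classify_case(all_na, rs)
  expect_equal(res3$label, "indeterminate")
  expect_true(all(res3$trace$status == "skipped_missing"))
})

test_that("adding a rule never changes labels decided at a lower rank", {
  rs6 <- ruleset(default_ruleset()$rules[1:6, ])
  rs7 <- default_ruleset()
  set.seed(12)
  x <- generate_cohort(default_cohort_spec(n_ea1 = 60, n_ea2 = 60,
                                           missingness = TRUE, seed = 77))
  c6 <- classify_cohort(x, rs6)
  c7 <- classify_cohort(x, rs7)
  decided <- !is.na(c6$fired_rank)
  expect_identical(c6$label[decided], c7$label[decided])
})

test_that("classification is deterministic and order-invariant", {
  x <- generate_cohort(default_cohort_spec(n_ea1 = 40, n_ea2 = 40,
                                           missingness = TRUE, seed = 5))
  calls <- classify_cohort(x)
  perm <- sample(nrow(x))
  xp <- x[perm, , drop = FALSE]
  class(xp) <- class(x)
  calls_p <- classify_cohort(xp)
  expect_identical(calls_p$label[order(perm)], calls$label)
})

test_that("evaluation counts indeterminate as a miss and handles edge cohorts", {
  # deterministic cohort: features set per vote
  x <- cohort(tibble::tibble(
    subject_id = sprintf("c%02d", 1:24),
    diagnosis = rep(c("EA1", "EA2"), each = 12),
    attack_duration_minutes = rep(c(5, 120), each = 12),
    interictal_nystagmus = rep(c(0L, 1L), each = 12)
  ))
  ev <- evaluate_classifier(x)
  expect_equal(unname(ev$sensitivity["EA1"]), 1)
  expect_equal(unname(ev$sensitivity["EA2"]), 1)
  expect_equal(ev$wrong_label_rate, 0)
  expect_equal(sum(ev$confusion), 24)

  # nothing evaluable: all indeterminate, sensitivity 0
  blank <- cohort(tibble::tibble(subject_id = c("a", "b"),
                                 diagnosis = c("EA1", "EA2")))
  ev0 <- evaluate_classifier(blank)
  expect_equal(unname(ev0$sensitivity), c(0, 0))
  expect_equal(ev0$indeterminate_rate, 1)

  # the published test-cohort arithmetic: 21 of 24 EA2 identified
  x24 <- cohort(tibble::tibble(
    subject_id = sprintf("t%02d", 1:25),
    diagnosis = c(rep("EA2", 24), "EA1"),
    interictal_nystagmus = c(rep(1L, 21), rep(0L, 3), 0L),
    attack_duration_minutes = c(rep(NA, 24), 5)
  ))
  ev24 <- evaluate_classifier(x24)
  expect_equal(unname(ev24$sensitivity["EA2"]), 0.875)

  expect_warning(evaluate_classifier(cohort(tibble::tibble(
    subject_id = c("u", "v"), diagnosis = c("EA1", NA),
    attack_duration_minutes = c(5, 5)))), "unlabeled")
})

test_that("specificity-weighted voting resolves multi-rule matches", {
  rs <- ruleset(default_ruleset()$rules,
                conflict_policy = "specificity_weighted_vote")
  case <- list(brief_attacks = 1L, peripheral_muscular_interictal = 0L,
               interictal_nystagmus = 1L, ictal_headache = 1L,
               trigger_kinesigenic_or_startle = 0L, interictal_ataxia = 0L,
               duration_prolonged_or_protracted = 0L)
  # EA2 weight 0.988 + 0.957 beats EA1 weight 0.940
  expect_equal(classify_case(case, rs)$label, "EA2")
})

test_that("default ruleset meets the operating-point performance envelope", {
  spec <- default_cohort_spec(n_ea1 = 300, n_ea2 = 300, missingness = FALSE)
  sens <- wrong <- numeric(3)
  for (i in 1:3) {
    x <- generate_cohort(spec, seed = 400 + i)
    ev <- evaluate_classifier(x)
    sens[i] <- ev$sensitivity["EA2"]
    wrong[i] <- ev$wrong_label_rate
  }
  expect_true(all(sens >= 0.80))
  expect_true(all(wrong <= 0.10))
})
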