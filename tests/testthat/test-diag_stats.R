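test_that("contingency construction uses complete-case denominators", {
  fm <- build_feature_matrix(core_prevalence_fixture())
  tab <- build_contingency(fm, "trigger_kinesigenic", "KCNA1")
  expect_equal(c(tab$tp, tab$fn, tab$fp, tab$tn), c(54, 25, 6, 108))
  expect_equal(tab$n, 193)
  tab <- build_contingency(fm, "brief_attacks", "KCNA1")
  expect_equal(c(tab$tp, tab$fn, tab$fp, tab$tn), c(61, 20, 11, 172))
  expect_equal(tab$n, 264)

  empty <- cohort(tibble::tibble(subject_id = "a", diagnosis = "EA1"))
  expect_error(build_contingency(build_feature_matrix(empty),
                                 "ictal_vertigo", "KCNA1"),
               class = "eadiag_degenerate_error")
  unlabeled <- cohort(tibble::tibble(subject_id = "a", ictal_vertigo = 1L))
  expect_error(build_contingency(build_feature_matrix(unlabeled),
                                 "ictal_vertigo", "KCNA1"),
               class = "eadiag_validation_error")
})

test_that("sensitivity/specificity/accuracy come out of the 2x2 counts", {
  m <- accuracy_metrics(contingency_2x2(54, 25, 6, 108))
  expect_equal(round(100 * m$sensitivity, 1), 68.4)
  expect_equal(round(100 * m$specificity, 1), 94.7)
  m <- accuracy_metrics(contingency_2x2(61, 20, 11, 172))
  expect_equal(round(100 * m$sensitivity, 1), 75.3)
  expect_equal(round(100 * m$specificity, 1), 94.0)
  m <- accuracy_metrics(contingency_2x2(1, 0, 0, 1))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_error(accuracy_metrics(contingency_2x2(0, 0, 3, 4)),
               "sensitivity", class = "eadiag_degenerate_error")
})

test_that("binary AUC is the three-point trapezoid (sens+spec)/2", {
  expect_equal(round(binary_auc(0.634, 0.988), 3), 0.811)
  expect_equal(round(binary_auc(54 / 79, 108 / 114), 3), 0.815)
  expect_equal(binary_auc(0, 1), 0.5)
  # identity with the explicit trapezoid over {(0,0),(1-spec,sens),(1,1)}
  set.seed(2)
  for (i in 1:50) {
    sens <- runif(1); spec <- runif(1)
    expect_equal(binary_auc(sens, spec),
                 eadiag:::trapezoid_auc(c(0, 1 - spec, 1), c(0, sens, 1)))
  }
})

test_that("ordinal ROC over duration categories gives the trapezoid AUC", {
  fm <- build_feature_matrix(core_prevalence_fixture())
  roc <- ordinal_roc(fm, "duration_category", "lower_favors_target", "KCNA1")
  expect_equal(roc$points$fpr, c(0, 11, 44, 163, 183) / 183)
  expect_equal(roc$points$tpr, c(0, 61, 70, 79, 81) / 81)
  expect_equal(roc$auc, 0.874, tolerance = 0.001)
  # monotone non-decreasing in both coordinates
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  # frequency, higher (daily) end favors EA1
  roc_f <- ordinal_roc(fm, "frequency_category", "higher_favors_target", "KCNA1")
  expect_gt(roc_f$auc, 0.5)
})

test_that("a two-level ordinal ROC equals the binary AUC of the split", {
  x <- cohort(tibble::tibble(
    subject_id = sprintf("s%02d", 1:40),
    diagnosis = rep(c("EA1", "EA2"), each = 20),
    attack_duration_minutes = c(rep(5, 14), rep(30, 6), rep(5, 3), rep(30, 17))
  ))
  fm <- build_feature_matrix(x)
  roc <- ordinal_roc(fm, "duration_category", "lower_favors_target", "KCNA1")
  expect_equal(roc$auc, binary_auc(14 / 20, 17 / 20))
})

test_that("AUC is symmetric under group swap with direction reversal", {
  fm <- build_feature_matrix(core_prevalence_fixture())
  a <- ordinal_roc(fm, "duration_category", "lower_favors_target", "KCNA1")$auc
  b <- ordinal_roc(fm, "duration_category", "higher_favors_target", "CACNA1A")$auc
  expect_equal(a, b)
})

test_that("ordinal ROC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  fm <- build_feature_matrix(core_prevalence_fixture())
  keep <- !is.na(fm$duration_category)
  score <- match(fm$duration_category[keep], eadiag:::DURATION_LEVELS)
  resp <- as.integer(fm$diagnosis[keep] == "EA1")
  ref <- suppressMessages(pROC::auc(pROC::roc(resp, -score)))
  ours <- ordinal_roc(fm, "duration_category", "lower_favors_target", "KCNA1")$auc
  expect_equal(as.numeric(ref), ours, tolerance = 1e-9)
})

test_that("Hanley-McNeil interval behaves sensibly", {
  ci <- auc_confidence_interval(0.5, 1e6, 1e6)
  expect_lt(ci["high"] - ci["low"], 0.01)
  ci <- auc_confidence_interval(0.846, 81, 183)
  expect_true(ci["low"] < 0.846 && 0.846 < ci["high"])
  expect_true(ci["low"] >= 0 && ci["high"] <= 1)
  # width comparable to the published 0.787-0.906 interval
  expect_equal(unname(ci["high"] - ci["low"]), 0.119, tolerance = 0.5)
  expect_identical(auc_confidence_interval(0.7, 50, 60),
                   auc_confidence_interval(0.7, 50, 60))
})

test_that("association test gates between chi-square and Fisher", {
  # startle: zero cell -> Fisher, p < 0.001
  res <- association_test(contingency_2x2(38, 39, 0, 114))
  expect_equal(res$test_used, "fisher")
  expect_lt(res$p_value, 0.001)
  # sex table: all expected counts >= 5 -> Pearson chi-square
  res <- association_test(contingency_2x2(58, 36, 111, 165))
  expect_equal(res$test_used, "chi_square")
  expect_lt(res$p_value, 0.05)
  # small expected counts -> Fisher
  res <- association_test(contingency_2x2(3, 2, 1, 4))
  expect_equal(res$test_used, "fisher")
  # degenerate margins -> p = 1 with warning
  expect_warning(res <- association_test(contingency_2x2(0, 0, 3, 4)),
                 "degenerate")
  expect_equal(res$p_value, 1)
})

test_that("Fisher p equals hypergeometric enumeration for small tables", {
  checked <- 0L
  for (N in 1:15) {
    parts <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    parts <- parts[parts$a + parts$b + parts$c <= N, ]
    parts$d <- N - parts$a - parts$b - parts$c
    for (i in seq_len(nrow(parts))) {
      a <- parts$a[i]; b <- parts$b[i]; c <- parts$c[i]; d <- parts$d[i]
      p_pkg <- eadiag:::fisher_p(contingency_2x2(a, b, c, d))
      p_orc <- fisher_oracle(a, b, c, d)
      if (abs(p_pkg - p_orc) > 1e-8) {
        fail(sprintf("mismatch at (%d,%d,%d,%d): %.10f vs %.10f",
                     a, b, c, d, p_pkg, p_orc))
      }
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 3000)
})

test_that("Mann-Whitney p equals exhaustive permutation p for small groups", {
  set.seed(31)
  sizes <- list(c(3, 3), c(4, 4), c(5, 5), c(6, 4), c(8, 8))
  for (sz in sizes) {
    for (rep in 1:3) {
      a <- round(rnorm(sz[1], 0, 10), 4)
      b <- round(rnorm(sz[2], 2, 10), 4)
      expect_equal(eadiag:::mw_test(a, b), perm_oracle(a, b),
                   tolerance = 1e-10,
                   label = sprintf("sizes %d/%d rep %d", sz[1], sz[2], rep))
    }
  }
  # complete separation at sizes 8/8
  expect_equal(eadiag:::mw_test(1:8, 101:108), perm_oracle(1:8, 101:108))
})

test_that("continuous comparison gates on Shapiro-Wilk normality", {
  expect_equal(suppressWarnings(
    compare_continuous(c(1, 2, 3, 4), c(1, 2, 3, 4)))$p_value, 1)
  set.seed(1)
  skewed_a <- rlnorm(60, 0, 1); skewed_b <- rlnorm(60, 0.5, 1)
  expect_equal(compare_continuous(skewed_a, skewed_b)$test_used, "mann_whitney")
  norm_a <- rnorm(60); norm_b <- rnorm(60, 0.5)
  expect_equal(compare_continuous(norm_a, norm_b)$test_used, "t_test")
  expect_error(compare_continuous(1, c(1, 2)),
               class = "eadiag_insufficient_data")
})

test_that("chi-square p is uniform under the independence null", {
  set.seed(17)
  ps <- replicate(1000, {
    g <- rbinom(80, 1, 0.5); f <- rbinom(80, 1, 0.5)
    tab <- contingency_2x2(sum(g & f), sum(g & !f), sum(!g & f), sum(!g & !f))
    suppressWarnings(association_test(tab)$p_value)
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("drug response rates reproduce the published acetazolamide row", {
  rr <- response_rates(core_prevalence_fixture(), "acetazolamide")
  ea2 <- rr$rates[rr$rates$diagnosis == "EA2", ]
  ea1 <- rr$rates[rr$rates$diagnosis == "EA1", ]
  expect_equal(c(ea2$responders, ea2$evaluable), c(139, 162))
  expect_equal(c(ea1$responders, ea1$evaluable), c(17, 33))
  expect_equal(round(100 * ea2$proportion, 1), 85.8)
  expect_equal(round(100 * ea1$proportion, 1), 51.5)
  expect_lt(rr$test$p_value, 0.001)
  # single evaluable group: proportion returned, test skipped
  rr <- response_rates(core_prevalence_fixture(), "aminopyridine_4")
  expect_equal(rr$rates$proportion[rr$rates$diagnosis == "EA2"], 1)
  expect_true(is.na(rr$rates$proportion[rr$rates$diagnosis == "EA1"]))
  expect_null(rr$test)
})
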