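#' 2x2 diagnostic contingency table
#'
#' Counts cross-classifying diagnosis against a binary feature among cases
#' with non-missing data. "Positive" means feature present; "case" means the
#' feature's target gene group, so `tp` counts target-gene cases with the
#' feature present and `tn` counts other-gene cases with the feature absent.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @param feature,target_gene Labels carried along for reporting.
#' @return An object of class `ea_2x2`.
#' @export
contingency_2x2 <- function(tp, fn, fp, tn, feature = NA_character_,
                            target_gene = NA_character_) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    ea_stop("contingency counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 n = as.integer(tp + fn + fp + tn),
                 feature = feature, target_gene = target_gene),
            class = "ea_2x2")
}

#' @export
print.ea_2x2 <- function(x, ...) {
  cat(sprintf("<ea_2x2 %s vs %s: tp=%d fn=%d fp=%d tn=%d (N=%d)>\n",
              x$feature, x$target_gene, x$tp, x$fn, x$fp, x$tn, x$n))
  invisible(x)
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$tp, tab$fn, tab$fp, tab$tn), nrow = 2, byrow = TRUE,
         dimnames = list(group = c("target", "other"),
                         feature = c("present", "absent")))
}

#' Build the contingency table for one binary feature
#'
#' Complete-case convention: cases with an unknown feature value are
#' excluded from the denominator, never counted as absent; unlabeled cases
#' are rejected upstream by requiring a known diagnosis.
#'
#' @param fm An `ea_feature_matrix` whose cases carry known diagnoses.
#' @param feature Name of a tri-state feature column.
#' @param target_gene `"KCNA1"` (EA1 positive) or `"CACNA1A"` (EA2 positive).
#' @return An `ea_2x2`.
#' @export
build_contingency <- function(fm, feature, target_gene) {
  stopifnot(inherits(fm, "ea_feature_matrix"))
  if (!feature %in% attr(fm, "features")) {
    ea_stop("feature `%s` is not in the feature matrix", feature)
  }
  if (!target_gene %in% GENES) ea_stop("unknown target gene: %s", target_gene)
  if (any(is.na(fm$diagnosis))) {
    ea_stop("diagnostic accuracy requires labeled cases; %d unlabeled",
            sum(is.na(fm$diagnosis)), class = "eadiag_validation_error")
  }
  target_dx <- if (target_gene == "KCNA1") "EA1" else "EA2"
  v <- fm[[feature]]
  known <- !is.na(v)
  if (!any(known)) {
    ea_stop("feature `%s`: no non-missing cases (degenerate table)", feature,
            class = "eadiag_degenerate_error")
  }
  is_target <- fm$diagnosis == target_dx
  contingency_2x2(
    tp = sum(known & is_target & v == 1L),
    fn = sum(known & is_target & v == 0L),
    fp = sum(known & !is_target & v == 1L),
    tn = sum(known & !is_target & v == 0L),
    feature = feature, target_gene = target_gene
  )
}

#' Sensitivity, specificity and accuracy of a 2x2 table
#'
#' @param tab An `ea_2x2` with positive row and column margins.
#' @return A list with `sensitivity` (`tp/(tp+fn)`), `specificity`
#'   (`tn/(tn+fp)`) and `accuracy` (`(tp+tn)/N`).
#' @export
accuracy_metrics <- function(tab) {
  stopifnot(inherits(tab, "ea_2x2"))
  if (tab$tp + tab$fn == 0) {
    ea_stop("undefined sensitivity: no target-gene cases (tp+fn = 0)",
            class = "eadiag_degenerate_error")
  }
  if (tab$tn + tab$fp == 0) {
    ea_stop("undefined specificity: no comparison cases (tn+fp = 0)",
            class = "eadiag_degenerate_error")
  }
  list(sensitivity = tab$tp / (tab$tp + tab$fn),
       specificity = tab$tn / (tab$tn + tab$fp),
       accuracy = (tab$tp + tab$tn) / tab$n)
}

#' AUC of a single binary feature
#'
#' For one binary marker the ROC curve has a single interior point
#' `(1 - specificity, sensitivity)` and its trapezoidal area reduces to
#' `(sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return The AUC.
#' @export
binary_auc <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  (sensitivity + specificity) / 2
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC curve over an ordinal feature
#'
#' One operating point per cumulative threshold over the ordered category
#' levels. With `direction = "lower_favors_target"` a case is called
#' positive when its category is at or below the threshold (e.g. shorter
#' attacks favor EA1); `"higher_favors_target"` accumulates from the top.
#'
#' @param fm An `ea_feature_matrix`.
#' @param feature `"duration_category"` or `"frequency_category"`.
#' @param direction Which end of the ordinal scale favors the target gene.
#' @param target_gene `"KCNA1"` or `"CACNA1A"`.
#' @return An object of class `ea_roc`: `points` (tibble of `fpr`, `tpr`
#'   from (0,0) to (1,1)) and `auc` (trapezoidal).
#' @export
ordinal_roc <- function(fm, feature,
                        direction = c("lower_favors_target",
                                      "higher_favors_target"),
                        target_gene) {
  stopifnot(inherits(fm, "ea_feature_matrix"))
  direction <- match.arg(direction)
  if (!feature %in% attr(fm, "ordinal_features")) {
    ea_stop("feature `%s` is not ordinal", feature)
  }
  levels <- ordinal_levels(feature)
  if (direction == "higher_favors_target") levels <- rev(levels)
  target_dx <- if (target_gene == "KCNA1") "EA1" else "EA2"
  v <- fm[[feature]]
  known <- !is.na(v) & !is.na(fm$diagnosis)
  v <- v[known]
  is_target <- fm$diagnosis[known] == target_dx
  n_t <- sum(is_target)
  n_o <- sum(!is_target)
  if (n_t == 0 || n_o == 0) ea_stop("both groups must have evaluable cases")
  counts_t <- vapply(levels, function(l) sum(v == l & is_target), 0L)
  counts_o <- vapply(levels, function(l) sum(v == l & !is_target), 0L)
  if (sum(counts_t + counts_o > 0) < 2) {
    ea_warn("single-level ordinal feature: degenerate ROC (auc 0.5)")
    points <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
    return(structure(list(points = points, auc = 0.5, feature = feature,
                          target_gene = target_gene), class = "ea_roc"))
  }
  tpr <- unname(c(0, cumsum(counts_t) / n_t))
  fpr <- unname(c(0, cumsum(counts_o) / n_o))
  points <- tibble::tibble(fpr = fpr, tpr = tpr)
  structure(list(points = points, auc = trapezoid_auc(fpr, tpr),
                 feature = feature, target_gene = target_gene),
            class = "ea_roc")
}

#' @export
print.ea_roc <- function(x, ...) {
  cat(sprintf("<ea_roc %s vs %s: %d points, AUC %.3f>\n",
              x$feature %||% "?", x$target_gene %||% "?",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal interval using the Hanley-McNeil standard error
#' `sqrt((A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)) / (n1 n2))` with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, clipped to `[0, 1]`.
#'
#' @param auc Point estimate in `[0, 1]`.
#' @param n_target,n_other Group sizes (at least 1 each).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
auc_confidence_interval <- function(auc, n_target, n_other, level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_target >= 1, n_other >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_target - 1) * (q1 - auc^2) +
                (n_other - 1) * (q2 - auc^2)) / (n_target * n_other))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = max(0, auc - z * se), high = min(1, auc + z * se))
}

# Two-sided Fisher exact p for a 2x2 table.
fisher_p <- function(tab) {
  stats::fisher.test(as_matrix_2x2(tab), alternative = "two.sided")$p.value
}

#' Association test for a 2x2 table
#'
#' Pearson chi-square without continuity correction, switching to the
#' two-sided Fisher exact test when any expected cell count is below 5 or
#' any observed cell is zero (the zero-cell case is where the source
#' analyses consistently report Fisher). Degenerate margins give p = 1 with
#' a warning.
#'
#' @param tab An `ea_2x2`.
#' @return A list with `p_value` and `test_used` (`"chi_square"` or
#'   `"fisher"`).
#' @export
association_test <- function(tab) {
  stopifnot(inherits(tab, "ea_2x2"))
  m <- as_matrix_2x2(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    ea_warn("degenerate margins: association test undefined, p = 1")
    return(list(p_value = 1, test_used = "degenerate"))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5) || any(m == 0)) {
    list(p_value = fisher_p(tab), test_used = "fisher")
  } else {
    p <- stats::chisq.test(m, correct = FALSE)$p.value
    list(p_value = p, test_used = "chi_square")
  }
}

# Mann-Whitney two-sided p (wilcox.test: exact for small tie-free samples,
# otherwise normal approximation with tie correction).
mw_test <- function(a, b) {
  suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))$p.value
}

#' Compare a continuous variable between the two groups
#'
#' Shapiro-Wilk at alpha 0.05 on each group decides the test: both normal
#' gives Welch's two-sided t-test, otherwise the Mann-Whitney U test.
#'
#' @param values_a,values_b Numeric vectors (at least 2 observations each).
#' @return A list with `p_value` and `test_used` (`"t_test"` or
#'   `"mann_whitney"`).
#' @export
compare_continuous <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    ea_stop("compare_continuous needs at least 2 observations per group",
            class = "eadiag_insufficient_data")
  }
  normal <- function(v) {
    if (length(v) < 3 || length(unique(v)) == 1) return(FALSE)
    if (length(v) > 5000) v <- sample(v, 5000)
    stats::shapiro.test(v)$p.value > 0.05
  }
  if (normal(values_a) && normal(values_b)) {
    list(p_value = stats::t.test(values_a, values_b, var.equal = FALSE)$p.value,
         test_used = "t_test")
  } else {
    list(p_value = mw_test(values_a, values_b), test_used = "mann_whitney")
  }
}

#' Per-gene drug response rates
#'
#' Response means complete or partial remission; unknown responses are
#' excluded from the denominators. When both genes have evaluable cases the
#' 2x2 association test is run; with a single evaluable group the test is
#' skipped.
#'
#' @param x An `ea_cohort` with labeled cases.
#' @param drug Drug column name (e.g. `"drug_acetazolamide"`), or the bare
#'   name without the `drug_` prefix.
#' @return A list: `rates` (tibble with gene, responders, evaluable,
#'   proportion) and `test` (association result or `NULL` when skipped).
#' @export
response_rates <- function(x, drug) {
  stopifnot(inherits(x, "ea_cohort"))
  if (!drug %in% DRUGS) drug <- paste0("drug_", drug)
  if (!drug %in% DRUGS) ea_stop("unknown drug column: %s", drug)
  resp <- x[[drug]]
  known <- !is.na(resp) & !is.na(x$diagnosis)
  rates <- do.call(rbind, lapply(c("EA1", "EA2"), function(dx) {
    sel <- known & x$diagnosis == dx
    n <- sum(sel)
    r <- sum(sel & resp %in% c("complete", "partial"))
    data.frame(diagnosis = dx, gene = if (dx == "EA1") "KCNA1" else "CACNA1A",
               responders = r, evaluable = n,
               proportion = if (n > 0) r / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rates <- tibble::as_tibble(rates)
  if (all(rates$evaluable == 0)) {
    ea_stop("no evaluable responses for %s in either group", drug,
            class = "eadiag_degenerate_error")
  }
  test <- NULL
  if (all(rates$evaluable > 0)) {
    tab <- contingency_2x2(
      tp = rates$responders[rates$diagnosis == "EA2"],
      fn = rates$evaluable[rates$diagnosis == "EA2"] -
        rates$responders[rates$diagnosis == "EA2"],
      fp = rates$responders[rates$diagnosis == "EA1"],
      tn = rates$evaluable[rates$diagnosis == "EA1"] -
        rates$responders[rates$diagnosis == "EA1"],
      feature = drug, target_gene = "CACNA1A"
    )
    test <- association_test(tab)
  }
  list(rates = rates, test = test)
}

#' Full diagnostic-accuracy row for one binary feature
#'
#' Combines [build_contingency()], [accuracy_metrics()], [binary_auc()],
#' [auc_confidence_interval()] and [association_test()] into one record.
#'
#' @param fm An `ea_feature_matrix`.
#' @param feature Tri-state feature column name.
#' @param target_gene `"KCNA1"` or `"CACNA1A"`.
#' @return A one-row tibble: feature, target_gene, n, sensitivity,
#'   specificity, accuracy, auc, ci_low, ci_high, p_value, test_used.
#' @export
diagnostic_accuracy <- function(fm, feature, target_gene) {
  tab <- build_contingency(fm, feature, target_gene)
  met <- accuracy_metrics(tab)
  auc <- binary_auc(met$sensitivity, met$specificity)
  ci <- auc_confidence_interval(auc, tab$tp + tab$fn, tab$fp + tab$tn)
  test <- association_test(tab)
  tibble::tibble(
    feature = feature, target_gene = target_gene, n = tab$n,
    sensitivity = met$sensitivity, specificity = met$specificity,
    accuracy = met$accuracy, auc = auc,
    ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
    p_value = test$p_value, test_used = test$test_used
  )
}
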