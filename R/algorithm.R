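#' Feature-selection configuration
#'
#' Selection keeps features that (i) are statistically significant at
#' `alpha`, (ii) have an AUC whose confidence interval lies entirely above
#' 0.5, and (iii) exceed the specificity floor; features on the
#' expert-consensus exclusion list are then removed. The default exclusions
#' are ictal fatigue and gastrointestinal symptoms, dropped during algorithm
#' construction for being too subjective/heterogeneous to extract reliably.
#'
#' @param alpha Significance level (default 0.05).
#' @param specificity_floor Minimum specificity, exclusive (default 0.90).
#' @param exclusion_list Feature names removed by expert consensus.
#' @return A list of class `ea_selection_config`.
#' @export
selection_config <- function(alpha = 0.05, specificity_floor = 0.90,
                             exclusion_list = c("ictal_fatigue",
                                                "ictal_gi_symptoms")) {
  if (specificity_floor <= 0 || specificity_floor >= 1) {
    ea_stop("specificity_floor must lie in (0, 1)")
  }
  structure(list(alpha = alpha, specificity_floor = specificity_floor,
                 exclusion_list = exclusion_list),
            class = "ea_selection_config")
}

#' Select candidate features for the diagnostic algorithm
#'
#' Filters diagnostic-accuracy rows with the criteria in
#' [selection_config()] and ranks survivors by descending specificity,
#' breaking ties by descending sensitivity then feature name, so the output
#' is invariant to the input row order.
#'
#' @param accuracy_rows A tibble as produced by [diagnostic_accuracy()] /
#'   [accuracy_table()] (columns `feature`, `sensitivity`, `specificity`,
#'   `ci_low`, `p_value`).
#' @param config An `ea_selection_config`.
#' @return The retained rows, ranked; zero rows (with a warning) when
#'   nothing survives.
#' @export
select_features <- function(accuracy_rows, config = selection_config()) {
  stopifnot(is.data.frame(accuracy_rows))
  req <- c("feature", "sensitivity", "specificity", "ci_low", "p_value")
  missing_cols <- setdiff(req, names(accuracy_rows))
  if (length(missing_cols) > 0) {
    ea_stop("accuracy rows lack column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  keep <- accuracy_rows$p_value < config$alpha &
    accuracy_rows$ci_low > 0.5 &
    accuracy_rows$specificity > config$specificity_floor &
    !accuracy_rows$feature %in% config$exclusion_list
  out <- accuracy_rows[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    ea_warn("no features survive selection")
    return(out)
  }
  ord <- order(-out$specificity, -out$sensitivity, out$feature)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Build a rule set for the sequential classifier
#'
#' @param rules A data frame with columns `rank` (unique positive
#'   integers), `feature` (feature-matrix column), `state` (`"present"` or
#'   `"absent"`), `vote` (`"EA1"` or `"EA2"`), and optionally `specificity`
#'   (the provenance value that justified inclusion; used as the weight
#'   under the `specificity_weighted_vote` policy).
#' @param conflict_policy `"first_match"` (stop at the first matching rule)
#'   or `"specificity_weighted_vote"` (evaluate all rules, sum specificity
#'   weights per vote, ties give indeterminate).
#' @return An object of class `ea_ruleset`.
#' @export
ruleset <- function(rules, conflict_policy = c("first_match",
                                               "specificity_weighted_vote")) {
  conflict_policy <- match.arg(conflict_policy)
  rules <- tibble::as_tibble(rules)
  req <- c("rank", "feature", "state", "vote")
  if (!all(req %in% names(rules))) {
    ea_stop("rules need columns: %s", paste(req, collapse = ", "),
            class = "eadiag_config_error")
  }
  if (anyDuplicated(rules$rank)) {
    ea_stop("duplicate rule ranks", class = "eadiag_validation_error")
  }
  if (!all(rules$vote %in% DIAGNOSES)) {
    ea_stop("rule votes must be EA1 or EA2", class = "eadiag_validation_error")
  }
  if (!all(rules$state %in% c("present", "absent"))) {
    ea_stop("rule states must be present or absent",
            class = "eadiag_validation_error")
  }
  if (length(unique(rules$vote)) < 2) {
    ea_stop("a rule set must contain at least one rule voting for each diagnosis",
            class = "eadiag_validation_error")
  }
  if (!"specificity" %in% names(rules)) rules$specificity <- NA_real_
  rules <- rules[order(rules$rank), , drop = FALSE]
  structure(list(rules = rules, conflict_policy = conflict_policy,
                 default_label = "indeterminate"),
            class = "ea_ruleset")
}

#' The shipped default rule set
#'
#' A sequential reconstruction of the published management flowchart,
#' ordered by the specificity evidence of each feature (the figure's exact
#' branch topology is not printed in the text, so the shipped order is this
#' package's documented reconstruction; pass a rule file to
#' [read_ruleset()] to encode a different topology):
#'
#' 1. brief attacks (at most 10 min) present -> EA1
#' 2. interictal peripheral muscular signs (myokymia, neuromyotonia, EMG
#'    myokymia or other) present -> EA1
#' 3. interictal nystagmus present -> EA2
#' 4. ictal headache present -> EA2
#' 5. kinesigenic or startle trigger present -> EA1
#' 6. interictal ataxia present -> EA2
#' 7. prolonged or protracted attack duration -> EA2
#'
#' A rule whose feature is unknown for a case is skipped; a case matching
#' no rule is indeterminate.
#'
#' @return An `ea_ruleset` with `first_match` conflict policy.
#' @export
default_ruleset <- function() {
  ruleset(tibble::tibble(
    rank = 1:7,
    feature = c("brief_attacks", "peripheral_muscular_interictal",
                "interictal_nystagmus", "ictal_headache",
                "trigger_kinesigenic_or_startle", "interictal_ataxia",
                "duration_prolonged_or_protracted"),
    state = "present",
    vote = c("EA1", "EA1", "EA2", "EA2", "EA1", "EA2", "EA2"),
    specificity = c(0.940, 0.992, 0.988, 0.957, 0.947, 0.912, 0.864)
  ), conflict_policy = "first_match")
}

#' Read a rule set from a YAML or JSON file
#'
#' The file holds a list of rules (`feature`, `state`, `vote`, `rank`,
#' optional `specificity`) and optionally a `conflict_policy`.
#'
#' @param path Rule file; format chosen from the extension.
#' @return An `ea_ruleset`.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) ea_stop("rule file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  policy <- raw$conflict_policy %||% "first_match"
  rules <- raw$rules %||% raw
  df <- do.call(rbind, lapply(rules, function(r) {
    data.frame(rank = as.integer(r$rank), feature = r$feature,
               state = r$state %||% "present", vote = r$vote,
               specificity = as.numeric(r$specificity %||% NA),
               stringsAsFactors = FALSE)
  }))
  ruleset(df, conflict_policy = policy)
}

#' @export
print.ea_ruleset <- function(x, ...) {
  cat(sprintf("<ea_ruleset: %d rules, policy %s>\n",
              nrow(x$rules), x$conflict_policy))
  for (i in seq_len(nrow(x$rules))) {
    r <- x$rules[i, ]
    cat(sprintf("  %d. %s %s -> %s\n", r$rank, r$feature, r$state, r$vote))
  }
  invisible(x)
}

#' Classify one case with a rule set
#'
#' Rules are evaluated in rank order on the case's engineered features
#' (tri-state values as in [build_feature_matrix()]). A rule whose feature
#' is unknown is skipped and recorded as `skipped_missing`. Under
#' `first_match` the first matching rule decides the label; if every rule
#' fails or is skipped the case is indeterminate.
#'
#' @param case A named list / one-row feature matrix of tri-state values.
#' @param rules An `ea_ruleset`.
#' @return A list of class `ea_classification`: `label` (`"EA1"`, `"EA2"`
#'   or `"indeterminate"`), `fired_rules` (ranks that matched, in order) and
#'   `trace` (tibble with per-rule status: matched / failed /
#'   skipped_missing / not_evaluated).
#' @export
classify_case <- function(case, rules) {
  stopifnot(inherits(rules, "ea_ruleset"))
  rs <- rules$rules
  status <- character(nrow(rs))
  matched <- logical(nrow(rs))
  label <- "indeterminate"
  fired <- integer(0)
  for (i in seq_len(nrow(rs))) {
    feat <- rs$feature[i]
    val <- case[[feat]]
    if (is.null(val)) ea_stop("case lacks feature `%s`", feat)
    val <- val[[1]]
    if (is.na(val)) {
      status[i] <- "skipped_missing"
      next
    }
    want <- if (rs$state[i] == "present") 1L else 0L
    if (val == want) {
      status[i] <- "matched"
      matched[i] <- TRUE
      fired <- c(fired, rs$rank[i])
      if (rules$conflict_policy == "first_match") {
        label <- rs$vote[i]
        if (i < nrow(rs)) status[(i + 1):nrow(rs)] <- "not_evaluated"
        break
      }
    } else {
      status[i] <- "failed"
    }
  }
  if (rules$conflict_policy == "specificity_weighted_vote" && any(matched)) {
    w <- ifelse(is.na(rs$specificity), 1, rs$specificity)
    votes <- tapply(w[matched], rs$vote[matched], sum)
    if (length(votes) == 1 || max(votes) > min(votes)) {
      label <- names(votes)[which.max(votes)]
    } # exact tie stays indeterminate
  }
  structure(list(label = label, fired_rules = fired,
                 trace = tibble::tibble(rank = rs$rank, feature = rs$feature,
                                        vote = rs$vote, status = status)),
            class = "ea_classification")
}

#' Classify every case in a cohort
#'
#' @param x An `ea_cohort` or `ea_feature_matrix`.
#' @param rules An `ea_ruleset` (default [default_ruleset()]).
#' @return A tibble: `subject_id`, `diagnosis` (true label, `NA` when
#'   unknown), `label` (assigned), `fired_rank`, `fired_feature`.
#' @export
classify_cohort <- function(x, rules = default_ruleset()) {
  fm <- if (inherits(x, "ea_feature_matrix")) x else build_feature_matrix(x)
  rs <- rules$rules
  res <- lapply(seq_len(nrow(fm)), function(i) classify_case(fm[i, ], rules))
  labels <- vapply(res, function(r) r$label, "")
  first_rank <- vapply(res, function(r) {
    if (length(r$fired_rules) > 0) r$fired_rules[1] else NA_integer_
  }, 0L)
  tibble::tibble(
    subject_id = fm$subject_id,
    diagnosis = fm$diagnosis,
    label = labels,
    fired_rank = first_rank,
    fired_feature = ifelse(is.na(first_rank), NA_character_,
                           rs$feature[match(first_rank, rs$rank)])
  )
}

#' Evaluate the classifier on a labeled cohort
#'
#' Per-diagnosis sensitivity counts indeterminate as a miss (the case was
#' not identified). The wrong-label rate is the fraction of labeled cases
#' receiving the opposite (non-indeterminate) diagnosis. Unlabeled cases
#' are excluded with a warning.
#'
#' @param x An `ea_cohort` or `ea_feature_matrix` with labeled cases.
#' @param rules An `ea_ruleset`.
#' @return A list of class `ea_classifier_evaluation`: `confusion` (true
#'   diagnosis by assigned label, including the indeterminate column),
#'   `sensitivity` (named by diagnosis), `specificity` (named by
#'   diagnosis), `wrong_label_rate`, `indeterminate_rate`, `n`.
#' @export
evaluate_classifier <- function(x, rules = default_ruleset()) {
  calls <- classify_cohort(x, rules)
  unlabeled <- is.na(calls$diagnosis)
  if (any(unlabeled)) {
    ea_warn("%d unlabeled case(s) excluded from evaluation", sum(unlabeled))
    calls <- calls[!unlabeled, , drop = FALSE]
  }
  if (nrow(calls) == 0) ea_stop("no labeled cases to evaluate")
  truth <- factor(calls$diagnosis, levels = DIAGNOSES)
  assigned <- factor(calls$label, levels = c(DIAGNOSES, "indeterminate"))
  confusion <- table(truth = truth, assigned = assigned)
  sens <- vapply(DIAGNOSES, function(dx) {
    n <- sum(truth == dx)
    if (n == 0) NA_real_ else confusion[dx, dx] / n
  }, 0)
  spec <- vapply(DIAGNOSES, function(dx) {
    other <- setdiff(DIAGNOSES, dx)
    n <- sum(truth == other)
    if (n == 0) NA_real_ else sum(confusion[other, colnames(confusion) != dx]) / n
  }, 0)
  wrong <- sum(confusion["EA1", "EA2"], confusion["EA2", "EA1"])
  structure(list(confusion = confusion, sensitivity = sens,
                 specificity = spec,
                 wrong_label_rate = wrong / nrow(calls),
                 indeterminate_rate = sum(confusion[, "indeterminate"]) / nrow(calls),
                 n = nrow(calls)),
            class = "ea_classifier_evaluation")
}

#' @export
print.ea_classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier evaluation: n=%d>\n", x$n))
  print(x$confusion)
  cat(sprintf("sensitivity: EA1 %.3f, EA2 %.3f\n",
              x$sensitivity["EA1"], x$sensitivity["EA2"]))
  cat(sprintf("wrong-label rate %.3f, indeterminate rate %.3f\n",
              x$wrong_label_rate, x$indeterminate_rate))
  invisible(x)
}
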