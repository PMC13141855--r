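#' Collapse a reported range or mean to a single value
#'
#' Published attack metrics are often given as a range or a mean. The
#' curation rule keeps the longest/largest value of a range, or the mean
#' when only a mean is reported.
#'
#' @param min_value,max_value Range endpoints (either may be `NA`).
#' @param mean_value Reported mean (`NA` if not given).
#' @return A single numeric value, or `NA` when nothing was provided.
#' @export
#' @examples
#' collapse_range(5, 30)          # -> 30
#' collapse_range(NA, NA, 15)     # -> 15
#' collapse_range(10)             # -> 10
collapse_range <- function(min_value = NA, max_value = NA, mean_value = NA) {
  if (!is.na(max_value)) return(max_value)
  if (!is.na(min_value)) return(min_value)
  if (!is.na(mean_value)) return(mean_value)
  NA_real_
}

#' Bin attack duration into the four ordinal categories
#'
#' Brief: at most 10 minutes; intermediate: more than 10 and at most 60;
#' prolonged: more than one hour and under one day; protracted: one day or
#' longer.
#'
#' @param minutes Attack duration in minutes (positive).
#' @return One of `"brief"`, `"intermediate"`, `"prolonged"`, `"protracted"`.
#' @export
bin_duration <- function(minutes) {
  if (is.na(minutes)) return(NA_character_)
  if (minutes <= 0) ea_stop("duration must be positive, got %g", minutes)
  if (minutes <= 10) "brief"
  else if (minutes <= 60) "intermediate"
  else if (minutes < 1440) "prolonged"
  else "protracted"
}

#' Bin attack frequency into the four ordinal categories
#'
#' Daily: at least one attack per day; weekly: at least one per week but
#' fewer than one per day; monthly: at least one per month but fewer than
#' one per week; rare/sporadic: fewer than one per month. Frequencies are
#' normalised to attacks per 30-day month with a 7-day week, so the cut
#' points are 30, 30/7 and 1.
#'
#' @param attacks_per_month Attack frequency per 30-day month (positive).
#' @return One of `"daily"`, `"weekly"`, `"monthly"`, `"rare_sporadic"`.
#' @export
bin_frequency <- function(attacks_per_month) {
  if (is.na(attacks_per_month)) return(NA_character_)
  if (attacks_per_month <= 0) {
    ea_stop("frequency must be positive, got %g", attacks_per_month)
  }
  if (attacks_per_month >= 30) "daily"
  else if (attacks_per_month >= 30 / 7) "weekly"
  else if (attacks_per_month >= 1) "monthly"
  else "rare_sporadic"
}

trigger_dict_cache <- new.env(parent = emptyenv())

trigger_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(trigger_dict_cache$default)) return(trigger_dict_cache$default)
    path <- system.file("extdata", "trigger_synonyms.yaml", package = "eadiag")
  }
  dict <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(names(dict), function(lbl) {
    data.frame(label = tolower(lbl), category = dict[[lbl]]$category,
               subtype = dict[[lbl]]$subtype %||% "none",
               stringsAsFactors = FALSE)
  }))
  trigger_dict_cache$default <- tab
  tab
}

#' Map a free-text trigger label onto the trigger taxonomy
#'
#' Triggers are classified as kinesigenic (sudden movement / movement
#' initiation), exercise-induced, or non-kinesigenic; non-kinesigenic
#' triggers carry a subtype (alcohol, tobacco, sleep deprivation,
#' physiological stress covering fever/illness/infection, fatigue, fasting,
#' caffeine, startle, heat, anxiety, menstruation, excitement, emotional
#' stress, or other). Lookup is case-insensitive against a shipped,
#' user-editable synonym dictionary; an unmatched label falls back to
#' non-kinesigenic/other with a warning.
#'
#' @param raw_label Character vector of free-text trigger labels.
#' @param dictionary Optional path to an alternative YAML synonym dictionary
#'   (`raw label -> {category, subtype}`).
#' @return A tibble with columns `label`, `category`, `subtype`.
#' @export
map_trigger <- function(raw_label, dictionary = NULL) {
  dict <- trigger_dictionary(dictionary)
  key <- tolower(trimws(raw_label))
  idx <- match(key, dict$label)
  unmatched <- is.na(idx)
  if (any(unmatched)) {
    ea_warn("unrecognised trigger label(s) mapped to non_kinesigenic/other: %s",
            paste(unique(raw_label[unmatched]), collapse = ", "))
  }
  tibble::tibble(
    label = raw_label,
    category = ifelse(unmatched, "non_kinesigenic", dict$category[idx]),
    subtype = ifelse(unmatched, "other", dict$subtype[idx])
  )
}

# any-of composite over tri-state columns: present if any present,
# unknown only if every component is unknown, absent otherwise
tri_any <- function(mat) {
  any_present <- apply(mat, 1, function(r) any(!is.na(r) & r == 1L))
  all_unknown <- apply(mat, 1, function(r) all(is.na(r)))
  out <- rep(0L, nrow(mat))
  out[any_present] <- 1L
  out[!any_present & all_unknown] <- NA_integer_
  out
}

#' Build the per-case binary/ordinal feature matrix
#'
#' Derives the analysis features from a cohort: every trigger, ictal-sign
#' and interictal-sign tri-state column; the ordinal `duration_category` and
#' `frequency_category` (binned from the raw value when not cached); the
#' binary `brief_attacks` (duration category is brief) and `daily_attacks`
#' (frequency category is daily); the composite
#' `peripheral_muscular_interictal` (present iff any of clinical myokymia,
#' neuromyotonia, EMG myokymia or another stated peripheral muscular sign is
#' present; unknown iff all components are unknown); and two classifier
#' helper composites, `trigger_kinesigenic_or_startle` and
#' `duration_prolonged_or_protracted`. Missingness propagates: an unknown
#' input yields an unknown feature.
#'
#' @param x An `ea_cohort`.
#' @return A tibble of class `ea_feature_matrix` with `subject_id`,
#'   `diagnosis`, tri-state feature columns (attributes `features`) and the
#'   two ordinal columns (attribute `ordinal_features`).
#' @export
build_feature_matrix <- function(x) {
  stopifnot(inherits(x, "ea_cohort"))
  dur <- ifelse(is.na(x$duration_category) & !is.na(x$attack_duration_minutes),
                vapply(x$attack_duration_minutes,
                       function(m) if (is.na(m)) NA_character_ else bin_duration(m),
                       ""),
                x$duration_category)
  freq <- ifelse(is.na(x$frequency_category) & !is.na(x$attack_frequency_per_month),
                 vapply(x$attack_frequency_per_month,
                        function(m) if (is.na(m)) NA_character_ else bin_frequency(m),
                        ""),
                 x$frequency_category)
  fm <- tibble::tibble(subject_id = x$subject_id, diagnosis = x$diagnosis)
  for (col in c(TRIGGER_FEATURES, ICTAL_FEATURES, INTERICTAL_FEATURES,
                OTHER_TRISTATE)) {
    fm[[col]] <- x[[col]]
  }
  fm$brief_attacks <- ifelse(is.na(dur), NA_integer_,
                             as.integer(dur == "brief"))
  fm$daily_attacks <- ifelse(is.na(freq), NA_integer_,
                             as.integer(freq == "daily"))
  fm$duration_prolonged_or_protracted <-
    ifelse(is.na(dur), NA_integer_,
           as.integer(dur %in% c("prolonged", "protracted")))
  fm$peripheral_muscular_interictal <-
    tri_any(as.matrix(fm[, PERIPHERAL_COMPONENTS]))
  fm$trigger_kinesigenic_or_startle <-
    tri_any(as.matrix(fm[, c("trigger_kinesigenic", "trigger_startle")]))
  fm$duration_category <- dur
  fm$frequency_category <- freq
  tri_cols <- setdiff(names(fm), c("subject_id", "diagnosis",
                                   "duration_category", "frequency_category"))
  structure(fm, features = tri_cols,
            ordinal_features = c("duration_category", "frequency_category"),
            class = c("ea_feature_matrix", class(tibble::tibble())))
}

#' Per-feature non-missing counts
#'
#' @param fm An `ea_feature_matrix`.
#' @return Named integer vector: evaluable (non-unknown) cases per feature.
#' @export
feature_n <- function(fm) {
  stopifnot(inherits(fm, "ea_feature_matrix"))
  cols <- c(attr(fm, "features"), attr(fm, "ordinal_features"))
  vapply(cols, function(col) sum(!is.na(fm[[col]])), 0L)
}

ordinal_levels <- function(feature) {
  switch(feature,
    duration_category = DURATION_LEVELS,
    frequency_category = FREQUENCY_LEVELS,
    ea_stop("not an ordinal feature: %s", feature)
  )
}
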