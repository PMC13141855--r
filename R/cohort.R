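#' Construct a cohort from a case table
#'
#' Canonicalises a data frame of case records into an `ea_cohort`: missing
#' columns are added as all-unknown, enumerated columns are validated
#' (case-insensitively) against [ea_schema()], and the record-level
#' invariants are checked. Symptom/trigger/sign columns are tri-state
#' integers: `1` present, `0` absent, `NA` unknown.
#'
#' Record invariants enforced here: `(source_ref, subject_id)` pairs are
#' unique; when `trigger_data_available` is `FALSE` every trigger entry is
#' unknown; `age_onset <= age_at_report` when both are known; cached
#' `duration_category` / `frequency_category` values agree with
#' [bin_duration()] / [bin_frequency()] applied to the raw value.
#'
#' @param cases A data frame with a `subject_id` column; any subset of the
#'   schema columns may be present.
#' @param label Free-text cohort label (e.g. `"core"`, `"test"`).
#' @return A tibble of class `ea_cohort` with the full schema column set.
#' @export
cohort <- function(cases, label = "cohort") {
  if (!is.data.frame(cases)) ea_stop("`cases` must be a data frame")
  cases <- tibble::as_tibble(cases)
  if (!"subject_id" %in% names(cases)) ea_stop("column `subject_id` is required")
  extra <- setdiff(names(cases), cohort_columns())
  if (length(extra) > 0) {
    ea_stop("unrecognised column(s): %s", paste(extra, collapse = ", "),
            class = "eadiag_parse_error")
  }
  n <- nrow(cases)
  out <- tibble::tibble(.rows = n)
  for (col in cohort_columns()) {
    raw <- if (col %in% names(cases)) cases[[col]] else rep(NA, n)
    out[[col]] <- coerce_column(raw, col)
  }
  validate_cohort(out)
  structure(out, label = label,
            class = c("ea_cohort", class(tibble::tibble())))
}

coerce_column <- function(x, col) {
  kind <- column_kind(col)
  if (kind == "drug") kind <- "character" # enum check via schema_values()
  if (is.character(x)) x[!is.na(x) & !nzchar(trimws(x))] <- NA
  switch(kind,
    numeric = {
      if (is.character(x)) x <- suppressWarnings(as.numeric(x))
      v <- as.numeric(x)
      if (any(!is.na(v) & v < 0)) {
        ea_stop("column `%s`: negative value at row %d", col,
                which(!is.na(v) & v < 0)[1], class = "eadiag_parse_error")
      }
      v
    },
    tristate = {
      if (is.logical(x)) x <- as.integer(x)
      if (is.character(x)) {
        lx <- tolower(trimws(x))
        v <- rep(NA_integer_, length(x))
        v[lx %in% c("1", "present", "true", "yes")] <- 1L
        v[lx %in% c("0", "absent", "false", "no")] <- 0L
        bad <- !is.na(x) & is.na(v) & !lx %in% c("unknown", "na")
        if (any(bad)) {
          ea_stop("column `%s`: invalid tri-state value \"%s\" at row %d",
                  col, x[bad][1], which(bad)[1], class = "eadiag_parse_error")
        }
        v
      } else {
        v <- as.integer(x)
        if (any(!is.na(v) & !v %in% c(0L, 1L))) {
          ea_stop("column `%s`: tri-state values must be 0/1/NA", col,
                  class = "eadiag_parse_error")
        }
        v
      }
    },
    logical = {
      if (is.character(x)) {
        lx <- tolower(trimws(x))
        v <- rep(NA, length(x))
        v[lx %in% c("true", "1", "yes")] <- TRUE
        v[lx %in% c("false", "0", "no")] <- FALSE
        bad <- !is.na(x) & is.na(v)
        if (any(bad)) {
          ea_stop("column `%s`: invalid logical \"%s\" at row %d", col,
                  x[bad][1], which(bad)[1], class = "eadiag_parse_error")
        }
        x <- v
      }
      v <- as.logical(x)
      # availability flags default to FALSE, dominant-negative to FALSE
      v[is.na(v)] <- FALSE
      v
    },
    character = {
      v <- as.character(x)
      v <- trimws(v)
      v[!is.na(v) & !nzchar(v)] <- NA
      allowed <- schema_values(col)
      if (!is.null(allowed)) {
        idx <- match(tolower(v), tolower(allowed))
        bad <- !is.na(v) & is.na(idx)
        if (any(bad)) {
          ea_stop("column `%s`: invalid value \"%s\" at row %d (allowed: %s)",
                  col, v[bad][1], which(bad)[1], paste(allowed, collapse = ", "),
                  class = "eadiag_parse_error")
        }
        v <- allowed[idx]
      }
      v
    }
  )
}

schema_values <- function(col) {
  if (col %in% DRUGS) return(DRUG_LEVELS)
  switch(col,
    diagnosis = DIAGNOSES, sex = SEXES,
    duration_category = DURATION_LEVELS,
    frequency_category = FREQUENCY_LEVELS,
    variant_gene = GENES, variant_effect = VARIANT_EFFECTS,
    variant_acmg = ACMG_CLASSES,
    variant_functional_study = FUNCTIONAL_STUDIES,
    NULL)
}

validate_cohort <- function(x) {
  key <- paste(x$source_ref %||% "", x$subject_id, sep = "\r")
  if (anyDuplicated(key)) {
    ea_stop("duplicate subject_id within source_ref at row %d",
            which(duplicated(key))[1], class = "eadiag_validation_error")
  }
  if (any(is.na(x$subject_id))) {
    ea_stop("missing subject_id at row %d", which(is.na(x$subject_id))[1],
            class = "eadiag_validation_error")
  }
  no_trig <- !x$trigger_data_available
  for (col in TRIGGER_FEATURES) {
    bad <- no_trig & !is.na(x[[col]])
    if (any(bad)) {
      ea_stop("row %d: `%s` is set but trigger_data_available is false",
              which(bad)[1], col, class = "eadiag_validation_error")
    }
  }
  both <- !is.na(x$age_onset) & !is.na(x$age_at_report)
  if (any(both & x$age_onset > x$age_at_report)) {
    ea_stop("row %d: age_onset exceeds age_at_report",
            which(both & x$age_onset > x$age_at_report)[1],
            class = "eadiag_validation_error")
  }
  chk <- !is.na(x$duration_category) & !is.na(x$attack_duration_minutes)
  if (any(chk)) {
    expect <- vapply(x$attack_duration_minutes[chk], bin_duration, "")
    if (any(expect != x$duration_category[chk])) {
      ea_stop("row %d: cached duration_category disagrees with binned raw value",
              which(chk)[which(expect != x$duration_category[chk])[1]],
              class = "eadiag_validation_error")
    }
  }
  chk <- !is.na(x$frequency_category) & !is.na(x$attack_frequency_per_month)
  if (any(chk)) {
    expect <- vapply(x$attack_frequency_per_month[chk], bin_frequency, "")
    if (any(expect != x$frequency_category[chk])) {
      ea_stop("row %d: cached frequency_category disagrees with binned raw value",
              which(chk)[which(expect != x$frequency_category[chk])[1]],
              class = "eadiag_validation_error")
    }
  }
  invisible(x)
}

#' @export
print.ea_cohort <- function(x, ...) {
  cat(sprintf("<ea_cohort \"%s\": %d cases (EA1 %d, EA2 %d, unlabeled %d)>\n",
              attr(x, "label") %||% "cohort", nrow(x),
              sum(x$diagnosis == "EA1", na.rm = TRUE),
              sum(x$diagnosis == "EA2", na.rm = TRUE),
              sum(is.na(x$diagnosis))))
  NextMethod()
}

#' Read a cohort file
#'
#' Reads a cohort from the package's flat CSV dialect (UTF-8, one column per
#' feature, tri-states encoded `1`/`0`/empty) or from its JSON dialect
#' (array of case objects with a nested `variant` object). Enumerated values
#' are matched case-insensitively; empty cells become unknown. Row order is
#' preserved.
#'
#' @param path File to read.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @param label Cohort label; defaults to the file name.
#' @return An `ea_cohort`.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json"),
                        label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) ea_stop("file not found: %s", path)
  label <- label %||% basename(path)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          na.strings = character(), fileEncoding = "UTF-8")
    cohort(df, label = label)
  } else {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!is.null(recs$cases)) {
      label <- recs$label %||% label
      recs <- recs$cases
    }
    rows <- lapply(recs, json_case_to_row)
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
    }))
    cohort(tibble::as_tibble(df), label = label)
  }
}

json_case_to_row <- function(rec) {
  variant <- rec$variant
  rec$variant <- NULL
  if (!is.null(variant)) {
    names(variant) <- paste0("variant_", names(variant))
    rec <- c(rec, variant)
  }
  bad <- setdiff(names(rec), cohort_columns())
  if (length(bad) > 0) {
    ea_stop("unrecognised field(s) in JSON case: %s", paste(bad, collapse = ", "),
            class = "eadiag_parse_error")
  }
  out <- lapply(cohort_columns(), function(col) {
    v <- rec[[col]]
    if (is.null(v)) NA else v
  })
  names(out) <- cohort_columns()
  out
}

#' Write a cohort file
#'
#' The inverse of [read_cohort()]: writes the flat CSV dialect or the nested
#' JSON dialect with full fidelity (tri-states, unknowns, variant
#' subfields). `write_cohort()` after a read of its own output is
#' byte-identical (serialisation is a fixed point).
#'
#' @param x An `ea_cohort`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "ea_cohort"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    out <- lapply(cohort_columns(), function(col) encode_csv_column(x[[col]], col))
    names(out) <- cohort_columns()
    df <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                       fileEncoding = "UTF-8", na = "")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) ea_stop("cannot write to %s", path)
  } else {
    cases <- lapply(seq_len(nrow(x)), function(i) row_to_json_case(x[i, ]))
    json <- jsonlite::toJSON(list(label = attr(x, "label") %||% "cohort",
                                  cases = cases),
                             auto_unbox = TRUE, null = "null", na = "null",
                             digits = NA, pretty = TRUE)
    ok <- tryCatch({ writeLines(json, path, useBytes = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok) ea_stop("cannot write to %s", path)
  }
  invisible(path)
}

encode_csv_column <- function(v, col) {
  kind <- column_kind(col)
  out <- switch(kind,
    tristate = ifelse(is.na(v), "", as.character(v)),
    logical = ifelse(v, "true", "false"),
    numeric = ifelse(is.na(v), "", vapply(v, function(z) {
      if (is.na(z)) "" else format(z, digits = 15, scientific = FALSE, trim = TRUE)
    }, "")),
    ifelse(is.na(v), "", as.character(v))
  )
  out
}

row_to_json_case <- function(row) {
  rec <- list()
  for (col in setdiff(cohort_columns(), VARIANT_COLUMNS)) {
    val <- row[[col]]
    if (!is.na(val)) rec[[col]] <- if (col %in% TRISTATE_COLUMNS) as.integer(val) else val
    if (column_kind(col) == "logical") rec[[col]] <- val
  }
  if (!is.na(row$variant_gene)) {
    variant <- list()
    for (col in VARIANT_COLUMNS) {
      val <- row[[col]]
      nm <- sub("^variant_", "", col)
      if (col == "variant_dominant_negative") variant[[nm]] <- val
      else if (!is.na(val)) {
        variant[[nm]] <- if (col %in% TRISTATE_COLUMNS) as.integer(val) else val
      }
    }
    rec$variant <- variant
  }
  rec
}

#' Filter a cohort with a registered predicate
#'
#' Registered predicates: `"identity"` (keep all), `"gene"` (cases whose
#' variant is in `gene`), `"diagnostic_variant_only"` (pathogenic or likely
#' pathogenic and not a repeat expansion, mirroring the curation exclusion of
#' non-diagnostic variants), `"haploinsufficiency"` (cases whose diagnostic
#' variant falls in `group`, `"haploinsufficient"` or
#' `"non_haploinsufficient"`), and `"has_field"` (cases with a non-missing
#' value in column `field`). The number of removed cases is reported via
#' `message()` and stored in the `removed` attribute.
#'
#' @param x An `ea_cohort`.
#' @param predicate Name of a registered filter.
#' @param gene,group,field Predicate parameters.
#' @param quiet Suppress the removed-count message.
#' @return The filtered `ea_cohort`.
#' @export
filter_cohort <- function(x, predicate, gene = NULL, group = NULL,
                          field = NULL, quiet = FALSE) {
  stopifnot(inherits(x, "ea_cohort"))
  keep <- switch(predicate,
    identity = rep(TRUE, nrow(x)),
    gene = {
      if (is.null(gene) || !gene %in% GENES)
        ea_stop("filter `gene` requires gene = KCNA1 or CACNA1A",
                class = "eadiag_config_error")
      !is.na(x$variant_gene) & x$variant_gene == gene
    },
    diagnostic_variant_only = diagnostic_variant_mask(x),
    haploinsufficiency = {
      if (is.null(group) ||
          !group %in% c("haploinsufficient", "non_haploinsufficient"))
        ea_stop("filter `haploinsufficiency` requires group = haploinsufficient or non_haploinsufficient",
                class = "eadiag_config_error")
      hap <- haploinsufficiency_mask(x)
      if (group == "haploinsufficient") hap$haplo else hap$non_haplo
    },
    has_field = {
      if (is.null(field) || !field %in% cohort_columns())
        ea_stop("filter `has_field` requires a valid `field`",
                class = "eadiag_config_error")
      !is.na(x[[field]])
    },
    ea_stop("unknown filter predicate: %s", predicate,
            class = "eadiag_config_error")
  )
  removed <- sum(!keep)
  out <- x[keep, , drop = FALSE]
  attr(out, "label") <- attr(x, "label")
  attr(out, "removed") <- removed
  class(out) <- class(x)
  if (!quiet) message(sprintf("filter_cohort(%s): removed %d of %d cases",
                              predicate, removed, nrow(x)))
  out
}
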