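#' Is a variant diagnostic?
#'
#' A variant supports a molecular diagnosis when its ACMG class is
#' pathogenic or likely pathogenic and it is not a trinucleotide repeat
#' expansion (repeat expansions in CACNA1A cause SCA6, a distinct
#' degenerative phenotype, and are excluded from episodic-ataxia cohorts).
#'
#' @param variant A named list or one-row data frame with fields `acmg`
#'   (or `variant_acmg`) and `effect` (or `variant_effect`).
#' @return `TRUE` or `FALSE`.
#' @export
variant_field <- function(variant, name) {
  for (key in c(name, paste0("variant_", name))) {
    if (key %in% names(variant)) return(variant[[key]])
  }
  NULL
}

is_diagnostic <- function(variant) {
  acmg <- variant_field(variant, "acmg")
  effect <- variant_field(variant, "effect")
  if (is.null(acmg) || is.na(acmg)) ea_stop("variant has no ACMG class")
  isTRUE(acmg %in% c("pathogenic", "likely_pathogenic")) &&
    !isTRUE(effect == "repeat_expansion")
}

diagnostic_variant_mask <- function(x) {
  !is.na(x$variant_acmg) &
    x$variant_acmg %in% c("pathogenic", "likely_pathogenic") &
    (is.na(x$variant_effect) | x$variant_effect != "repeat_expansion")
}

#' Assign a variant to a functional group
#'
#' Implements the loss-of-function / gain-of-function / unknown grouping
#' used for genotype-phenotype comparison:
#'
#' * truncating effects (nonsense, frameshift, out-of-frame deletion, or a
#'   splice change predicted to introduce a premature stop) with predicted
#'   nonsense-mediated decay are LoF through haploinsufficiency;
#' * any variant with a functional study showing decreased channel function
#'   is LoF (non-haploinsufficient unless the truncating/NMD rule also
#'   applies); dominant-negative missense variants keep their flag but are
#'   grouped LoF;
#' * a functional study showing increased function gives GoF;
#' * otherwise variants predicted to be translated (missense, in-frame
#'   deletion, NMD-escaping truncation, in-frame splice change) are of
#'   unknown effect.
#'
#' A truncating NMD-predicted variant whose functional study reports
#' increased function is contradictory and raises a validation error.
#'
#' @param variant A named list or one-row data frame with fields `effect`,
#'   `nmd_predicted` (1/0/NA), `functional_study`, `dominant_negative`
#'   (optionally prefixed `variant_`).
#' @return A list with `group` (`"LoF"`, `"GoF"` or `"unknown"`),
#'   `haploinsufficient` (only meaningful for LoF) and `dominant_negative`.
#' @export
assign_functional_group <- function(variant) {
  effect <- variant_field(variant, "effect")
  nmd <- variant_field(variant, "nmd_predicted") %||% NA
  fs <- variant_field(variant, "functional_study") %||% "none"
  dn <- isTRUE(variant_field(variant, "dominant_negative"))
  if (is.null(effect) || is.na(effect)) ea_stop("variant has no mutational effect")
  if (is.na(fs)) fs <- "none"
  haplo <- effect %in% TRUNCATING_EFFECTS && !is.na(nmd) && nmd == 1L
  if (haplo && fs == "increased_function") {
    ea_stop("contradictory evidence: NMD-predicted truncation with increased-function study",
            class = "eadiag_validation_error")
  }
  group <-
    if (haplo || fs == "decreased_function") "LoF"
    else if (fs == "increased_function") "GoF"
    else "unknown"
  list(group = group,
       haploinsufficient = group == "LoF" && haplo,
       dominant_negative = dn)
}

# vectorised haploinsufficiency classification over cohort rows;
# only cases carrying a diagnostic variant are eligible
haploinsufficiency_mask <- function(x) {
  diag_var <- diagnostic_variant_mask(x)
  haplo <- diag_var &
    !is.na(x$variant_effect) & x$variant_effect %in% TRUNCATING_EFFECTS &
    !is.na(x$variant_nmd_predicted) & x$variant_nmd_predicted == 1L
  list(haplo = haplo, non_haplo = diag_var & !haplo)
}

#' Split a cohort into haploinsufficient vs non-haploinsufficient carriers
#'
#' Restricted to cases carrying a diagnostic variant of `gene`, the cohort
#' is split into carriers of haploinsufficient variants (truncating,
#' NMD-predicted) and carriers of every other diagnostic variant (LoF by
#' functional study, dominant-negative missense, GoF, unknown effect).
#' Cases without a variant record are excluded with a warning.
#'
#' @param x An `ea_cohort`.
#' @param gene `"KCNA1"` or `"CACNA1A"`.
#' @return A list of two `ea_cohort`s: `haploinsufficient` and
#'   `non_haploinsufficient`.
#' @export
haploinsufficiency_partition <- function(x, gene) {
  stopifnot(inherits(x, "ea_cohort"), gene %in% GENES)
  in_gene <- !is.na(x$variant_gene) & x$variant_gene == gene
  no_variant <- is.na(x$variant_gene)
  if (any(no_variant)) {
    ea_warn("%d case(s) without a variant record excluded from the partition",
            sum(no_variant))
  }
  masks <- haploinsufficiency_mask(x)
  sub <- function(keep, side) {
    out <- x[keep, , drop = FALSE]
    attr(out, "label") <- paste0(attr(x, "label") %||% "cohort", "/", side)
    class(out) <- class(x)
    out
  }
  res <- list(
    haploinsufficient = sub(in_gene & masks$haplo, "haploinsufficient"),
    non_haploinsufficient = sub(in_gene & masks$non_haplo, "non_haploinsufficient")
  )
  message(sprintf("haploinsufficiency_partition(%s): %d haploinsufficient, %d non-haploinsufficient",
                  gene, nrow(res$haploinsufficient),
                  nrow(res$non_haploinsufficient)))
  res
}
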