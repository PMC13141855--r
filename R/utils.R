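#' @keywords internal
"_PACKAGE"

# Round half away from zero, the convention used in the report tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percent with one decimal, half-up.
as_pct <- function(x) round_half_up(100 * x, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

ea_stop <- function(fmt, ..., class = "eadiag_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

ea_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar coercion helpers used by the readers
chr1 <- function(x) if (length(x) == 0 || is.na(x) || !nzchar(x)) NA_character_ else as.character(x)
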