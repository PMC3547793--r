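#' @keywords internal
"_PACKAGE"

# Signal a classed error so callers/tests can match on condition class
# (e.g. "rilexpr_format", "rilexpr_parents-missing").
ril_abort <- function(code, msg) {
  stop(errorCondition(msg, class = c(paste0("rilexpr_", code), "rilexpr_error")))
}

#' Haldane map function
#'
#' Converts a genetic distance in centiMorgans into a recombination fraction
#' assuming crossovers occur as a Poisson process with no interference.
#'
#' @param d_cm Genetic distance in cM (vectorised, `d_cm >= 0`).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d_cm) {
  0.5 * (1 - exp(-2 * d_cm / 100))
}

# quantile shorthand used throughout (empirical, type 7)
emp_quantile <- function(x, p) unname(stats::quantile(x, p, names = FALSE, type = 7))

`%||%` <- function(a, b) if (is.null(a)) b else a

# A/B/H character calls -> numeric codes: A (B73) = -1, B (Mo17) = +1, H/NA = NA.
# Heterozygous calls are treated as missing in all two-class statistics.
geno_numeric <- function(calls) {
  out <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  out[calls == "A"] <- -1
  out[calls == "B"] <- 1
  out
}
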