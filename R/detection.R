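#' Calibrate RPKM detection thresholds from non-genic background
#'
#' The cutoff at FDR level `f` is the empirical `1 - f` quantile of the
#' background RPKM distribution: by construction a fraction `f` of non-genic
#' fragments exceeds it. Monotonicity (cutoffs strictly non-increasing as FDR
#' grows) is enforced.
#'
#' @param background Numeric vector of non-genic RPKM values (length >= 100).
#' @param fdr_levels FDR levels to calibrate (default the grid 0.05, 0.01,
#'   0.005, 0.001).
#' @return A `detection_thresholds` object: named cutoff vector plus a
#'   `provenance` field (`"calibrated"`).
#' @export
calibrate_thresholds <- function(background,
                                 fdr_levels = c(0.05, 0.01, 0.005, 0.001)) {
  if (length(background) < 100)
    ril_abort("no-background", "background must contain at least 100 values")
  fdr_levels <- sort(fdr_levels, decreasing = TRUE)
  cut <- vapply(fdr_levels, function(f) emp_quantile(background, 1 - f), numeric(1))
  cut <- cummax(cut)  # smaller FDR never gets a smaller cutoff
  nm <- vapply(fdr_levels, format, character(1))
  structure(list(cutoffs = stats::setNames(cut, nm),
                 provenance = "calibrated"),
            class = "detection_thresholds")
}

#' Reference detection thresholds for maize shoot-apex RNA-seq
#'
#' RPKM cutoffs calibrated on 10,000 non-genic fragments of B73 shoot-apex
#' RNA-seq data: 0.055, 1.03, 2.02 and 5.41 at FDR 0.05, 0.01, 0.005 and
#' 0.001. Usable in place of [calibrate_thresholds()] when no background
#' vector is at hand; flagged by provenance.
#'
#' @return A `detection_thresholds` object with provenance `"published"`.
#' @export
reference_thresholds <- function() {
  structure(list(cutoffs = c("0.05" = 0.055, "0.01" = 1.03,
                             "0.005" = 2.02, "0.001" = 5.41),
                 provenance = "published"),
            class = "detection_thresholds")
}

#' @export
print.detection_thresholds <- function(x, ...) {
  cat("detection_thresholds (", x$provenance, "):\n", sep = "")
  print(x$cutoffs)
  invisible(x)
}

# pick the cutoff for a given FDR level out of a thresholds object
threshold_at <- function(thresholds, fdr = 0.05) {
  key <- format(fdr)
  if (!key %in% names(thresholds$cutoffs))
    ril_abort("format", paste("no cutoff calibrated at FDR", key))
  unname(thresholds$cutoffs[key])
}

#' Three-state presence/absence calls
#'
#' A value is `present` when RPKM >= cutoff, `absent` when RPKM is exactly 0,
#' and `ambiguous` otherwise: intermediate values are assigned neither call.
#' The boundary value counts as present.
#'
#' @param expr An [expression_matrix()].
#' @param cutoff Positive RPKM cutoff (e.g. 1.03 at FDR 0.01).
#' @return A character matrix (genes x samples) of class `presence_calls`
#'   with the cutoff stored as an attribute.
#' @export
call_presence <- function(expr, cutoff) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (cutoff <= 0) ril_abort("format", "cutoff must be positive")
  v <- expr$values
  out <- matrix("ambiguous", nrow(v), ncol(v), dimnames = dimnames(v))
  out[v >= cutoff] <- "present"
  out[v == 0] <- "absent"
  attr(out, "cutoff") <- cutoff
  attr(out, "roles") <- expr$roles
  class(out) <- c("presence_calls", class(out))
  out
}

#' Detected and core expressed gene sets
#'
#' A gene is *detected* when it is present (at the FDR 0.05 cutoff) in at
#' least `detect_fraction` of the RILs or in at least one parent. The *core*
#' set is the subset additionally present in both parents and in at least
#' `core_fraction` of the RILs. `core_set` is always a subset of
#' `detected_set`. Fractions are taken over RILs only; parents enter through
#' their explicit clauses.
#'
#' @param expr An [expression_matrix()].
#' @param thresholds A `detection_thresholds` object containing an FDR 0.05
#'   cutoff, or a single numeric cutoff.
#' @param detect_fraction,core_fraction RIL presence fractions (defaults 0.10
#'   and 0.90).
#' @return A list with character vectors `detected_set` and `core_set`.
#' @export
expressed_gene_sets <- function(expr, thresholds, detect_fraction = 0.10,
                                core_fraction = 0.90) {
  stopifnot(inherits(expr, "expression_matrix"))
  cutoff <- if (inherits(thresholds, "detection_thresholds"))
    threshold_at(thresholds, 0.05) else as.numeric(thresholds)
  rv <- ril_values(expr)
  if (ncol(rv) == 0) ril_abort("no-rils", "expression matrix has no RIL samples")
  pres <- rv >= cutoff
  frac <- rowMeans(pres)
  b73 <- parent_values(expr, "B73") >= cutoff
  mo17 <- parent_values(expr, "Mo17") >= cutoff
  detected <- frac >= detect_fraction | b73 | mo17
  core <- detected & b73 & mo17 & frac >= core_fraction
  list(detected_set = rownames(rv)[detected], core_set = rownames(rv)[core])
}
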