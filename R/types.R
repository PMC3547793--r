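#' Expression matrix with sample roles
#'
#' Container for gene-level RPKM values across the two parents, optional F1
#' hybrids and the RILs. Values are non-negative, genes are rows, samples are
#' columns; each sample carries a role (`B73_parent`, `Mo17_parent`, `F1`,
#' `RIL`) and there is exactly one sample per parent role.
#'
#' @param values Numeric matrix (genes x samples) with unique row and column
#'   names; all entries `>= 0`.
#' @param roles Named character vector mapping every sample id to one of
#'   `"B73_parent"`, `"Mo17_parent"`, `"F1"`, `"RIL"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, roles) {
  if (!is.matrix(values) || !is.numeric(values))
    ril_abort("format", "values must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) || is.null(colnames(values)))
    ril_abort("format", "values must carry gene and sample names")
  if (anyDuplicated(rownames(values))) ril_abort("format", "gene ids must be unique")
  if (anyDuplicated(colnames(values))) ril_abort("format", "sample ids must be unique")
  if (any(values < 0, na.rm = TRUE)) ril_abort("format", "RPKM values must be non-negative")
  roles <- roles[colnames(values)]
  if (any(is.na(names(roles))) || length(roles) != ncol(values))
    ril_abort("format", "every sample needs a role")
  ok <- roles %in% c("B73_parent", "Mo17_parent", "F1", "RIL")
  if (!all(ok)) ril_abort("format", "unknown sample role")
  if (sum(roles == "B73_parent") != 1 || sum(roles == "Mo17_parent") != 1)
    ril_abort("parents-missing", "exactly one B73_parent and one Mo17_parent sample required")
  structure(list(values = values, roles = roles), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d RILs, %d F1)\n",
              nrow(x$values), ncol(x$values),
              sum(x$roles == "RIL"), sum(x$roles == "F1")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Sample accessors for an expression matrix
#'
#' `ril_values()` returns the genes x RILs sub-matrix, `parent_values()` the
#' named vector of one parent's values, `f1_values()` the genes x F1 matrix.
#'
#' @param x An `expression_matrix`.
#' @param parent `"B73"` or `"Mo17"`.
#' @return Numeric matrix or vector.
#' @export
ril_values <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  x$values[, x$roles == "RIL", drop = FALSE]
}

#' @rdname ril_values
#' @export
parent_values <- function(x, parent = c("B73", "Mo17")) {
  parent <- match.arg(parent)
  role <- paste0(parent, "_parent")
  x$values[, which(x$roles == role)]
}

#' @rdname ril_values
#' @export
f1_values <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  x$values[, x$roles == "F1", drop = FALSE]
}

#' Genetic map
#'
#' One row per marker with chromosome, genetic (cM) and physical (bp)
#' position. Markers are stored sorted by chromosome then cM (ties broken by
#' bp).
#'
#' @param marker,chrom Character vectors of marker ids and chromosome labels.
#' @param cm Genetic positions in cM (`>= 0`).
#' @param bp Physical positions in bp (`>= 1`).
#' @return A `genetic_map` data frame.
#' @export
genetic_map <- function(marker, chrom, cm, bp) {
  if (anyDuplicated(marker)) ril_abort("format", "marker ids must be unique")
  if (any(cm < 0)) ril_abort("format", "cM positions must be >= 0")
  if (any(bp < 1)) ril_abort("format", "bp positions must be >= 1")
  df <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                   cm = as.numeric(cm), bp = as.numeric(bp),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$cm, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Genotype matrix
#'
#' Marker x RIL calls with codes `A` (B73 allele), `B` (Mo17 allele), `H`
#' (residual heterozygote) or `NA` (missing). RIL populations are near-fully
#' inbred, so the fraction of `H` calls must not exceed 5%.
#'
#' @param calls Character matrix (markers x RILs).
#' @param map A `genetic_map` whose marker order the rows must follow.
#' @return A `genotype_matrix` (character matrix with a `map` attribute check
#'   performed; the map itself is kept alongside by the caller).
#' @export
genotype_matrix <- function(calls, map) {
  if (!is.matrix(calls)) ril_abort("format", "calls must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    ril_abort("format", "calls must carry marker and RIL names")
  if (!identical(rownames(calls), map$marker))
    ril_abort("marker-mismatch", "marker rows must match the genetic map order")
  bad <- !(calls %in% c("A", "B", "H") | is.na(calls))
  if (any(bad)) ril_abort("format", "genotype codes must be A, B, H or NA")
  h_frac <- mean(calls == "H", na.rm = TRUE)
  if (is.finite(h_frac) && h_frac > 0.05)
    ril_abort("format", sprintf("heterozygote fraction %.3f exceeds 5%%", h_frac))
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' Gene annotation table
#'
#' One row per gene: 1-based inclusive coordinates, strand, exon count of the
#' longest transcript, syntenic status and gene-family size.
#'
#' @param gene,chrom,strand Character vectors.
#' @param start,end Integer coordinates, `start <= end`.
#' @param exon_count Integer `>= 1`.
#' @param syntenic One of `"syntenic"`, `"inserted"`, `"unknown"`.
#' @param family_size Integer `>= 1`.
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(gene, chrom, start, end, strand = "+",
                            exon_count = 1L, syntenic = "unknown",
                            family_size = 1L) {
  if (any(end < start)) ril_abort("format", "gene end < start")
  if (any(exon_count < 1)) ril_abort("format", "exon_count must be >= 1")
  if (any(family_size < 1)) ril_abort("format", "family_size must be >= 1")
  if (!all(syntenic %in% c("syntenic", "inserted", "unknown")))
    ril_abort("format", "syntenic must be syntenic/inserted/unknown")
  df <- data.frame(gene = as.character(gene), chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(gene)),
                   exon_count = rep_len(as.integer(exon_count), length(gene)),
                   syntenic = rep_len(as.character(syntenic), length(gene)),
                   family_size = rep_len(as.integer(family_size), length(gene)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the workflow with their defaults: the
#' FDR grid of detection cutoffs, detected/core population fractions, the
#' paramutation z-rules, LOD/permutation settings, hotspot window and density
#' cutoff, segregation and epistasis alphas, and the CNV expression filters.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fdr_grid = c("0.05" = 0.055, "0.01" = 1.03, "0.005" = 2.02, "0.001" = 5.41),
    detect_fraction = 0.10,
    core_fraction = 0.90,
    fold_change_min = 2,
    near_sd = 2,
    far_sd = 3,
    lod_alpha = 0.05,
    lod_drop = 1.0,
    merge_cm = 10,
    hotspot_window_mb = 1,
    hotspot_alpha = 0.01,
    density_cutoff = 1.25,
    seg_alpha = 0.01,
    epistasis_alpha = 0.05,
    cnv_expr_fraction = 0.40,
    cnv_min_per_class = 40,
    rng_seed = NULL
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) ril_abort("format", paste("unknown config field:", unknown[1]))
  cfg[names(ov)] <- ov
  fr <- c(cfg$detect_fraction, cfg$core_fraction, cfg$cnv_expr_fraction)
  al <- c(cfg$lod_alpha, cfg$hotspot_alpha, cfg$seg_alpha, cfg$epistasis_alpha)
  if (any(fr <= 0 | fr >= 1)) ril_abort("format", "fractions must lie in (0,1)")
  if (any(al <= 0 | al >= 1)) ril_abort("format", "alpha levels must lie in (0,1)")
  if (any(cfg$fdr_grid < 0)) ril_abort("format", "cutoffs must be >= 0")
  structure(cfg, class = "pipeline_config")
}
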