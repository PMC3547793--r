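#' Chi-square segregation ratio test
#'
#' Goodness-of-fit of (present, absent) RIL counts against a stated ratio,
#' df = 1, no continuity correction.
#'
#' @param n_present,n_absent Counts (total `>= 1`).
#' @param ratio Length-2 expected ratio, present:absent (default `c(1, 1)`).
#' @return The p-value.
#' @export
segregation_chisq <- function(n_present, n_absent, ratio = c(1, 1)) {
  tot <- n_present + n_absent
  if (tot < 1) ril_abort("empty", "no informative RILs")
  exp_counts <- tot * ratio / sum(ratio)
  stat <- sum((c(n_present, n_absent) - exp_counts)^2 / exp_counts)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Classify a gene's presence/absence segregation pattern
#'
#' Types (fractions over all RILs; ambiguous calls excluded from the test
#' counts):
#' * `I` - present in both parents but absent in more than `min_frac` of RILs;
#' * `II` - absent in both parents but present in at least `min_frac` of RILs;
#' * one-parent genes: `mendelian_50` when a 1:1 present:absent ratio is not
#'   rejected at `seg_alpha`; otherwise `IIIA` (present fraction below 1/2) or
#'   `IIIB` (above);
#' * `none` otherwise.
#'
#' @param parent_calls Named character vector with entries `B73` and `Mo17`
#'   (`"present"`/`"absent"`/`"ambiguous"`).
#' @param ril_calls Character vector of per-RIL calls.
#' @param min_frac RIL fraction rule (default 0.10).
#' @param seg_alpha Chi-square level (default 0.01).
#' @return A one-row data frame: `parent_pattern`, `n_present`, `n_absent`,
#'   `n_ambiguous`, `p_1to1`, `p_1to3`, `p_3to1`, `seg_class`; or `NULL`
#'   (with a warning) when a parent call is ambiguous.
#' @export
classify_presence_pattern <- function(parent_calls, ril_calls,
                                      min_frac = 0.10, seg_alpha = 0.01) {
  b <- parent_calls[["B73"]]; m <- parent_calls[["Mo17"]]
  if (b == "ambiguous" || m == "ambiguous") {
    warning("ambiguous parent call; gene skipped")
    return(NULL)
  }
  n_rils <- length(ril_calls)
  n_p <- sum(ril_calls == "present")
  n_a <- sum(ril_calls == "absent")
  n_u <- n_rils - n_p - n_a
  tot <- n_p + n_a
  p11 <- if (tot >= 1) segregation_chisq(n_p, n_a, c(1, 1)) else NA_real_
  p13 <- if (tot >= 1) segregation_chisq(n_p, n_a, c(1, 3)) else NA_real_
  p31 <- if (tot >= 1) segregation_chisq(n_p, n_a, c(3, 1)) else NA_real_
  parent_pattern <- if (b == "present" && m == "present") "both"
  else if (b == "absent" && m == "absent") "neither"
  else if (b == "present") "B73_only" else "Mo17_only"
  cls <- "none"
  if (parent_pattern == "both") {
    if (n_a / n_rils > min_frac) cls <- "I"
  } else if (parent_pattern == "neither") {
    if (n_p / n_rils >= min_frac) cls <- "II"
  } else if (tot >= 1) {
    if (!is.na(p11) && p11 >= seg_alpha) cls <- "mendelian_50"
    else if (n_p / tot < 0.5) cls <- "IIIA"
    else if (n_p / tot > 0.5) cls <- "IIIB"
  }
  data.frame(parent_pattern = parent_pattern, n_present = n_p,
             n_absent = n_a, n_ambiguous = n_u, p_1to1 = p11, p_1to3 = p13,
             p_3to1 = p31, seg_class = cls, stringsAsFactors = FALSE)
}

#' Segregation typing across all genes of a presence-call matrix
#'
#' @param calls A `presence_calls` matrix from [call_presence()].
#' @param min_frac,seg_alpha See [classify_presence_pattern()].
#' @return Data frame with one row per classifiable gene.
#' @export
segregation_table <- function(calls, min_frac = 0.10, seg_alpha = 0.01) {
  roles <- attr(calls, "roles")
  b_col <- which(roles == "B73_parent"); m_col <- which(roles == "Mo17_parent")
  ril_cols <- which(roles == "RIL")
  rows <- lapply(rownames(calls), function(g) {
    rec <- withCallingHandlers(
      classify_presence_pattern(
        c(B73 = calls[g, b_col], Mo17 = calls[g, m_col]),
        calls[g, ril_cols], min_frac, seg_alpha),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(rec)) NULL else cbind(data.frame(gene = g), rec)
  })
  do.call(rbind, rows)
}

#' Quarter / three-quarter expressing candidates
#'
#' Genes whose presence fraction is consistent with two-locus control:
#' the quarter set holds Type II/IIIA genes not rejecting a 1:3
#' present:absent ratio, the three-quarter set Type I/IIIB genes not
#' rejecting 3:1.
#'
#' @param types Data frame from [segregation_table()].
#' @param seg_alpha Non-rejection level (default 0.01).
#' @return A list with `quarter_set` and `three_quarter_set` gene vectors.
#' @export
ratio_candidates <- function(types, seg_alpha = 0.01) {
  q <- types$gene[types$seg_class %in% c("II", "IIIA") &
                    !is.na(types$p_1to3) & types$p_1to3 >= seg_alpha]
  tq <- types$gene[types$seg_class %in% c("I", "IIIB") &
                     !is.na(types$p_3to1) & types$p_3to1 >= seg_alpha]
  list(quarter_set = q, three_quarter_set = tq)
}

#' Collapse markers into recombination blocks
#'
#' Consecutive markers on a chromosome with identical genotype vectors across
#' all RILs form one block; one representative marker per block is returned.
#'
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @return A list with `representatives` (marker ids, first of each block),
#'   `block_id` (integer vector over markers) and `n_blocks`.
#' @export
collapse_blocks <- function(genotypes, map) {
  if (nrow(genotypes) == 0) ril_abort("format", "empty genotype matrix")
  key <- apply(genotypes, 1, function(r) paste(ifelse(is.na(r), ".", r), collapse = ""))
  m <- nrow(map)
  new_block <- c(TRUE, map$chrom[-1] != map$chrom[-m] | key[-1] != key[-m])
  block_id <- cumsum(new_block)
  reps <- map$marker[new_block]
  list(representatives = reps, block_id = block_id, n_blocks = max(block_id))
}

# closed-form two-locus fits on the four homozygous genotype classes ---------
# continuous trait: full model = class means (one-way ANOVA over 4 cells);
# additive model y ~ a + b fitted by least squares; interaction = full vs
# additive F-test. binary trait: binomial deviances; full model is saturated
# over the 4 cells. model_p is computed for every pair; the interaction term
# is only fitted for the winning pair.
.pair_model_continuous <- function(y, a, b) {
  cls <- (a + 3) / 2 + (b + 1)              # 1..4 over {-1,1} x {-1,1}
  n <- length(y)
  s <- rowsum(y, cls); s2 <- rowsum(y^2, cls)
  nn <- tabulate(cls, 4)
  mu <- stats::setNames(as.vector(s) / nn, c("AA", "BA", "AB", "BB"))
  rss_full <- sum(s2) - sum(s^2 / nn)
  tss <- sum(y^2) - sum(y)^2 / n
  df2 <- n - 4
  f_model <- ((tss - rss_full) / 3) / (rss_full / df2)
  list(model_p = stats::pf(f_model, 3, df2, lower.tail = FALSE),
       class_means = mu, rss_full = rss_full, df2 = df2)
}

.pair_interaction_continuous <- function(y, a, b, fit) {
  rss_add <- .rss(cbind(1, a, b), y)
  f_int <- ((rss_add - fit$rss_full) / 1) / (fit$rss_full / fit$df2)
  stats::pf(f_int, 1, fit$df2, lower.tail = FALSE)
}

.pair_model_binary <- function(y, a, b) {
  cls <- (a + 3) / 2 + (b + 1)
  k <- as.vector(rowsum(y, cls))
  nn <- tabulate(cls, 4)
  ll_bin <- function(k, nn) {
    p <- k / nn
    sum(ifelse(k > 0, k * log(p), 0) +
          ifelse(nn - k > 0, (nn - k) * log(1 - p), 0))
  }
  lrt <- 2 * (ll_bin(k, nn) - ll_bin(sum(k), sum(nn)))
  list(model_p = stats::pchisq(lrt, df = 3, lower.tail = FALSE),
       class_means = stats::setNames(k / nn, c("AA", "BA", "AB", "BB")),
       k = k, nn = nn)
}

.pair_interaction_binary <- function(y, a, b, fit) {
  k <- fit$k; nn <- fit$nn
  # aggregated class order is (a,b) = (-1,-1), (1,-1), (-1,1), (1,1)
  av <- c(-1, 1, -1, 1); bv <- c(-1, -1, 1, 1)
  sep <- any(nn > 0 & (k == 0 | k == nn))
  tryCatch({
    gfit <- suppressWarnings(stats::glm(cbind(k, nn - k) ~ av + bv,
                                        family = stats::binomial()))
    if (sep && !gfit$converged) stop("separation")
    stats::pchisq(gfit$deviance, df = 1, lower.tail = FALSE)
  }, error = function(e) {
    # exact fallback under separation: Fisher test on the interaction
    # contrast a*b vs presence
    stats::fisher.test(table(factor(a * b, levels = c(-1, 1)),
                             factor(y, levels = c(0, 1))))$p.value
  })
}

#' Genome-wide two-locus epistasis scan
#'
#' Fits `trait ~ A + B + A:B` for every pair of recombination-block
#' representative markers (linear model for a continuous trait, binomial
#' model for a 0/1 presence trait with an exact fallback under perfect
#' separation) and returns the minimum-p pair. The gating statistic is the
#' full two-locus model against the null (`model_p`); the interaction term's
#' p-value is reported alongside. The significance threshold is
#' Bonferroni-adjusted by the number of block pairs:
#' `alpha_adj = alpha / (B (B-1) / 2)`.
#'
#' @param y Trait vector aligned with RIL columns: numeric RPKM or 0/1
#'   presence (logical accepted).
#' @param genotypes A [genotype_matrix()].
#' @param map The matching [genetic_map()].
#' @param gene_row Optional [gene_annotation()] row of the gene, to flag a
#'   cis locus (marker within `cis_margin_mb` of the gene on the same
#'   chromosome).
#' @param alpha Family-wise level before adjustment (default 0.05).
#' @param min_complete Minimum RILs with complete data per pair (default 40).
#' @param cis_margin_mb Cis window (default 1 Mb).
#' @return A list: `marker_a`, `marker_b`, `model_p`, `interaction_p`,
#'   `class_means`, `alpha_adj`, `n_blocks`, `passes_alpha`, `cis_locus`;
#'   or `NULL` when no pair is testable.
#' @export
epistasis_scan <- function(y, genotypes, map, gene_row = NULL, alpha = 0.05,
                           min_complete = 40, cis_margin_mb = 1) {
  binary <- is.logical(y) || all(y %in% c(0, 1, NA))
  if (is.logical(y)) y <- as.numeric(y)
  blocks <- collapse_blocks(genotypes, map)
  reps <- match(blocks$representatives, map$marker)
  B <- blocks$n_blocks
  n_pairs <- B * (B - 1) / 2
  alpha_adj <- alpha / n_pairs
  g <- geno_numeric(genotypes)
  best <- NULL
  for (i in seq_len(B - 1)) {
    ai <- g[reps[i], ]
    for (j in seq(i + 1, B)) {
      bj <- g[reps[j], ]
      ok <- !is.na(ai) & !is.na(bj) & !is.na(y)
      if (sum(ok) < min_complete) next
      aa <- ai[ok]; bb <- bj[ok]; yy <- y[ok]
      cls_n <- tabulate((aa + 3) / 2 + (bb + 1), 4)
      if (any(cls_n == 0)) next
      if (!binary && stats::sd(yy) == 0) next
      fit <- if (binary) .pair_model_binary(yy, aa, bb)
      else .pair_model_continuous(yy, aa, bb)
      if (is.null(best) || fit$model_p < best$model_p) {
        best <- c(fit, list(marker_a = map$marker[reps[i]],
                            marker_b = map$marker[reps[j]],
                            a = aa, b = bb, y = yy))
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$interaction_p <- if (binary)
    .pair_interaction_binary(best$y, best$a, best$b, best)
  else .pair_interaction_continuous(best$y, best$a, best$b, best)
  cis_locus <- "none"
  if (!is.null(gene_row) && nrow(gene_row) == 1) {
    mid <- (gene_row$start + gene_row$end) / 2
    margin <- cis_margin_mb * 1e6
    is_cis <- function(mk) {
      row <- map[map$marker == mk, ]
      row$chrom == gene_row$chrom && abs(row$bp - mid) <= margin
    }
    if (is_cis(best$marker_a)) cis_locus <- "a"
    else if (is_cis(best$marker_b)) cis_locus <- "b"
  }
  list(marker_a = best$marker_a, marker_b = best$marker_b,
       model_p = best$model_p, interaction_p = best$interaction_p,
       class_means = best$class_means, alpha_adj = alpha_adj,
       n_blocks = B, passes_alpha = best$model_p < alpha_adj,
       cis_locus = cis_locus)
}
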