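#' Relate genes to CNV/PAV segments
#'
#' For each gene: `entirely_within` when fully contained in exactly one
#' focal-class segment, `multiple_segments` when overlapping two or more,
#' `intersecting` when partially overlapping one, `other` otherwise.
#'
#' @param annot A [gene_annotation()].
#' @param segments A `cnv_segments` data frame (see [read_segments()]).
#' @param focal_classes CGH classes considered (default the copy-gain and PAV
#'   classes).
#' @return Data frame: `gene`, `relation`, `segments` (comma-separated
#'   indices into the focal segment table).
#' @export
relate_genes_segments <- function(annot, segments,
                                  focal_classes = c("B>M_int", "B>M_CNV",
                                                    "B>M_PAV", "M>B_CNV")) {
  seg <- segments[segments$cgh_class %in% focal_classes, , drop = FALSE]
  gr_gene <- GenomicRanges::GRanges(annot$chrom,
                                    IRanges::IRanges(annot$start, annot$end))
  gr_seg <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start, seg$end))
  hits <- GenomicRanges::findOverlaps(gr_gene, gr_seg)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  relation <- rep("other", nrow(annot))
  seg_refs <- rep("", nrow(annot))
  for (i in unique(qh)) {
    js <- sh[qh == i]
    seg_refs[i] <- paste(js, collapse = ",")
    if (length(js) >= 2) {
      relation[i] <- "multiple_segments"
    } else {
      j <- js
      contained <- annot$start[i] >= seg$start[j] & annot$end[i] <= seg$end[j]
      relation[i] <- if (contained) "entirely_within" else "intersecting"
    }
  }
  data.frame(gene = annot$gene, relation = relation, segments = seg_refs,
             stringsAsFactors = FALSE)
}

# genotype of the physically nearest marker per gene (same chromosome)
local_genotype <- function(annot, genotypes, map) {
  mid <- (annot$start + annot$end) / 2
  out <- matrix(NA_character_, nrow(annot), ncol(genotypes),
                dimnames = list(annot$gene, colnames(genotypes)))
  for (i in seq_len(nrow(annot))) {
    rows <- which(map$chrom == annot$chrom[i])
    if (!length(rows)) next
    j <- rows[which.min(abs(map$bp[rows] - mid[i]))]
    out[i, ] <- genotypes[j, ]
  }
  out
}

#' Filter genes eligible for CNV-expression association
#'
#' Keeps genes expressed (RPKM at least `cutoff`) in more than `min_frac` of
#' all samples and expressed in at least `min_per_class` RILs for each local
#' genotype class (genotype of the physically nearest marker). Genes on a
#' chromosome without markers are excluded as unmapped.
#'
#' @param expr An [expression_matrix()].
#' @param annot A [gene_annotation()] of candidate genes.
#' @param genotypes,map Genotypes and genetic map.
#' @param cutoff RPKM expression cutoff (default 1.03).
#' @param min_frac Minimum expressing fraction over all samples
#'   (strict >, default 0.40).
#' @param min_per_class Minimum expressing RILs per genotype class
#'   (default 40).
#' @return Data frame: `gene`, `eligible`, `reason`.
#' @export
cnv_expression_filter <- function(expr, annot, genotypes, map, cutoff = 1.03,
                                  min_frac = 0.40, min_per_class = 40) {
  v <- expr$values
  rv <- ril_values(expr)
  lg <- local_genotype(annot, genotypes, map)
  rows <- lapply(seq_len(nrow(annot)), function(i) {
    g <- annot$gene[i]
    if (!g %in% rownames(v))
      return(data.frame(gene = g, eligible = FALSE, reason = "not-measured"))
    if (all(is.na(lg[i, ])))
      return(data.frame(gene = g, eligible = FALSE, reason = "unmapped"))
    if (mean(v[g, ] >= cutoff) <= min_frac)
      return(data.frame(gene = g, eligible = FALSE, reason = "low-expressed-fraction"))
    cls <- lg[i, colnames(rv)]
    expressing <- rv[g, ] >= cutoff
    nA <- sum(expressing & cls == "A", na.rm = TRUE)
    nB <- sum(expressing & cls == "B", na.rm = TRUE)
    if (min(nA, nB) < min_per_class)
      return(data.frame(gene = g, eligible = FALSE, reason = "class-too-small"))
    data.frame(gene = g, eligible = TRUE, reason = "")
  })
  do.call(rbind, rows)
}

#' Association between local genotype and expression
#'
#' Two-sided t-test on `log2(RPKM + 1)` between the two local genotype
#' classes. The direction is positive when the higher-copy haplotype class
#' has the higher mean expression.
#'
#' @param values RIL RPKM values.
#' @param classes Local genotype per RIL (`"A"`/`"B"`; `H`/`NA` dropped).
#' @param higher_copy Which haplotype carries the copy gain (default `"A"`,
#'   i.e. B73).
#' @return A list: `direction` (`"positive"`, `"negative"` or `NA`), `t`,
#'   `p`.
#' @export
genotype_expression_association <- function(values, classes,
                                            higher_copy = "A") {
  ok <- classes %in% c("A", "B") & !is.na(values)
  v <- log2(values[ok] + 1)
  cl <- classes[ok]
  if (length(unique(cl)) < 2) ril_abort("degenerate", "one genotype class is empty")
  tt <- stats::t.test(v[cl == higher_copy], v[cl != higher_copy])
  dmean <- mean(v[cl == higher_copy]) - mean(v[cl != higher_copy])
  direction <- if (dmean > 0) "positive" else if (dmean < 0) "negative" else NA
  list(direction = direction, t = unname(tt$statistic), p = tt$p.value)
}

#' Cis-eQTL enrichment of CNV genes
#'
#' 2x2 comparison (cis vs non-cis by group) between CNV-related genes and all
#' detected genes, by chi-square without continuity correction, falling back
#' to Fisher's exact test when any expected cell is below 5.
#'
#' @param cnv_cis,cnv_total Counts for the CNV gene group.
#' @param all_cis,all_total Counts for the comparison group.
#' @return A list with `p` and `method`.
#' @export
cis_enrichment_test <- function(cnv_cis, cnv_total, all_cis, all_total) {
  if (cnv_total < 1 || all_total < 1) ril_abort("empty", "empty group")
  tab <- rbind(c(cnv_cis, cnv_total - cnv_cis),
               c(all_cis, all_total - all_cis))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p = stats::fisher.test(tab)$p.value, method = "fisher")
  } else {
    list(p = suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value,
         method = "chisq")
  }
}

#' Fragment / ancestral gene co-expression
#'
#' Pearson correlation over RILs (pairwise-complete) between each transposed
#' fragment gene and its ancestral syntenic homolog, with the p-value from the
#' t-transform of r, multiplicity adjustment over tested pairs, coupling by
#' the sign of r, and cis/trans action by the same-chromosome-within-window
#' rule. Pairs with fewer than 10 complete observations are skipped.
#'
#' @param pairs Data frame with columns `fragment`, `ancestral`.
#' @param expr An [expression_matrix()].
#' @param annot Optional [gene_annotation()] for the action classification.
#' @param alpha Significance level after adjustment (default 0.05).
#' @param adjust Multiplicity adjustment method (default `"bonferroni"`).
#' @param cis_margin_mb Same-region window (default 1 Mb).
#' @return Data frame: `fragment`, `ancestral`, `r`, `p`, `p_adj`,
#'   `significant`, `coupling`, `action`.
#' @export
fragment_ancestral_correlation <- function(pairs, expr, annot = NULL,
                                           alpha = 0.05,
                                           adjust = "bonferroni",
                                           cis_margin_mb = 1) {
  rv <- ril_values(expr)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    f <- pairs$fragment[i]; a <- pairs$ancestral[i]
    if (!(f %in% rownames(rv)) || !(a %in% rownames(rv))) return(NULL)
    x <- rv[f, ]; y <- rv[a, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 10) return(NULL)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NULL)
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    action <- NA_character_
    if (!is.null(annot)) {
      fr <- annot[annot$gene == f, ]; ar <- annot[annot$gene == a, ]
      if (nrow(fr) == 1 && nrow(ar) == 1) {
        same <- fr$chrom == ar$chrom &&
          abs((fr$start + fr$end) / 2 - (ar$start + ar$end) / 2) <=
          cis_margin_mb * 1e6
        action <- if (same) "cis" else "trans"
      }
    }
    data.frame(fragment = f, ancestral = a, r = unname(ct$estimate),
               p = ct$p.value, action = action, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adj < alpha
  out$coupling <- ifelse(out$r < 0, "negative", "positive")
  out[, c("fragment", "ancestral", "r", "p", "p_adj", "significant",
          "coupling", "action")]
}

#' Gene-set permutation enrichment test
#'
#' Compares a statistic of a focal gene set (the mean of a feature, or the
#' proportion with a logical flag) with its distribution over `n_perm` random
#' equal-size draws (without replacement) from the feature universe. The
#' empirical p uses the add-one correction
#' `p = (1 + #(perm >= obs)) / (n_perm + 1)` for the upper tail; two-sided is
#' the doubled smaller tail (capped at 1).
#'
#' @param focal_set Character vector of focal gene ids (must be a subset of
#'   the universe, and no larger).
#' @param feature_table Data frame with columns `gene` and `value` (numeric or
#'   logical).
#' @param statistic `"mean"` or `"proportion"`.
#' @param n_perm Number of permutations (default 10000).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param seed Optional RNG seed.
#' @return A list: `observed`, `null_mean`, `p`.
#' @export
geneset_permutation_test <- function(focal_set, feature_table,
                                     statistic = c("mean", "proportion"),
                                     n_perm = 10000,
                                     alternative = c("two.sided", "greater",
                                                     "less"),
                                     seed = NULL) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  if (!all(focal_set %in% feature_table$gene))
    ril_abort("size", "focal set contains genes outside the universe")
  k <- length(focal_set)
  if (k > nrow(feature_table))
    ril_abort("size", "focal set larger than the universe")
  vals <- feature_table$value
  names(vals) <- feature_table$gene
  stat <- if (statistic == "mean") mean else function(x) mean(as.logical(x))
  observed <- stat(vals[focal_set])
  null <- vapply(seq_len(n_perm), function(i)
    stat(vals[sample.int(length(vals), k)]), numeric(1))
  p_up <- (1 + sum(null >= observed)) / (n_perm + 1)
  p_dn <- (1 + sum(null <= observed)) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_up, less = p_dn,
              two.sided = min(1, 2 * min(p_up, p_dn)))
  list(observed = observed, null_mean = mean(null), p = p)
}
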